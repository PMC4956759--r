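#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and a two-sided p-value,
#' the correlation used for all cohort-level agreement analyses.
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @return List: `r`, `p`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    stop("zero rank variance")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         alternative = "two.sided",
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Kruskal-Wallis omnibus test with Dunn-Bonferroni pairwise comparisons
#'
#' Omnibus Kruskal-Wallis H (tie-corrected) across groups followed by
#' Dunn's pairwise z-tests with Bonferroni adjustment, the convention of
#' standard statistical software for Kruskal-Wallis post-hoc comparison.
#' When every value is identical the data carry no ordering information;
#' this degenerate case is reported as "no difference" (H = 0, p = 1).
#'
#' @param values Numeric vector (one value per sample).
#' @param groups Group labels (>= 2 groups, each with >= 2 members).
#' @return List: `H`, `p` (omnibus), `pairwise` (data frame `group1`,
#'   `group2`, `z`, `p_adj`), `degenerate`.
#' @export
group_compare <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  tab <- table(groups)
  if (any(tab < 2L)) stop("empty or singleton group: ",
                          paste(names(tab)[tab < 2L], collapse = ", "))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2L)
  if (length(unique(values)) == 1L) {
    pw <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                     z = 0, p_adj = 1, stringsAsFactors = FALSE)
    return(list(H = 0, p = 1, pairwise = pw, degenerate = TRUE))
  }
  kw <- stats::kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- as.numeric(tab)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  m <- ncol(pairs)
  z <- p_adj <- numeric(m)
  for (j in seq_len(m)) {
    i1 <- match(pairs[1L, j], lev); i2 <- match(pairs[2L, j], lev)
    se <- sqrt(s2 * (1 / n[i1] + 1 / n[i2]))
    z[j] <- (rbar[i1] - rbar[i2]) / se
    p_adj[j] <- min(1, 2 * stats::pnorm(-abs(z[j])) * m)
  }
  list(H = unname(kw$statistic), p = kw$p.value,
       pairwise = data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                             z = z, p_adj = p_adj, stringsAsFactors = FALSE),
       degenerate = FALSE)
}

#' Cohort statistics table
#'
#' Per parameter and zone: Spearman correlation of the per-sample zonal
#' summary against OARSI grade, and (for the four parameters compared
#' between OA groups: amide I area, carbohydrate area, collagen integrity
#' and the 1202 cm^-1 second-derivative peak) the Kruskal-Wallis omnibus
#' p-value and Dunn-Bonferroni pairwise p-values across the three pooled
#' OA groups. Statistics operate on per-sample summaries only, never on
#' pixels, to avoid pseudo-replication. Significance is annotated at 0.05
#' (*) and 0.01 (**).
#'
#' @param summaries Data frame of zonal summaries: one row per sample x
#'   zone with the parameter columns, `sample_id` and `zone`.
#' @param manifest [cohort_manifest()] output.
#' @return Data frame: `parameter`, `zone`, `spearman_r`, `spearman_p`,
#'   `kw_p`, `p_g1_g2`, `p_g1_g3`, `p_g2_g3`, `signif`.
#' @export
cohort_statistics <- function(summaries, manifest) {
  params <- c("amide_I_area", "carbohydrate_area", "carb_over_amideI",
              "collagen_integrity", "d2_1202", "d2_1064")
  kw_params <- c("amide_I_area", "carbohydrate_area", "collagen_integrity",
                 "d2_1202")
  out <- list()
  for (zn in unique(summaries$zone)) {
    sub <- summaries[summaries$zone == zn, ]
    idx <- match(sub$sample_id, manifest$sample_id)
    grade <- manifest$oarsi_grade[idx]
    grp <- manifest$group[idx]
    for (pm in params) {
      v <- sub[[pm]]
      sp <- spearman_cor(grade, v)
      row <- data.frame(parameter = pm, zone = zn, spearman_r = sp$r,
                        spearman_p = sp$p, kw_p = NA_real_,
                        p_g1_g2 = NA_real_, p_g1_g3 = NA_real_,
                        p_g2_g3 = NA_real_, stringsAsFactors = FALSE)
      if (pm %in% kw_params && length(unique(grp)) >= 2L) {
        gc <- group_compare(v, grp)
        row$kw_p <- gc$p
        pw <- gc$pairwise
        get_p <- function(a, b) {
          hit <- (pw$group1 == a & pw$group2 == b) |
            (pw$group1 == b & pw$group2 == a)
          if (any(hit)) pw$p_adj[hit][1L] else NA_real_
        }
        row$p_g1_g2 <- get_p("1", "2")
        row$p_g1_g3 <- get_p("1", "3")
        row$p_g2_g3 <- get_p("2", "3")
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  res$signif <- ifelse(is.na(res$spearman_p), "",
                       ifelse(res$spearman_p < 0.01, "**",
                              ifelse(res$spearman_p < 0.05, "*", "")))
  res
}
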