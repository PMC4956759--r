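#' Partial least squares regression (NIPALS)
#'
#' Sequential extraction of latent variables maximizing covariance between
#' the (internally mean-centred) predictors and response. Score vectors are
#' mutually orthogonal. Regression coefficients are returned for every
#' truncation 1..n_lv, so cross-validation can scan latent-variable counts
#' from a single fit.
#'
#' @param X n_samples x n_vars predictor matrix.
#' @param y Response vector.
#' @param n_lv Number of latent variables,
#'   `<= min(n_samples - 1, n_vars)`.
#' @return Object of class `plsr_model`: `coef` (n_vars x n_lv, original
#'   scale), `intercept` (length n_lv), `scores`, `loadings`, `weights`,
#'   `y_loadings`, `n_lv` (may be fewer than requested if X is exhausted).
#' @export
plsr_fit <- function(X, y, n_lv) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (stats::var(y) < .Machine$double.eps) stop("zero-variance response")
  if (n_lv > min(n - 1L, p)) {
    stop("n_lv must be <= min(n_samples - 1, n_vars)")
  }
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2L, xm)
  f <- y - ym
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  TT <- matrix(0, n, n_lv); q <- numeric(n_lv)
  a <- 0L
  for (i in seq_len(n_lv)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pp <- crossprod(E, t) / tt
    qq <- sum(f * t) / tt
    E <- E - tcrossprod(t, pp)
    f <- f - qq * t
    a <- i
    W[, i] <- w; P[, i] <- pp; TT[, i] <- t; q[i] <- qq
  }
  if (a == 0L) stop("no latent variable could be extracted")
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  TT <- TT[, seq_len(a), drop = FALSE]; q <- q[seq_len(a)]
  coef <- matrix(0, p, a)
  R <- crossprod(P, W)          # upper triangular with unit-ish diagonal
  for (i in seq_len(a)) {
    Ri <- R[seq_len(i), seq_len(i), drop = FALSE]
    coef[, i] <- W[, seq_len(i), drop = FALSE] %*%
      solve(Ri, q[seq_len(i)])
  }
  intercept <- ym - as.numeric(crossprod(xm, coef))
  structure(list(coef = coef, intercept = intercept, weights = W,
                 loadings = P, scores = TT, y_loadings = q,
                 x_mean = xm, y_mean = ym, n_lv = a),
            class = "plsr_model")
}

#' Predict from a PLSR model
#'
#' @param object A `plsr_model`.
#' @param newdata Matrix of predictors.
#' @param n_lv Latent variables to use (default: all fitted). If a vector,
#'   a matrix of predictions is returned with one column per entry.
#' @param ... Unused.
#' @export
predict.plsr_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  newdata <- matrix(as.numeric(newdata), ncol = length(object$x_mean))
  n_lv <- pmin(n_lv, object$n_lv)
  out <- sweep(newdata %*% object$coef[, n_lv, drop = FALSE], 2L,
               object$intercept[n_lv], `+`)
  if (length(n_lv) == 1L) as.numeric(out) else out
}

#' Leave-one-out cross-validation of PLSR
#'
#' For each left-out sample the model is fitted on the remainder; the
#' number of latent variables for that fold is chosen by nested
#' cross-validation on the training fold (`inner_folds`-fold, deterministic
#' response-stratified fold assignment, minimizing inner RMSECV), capped at
#' `n_lv_max`. The search starts at 2 latent variables whenever the data
#' admit them: a single-LV model on strongly collinear spectra collapses
#' onto one score direction, and its leave-one-out predictions are then
#' dominated by leverage and fold-mean artifacts rather than signal.
#' Fully deterministic given the inputs.
#'
#' @param X Predictor matrix (one row per sample).
#' @param y Responses (>= 3 samples).
#' @param n_lv_max Cap on latent variables (default 20).
#' @param inner_folds Folds of the nested selection (default 5; values
#'   >= the training-fold size fall back to inner leave-one-out).
#' @return List: `predictions`, `n_lv_fold` (chosen per fold), `n_lv`
#'   (count minimizing the plain LOOCV error curve, reported for the
#'   model), `rmsecv` (of `predictions`), `rmsecv_curve` (per LV count).
#' @export
loocv <- function(X, y, n_lv_max = 20L, inner_folds = 5L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 samples for LOOCV")
  if (stats::var(y) < .Machine$double.eps) stop("zero-variance response")
  a_out <- min(n_lv_max, n - 2L, ncol(X))
  a_lo <- min(2L, a_out)                 # 1-LV models only when unavoidable
  # plain LOOCV curve over LV counts (for the reported model size)
  curve_pred <- matrix(NA_real_, n, a_out)
  for (i in seq_len(n)) {
    fit <- plsr_fit(X[-i, , drop = FALSE], y[-i],
                    min(a_out, n - 2L, ncol(X)))
    curve_pred[i, ] <- predict(fit, X[i, , drop = FALSE],
                               n_lv = pmin(seq_len(a_out), fit$n_lv))
  }
  rmsecv_curve <- sqrt(colMeans((curve_pred - y)^2))
  # nested selection: per fold, inner k-fold CV on the training set
  preds <- numeric(n)
  n_lv_fold <- integer(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    m <- nrow(Xtr)
    k_in <- min(inner_folds, m)
    a_in <- min(n_lv_max, m - ceiling(m / k_in) - 1L, ncol(X))
    if (a_in < 1L) {
      a_star <- 1L            # training fold too small for nested selection
    } else {
      # stratify folds over the sorted response: balanced and canonical
      # (identical training multisets get identical fold compositions)
      folds <- integer(m)
      folds[order(ytr)] <- rep_len(seq_len(k_in), m)
      inner <- matrix(NA_real_, m, a_in)
      for (f in seq_len(k_in)) {
        te <- folds == f
        fit <- plsr_fit(Xtr[!te, , drop = FALSE], ytr[!te],
                        min(a_in, sum(!te) - 1L))
        inner[te, ] <- predict(fit, Xtr[te, , drop = FALSE],
                               n_lv = pmin(seq_len(a_in), fit$n_lv))
      }
      cand <- min(a_lo, a_in):a_in
      a_star <- cand[which.min(sqrt(colMeans((inner - ytr)^2))[cand])]
    }
    fit <- plsr_fit(Xtr, ytr, min(a_star, m - 1L))
    preds[i] <- predict(fit, X[i, , drop = FALSE], n_lv = fit$n_lv)
    n_lv_fold[i] <- fit$n_lv
  }
  cand_out <- min(a_lo, a_out):a_out
  list(predictions = preds, n_lv_fold = n_lv_fold,
       n_lv = cand_out[which.min(rmsecv_curve[cand_out])],
       rmsecv = sqrt(mean((preds - y)^2)), rmsecv_curve = rmsecv_curve)
}

#' CARS retention schedule
#'
#' Exponentially decreasing enforced retention counts
#' `r_i = round(p * a * exp(-k * i))` calibrated so that `r_1 = p` (all
#' variables) and `r_n = 2`; the sequence is monotone nonincreasing.
#'
#' @param p Number of variables.
#' @param n_runs Number of CARS iterations.
#' @return Integer vector of length `n_runs`.
#' @export
cars_schedule <- function(p, n_runs) {
  if (n_runs == 1L) return(as.integer(p))
  k <- log(p / 2) / (n_runs - 1L)
  a <- exp(k)
  r <- as.integer(round(p * a * exp(-k * seq_len(n_runs))))
  r[1L] <- as.integer(p)
  r[n_runs] <- 2L
  r
}

#' Competitive adaptive reweighted sampling (CARS) variable selection
#'
#' Iterative PLS-coefficient-driven variable elimination. At iteration i a
#' PLSR model is fitted on a Monte-Carlo subset of the samples
#' (`mc_ratio`); variables are ranked by the absolute value of their
#' regression coefficients; the enforced retention count follows
#' [cars_schedule()]; within it, adaptive reweighted sampling draws
#' variables with probability proportional to `|coefficient|`. Each
#' iteration's retained subset is scored by k-fold cross-validated RMSECV
#' (best LV count up to `max_lv`); the subset with minimal RMSECV wins,
#' ties going to fewer variables and then to the earlier iteration. With
#' `n_runs = 1` the full variable set is returned.
#'
#' Because a single elimination chain is stochastic (one unlucky
#' Monte-Carlo fit can discard a genuinely informative wavenumber for
#' good), `n_chains` independent chains are run and the subset with the
#' lowest cross-validated RMSECV across chains is returned -- the usual
#' practice when CARS is applied to spectroscopic data.
#'
#' @param X,y Predictors and response.
#' @param n_runs CARS iterations per chain (default 50).
#' @param mc_ratio Monte-Carlo sample ratio (default 0.8).
#' @param max_lv LV cap for the internal PLS models (default 20).
#' @param n_folds Folds of the scoring cross-validation (default 5).
#' @param n_chains Independent elimination chains (default 5).
#' @param seed Integer seed (Monte-Carlo sampling and fold assignment).
#' @return List: `selected` (sorted column indices), `best_chain`,
#'   `best_iter`, `rmsecv` (per iteration, winning chain), `n_retained`
#'   (per iteration, winning chain), `schedule`, `subsets` (winning
#'   chain), `chain_rmsecv` (best RMSECV per chain).
#' @export
cars_select <- function(X, y, n_runs = 50L, mc_ratio = 0.8, max_lv = 20L,
                        n_folds = 5L, n_chains = 5L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 2L) stop("need at least 2 variables")
  withr::with_seed(seed, {
    folds <- rep_len(seq_len(n_folds), n)[sample.int(n)]
    chains <- lapply(seq_len(n_chains), function(cc)
      cars_chain(X, y, n_runs, mc_ratio, max_lv, folds))
    best_r <- vapply(chains, function(ch) min(ch$rmsecv), 0)
    best_s <- vapply(chains, function(ch) length(ch$selected), 0L)
    win <- order(best_r, best_s, seq_len(n_chains))[1L]
    ch <- chains[[win]]
    list(selected = ch$selected, best_chain = win, best_iter = ch$best_iter,
         rmsecv = ch$rmsecv, n_retained = lengths(ch$subsets),
         schedule = ch$schedule, subsets = ch$subsets,
         chain_rmsecv = best_r)
  })
}

# one CARS elimination chain (uses the ambient RNG stream)
cars_chain <- function(X, y, n_runs, mc_ratio, max_lv, folds) {
  n <- nrow(X); p <- ncol(X)
  sched <- cars_schedule(p, n_runs)
  retained <- seq_len(p)
  rmsecv <- numeric(n_runs)
  subsets <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    mc <- sample.int(n, max(3L, round(mc_ratio * n)))
    a <- min(max_lv, length(mc) - 2L, length(retained))
    fit <- plsr_fit(X[mc, retained, drop = FALSE], y[mc], a)
    wgt <- abs(fit$coef[, fit$n_lv])
    if (all(wgt < .Machine$double.eps)) {
      stop("degenerate response: all PLS coefficients zero")
    }
    r_i <- min(sched[i], length(retained))
    if (r_i < length(retained)) {
      # adaptive reweighted sampling: competitive weighted draw of exactly
      # r_i survivors (without replacement), so the retained count follows
      # the enforced exponential schedule while elimination pressure is
      # proportional to |coefficient|
      draw <- sample(retained, size = r_i, replace = FALSE,
                     prob = wgt / sum(wgt))
      retained <- sort(draw)
    }
    subsets[[i]] <- retained
    rmsecv[i] <- cv_rmsecv(X[, retained, drop = FALSE], y, folds, max_lv)
  }
  best <- order(rmsecv, lengths(subsets), seq_len(n_runs))[1L]
  list(selected = subsets[[best]], best_iter = best, rmsecv = rmsecv,
       subsets = subsets, schedule = sched)
}

# k-fold cross-validated RMSE, minimized over LV counts
cv_rmsecv <- function(X, y, folds, max_lv) {
  n <- nrow(X)
  a_max <- min(max_lv, ncol(X), n - ceiling(n / max(folds)) - 1L)
  a_max <- max(a_max, 1L)
  pred <- matrix(NA_real_, n, a_max)
  for (f in unique(folds)) {
    te <- folds == f
    fit <- plsr_fit(X[!te, , drop = FALSE], y[!te],
                    min(a_max, sum(!te) - 1L, ncol(X)))
    pred[te, ] <- predict(fit, X[te, , drop = FALSE],
                          n_lv = pmin(seq_len(a_max), fit$n_lv))
  }
  min(sqrt(colMeans((pred - y)^2)))
}
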