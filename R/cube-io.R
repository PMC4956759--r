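#' Read and write hyperspectral cubes
#'
#' One file per sample, in a sectioned plain-text container holding the
#' axis, the absorbance array, both masks and the metadata. Numbers are
#' serialized with 17 significant digits, so a write/read round trip
#' reproduces every array bit-exactly. A CSV export of per-pixel spectra is
#' available for interoperability ([write_pixel_csv()]).
#'
#' Container layout (line oriented):
#' \preformatted{
#' CARTFTIR-CUBE 1
#' sample_id <id>
#' pixel_size <um>
#' dims <rows> <cols> <n_wavenumbers>
#' meta <JSON object>
#' axis
#' <one line: wavenumbers>
#' valid_mask
#' <rows lines of 0/1, cols entries each>
#' tissue_mask
#' <rows lines>
#' absorbance
#' <rows*cols lines (pixel (r,c) at line (r-1)*cols + c): spectrum values>
#' }
#'
#' @param path File path.
#' @return `read_cube()` returns a `spectral_cube`; `write_cube()` returns
#'   `path` invisibly.
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 6L || lines[[1L]] != "CARTFTIR-CUBE 1") {
    stop("malformed container: magic line missing")
  }
  header <- list()
  i <- 2L
  while (i <= length(lines) && grepl(" ", lines[[i]], fixed = TRUE)) {
    kv <- regmatches(lines[[i]], regexpr(" ", lines[[i]]), invert = TRUE)[[1L]]
    header[[kv[[1L]]]] <- kv[[2L]]
    i <- i + 1L
  }
  for (f in c("sample_id", "dims", "meta")) {
    if (is.null(header[[f]])) stop(f, " missing")
  }
  dims <- as.integer(strsplit(header$dims, " ")[[1L]])
  nr <- dims[1L]; nc <- dims[2L]; nw <- dims[3L]
  section <- function(name, n_lines) {
    if (i > length(lines) || lines[[i]] != name) stop(name, " missing")
    block <- lines[(i + 1L):(i + n_lines)]
    i <<- i + 1L + n_lines
    block
  }
  axis <- as.numeric(strsplit(section("axis", 1L), " ")[[1L]])
  if (length(axis) != nw) stop("axis/absorbance length mismatch")
  parse_mask <- function(block) {
    matrix(as.logical(as.integer(unlist(strsplit(block, " ")))),
           nrow = nr, ncol = nc, byrow = TRUE)
  }
  vm <- parse_mask(section("valid_mask", nr))
  tm <- parse_mask(section("tissue_mask", nr))
  ab_lines <- section("absorbance", nr * nc)
  ab <- array(NA_real_, dim = c(nr, nc, nw))
  vals <- matrix(as.numeric(unlist(strsplit(ab_lines, " "))),
                 nrow = nr * nc, ncol = nw, byrow = TRUE)
  for (w in seq_len(nw)) {
    ab[, , w] <- matrix(vals[, w], nrow = nr, ncol = nc, byrow = TRUE)
  }
  meta <- jsonlite::fromJSON(header$meta, simplifyVector = TRUE)
  spectral_cube(header$sample_id, wn_axis(axis), ab,
                pixel_size = as.numeric(header$pixel_size),
                valid_mask = vm, tissue_mask = tm, metadata = as.list(meta))
}

#' @rdname read_cube
#' @param cube A `spectral_cube`.
#' @export
write_cube <- function(cube, path) {
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ",
                                       dirname(path))
  d <- dim(cube$absorbance)
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  mask_lines <- function(m) {
    apply(m, 1L, function(r) paste(as.integer(r), collapse = " "))
  }
  # pixel (r, c) on line (r-1)*cols + c, spectra as rows
  flat <- matrix(cube$absorbance, ncol = d[3L])           # (r + (c-1)*nr) rows
  ord <- as.vector(t(matrix(seq_len(d[1L] * d[2L]), d[1L], d[2L])))
  ab_lines <- vapply(ord, function(k) num(flat[k, ]), "")
  lines <- c(
    "CARTFTIR-CUBE 1",
    paste("sample_id", cube$sample_id),
    paste("pixel_size", sprintf("%.17g", cube$pixel_size)),
    paste("dims", d[1L], d[2L], d[3L]),
    paste("meta", as.character(jsonlite::toJSON(cube$metadata,
                                                auto_unbox = TRUE,
                                                digits = NA))),
    "axis", num(as.numeric(cube$axis)),
    "valid_mask", mask_lines(cube$valid_mask),
    "tissue_mask", mask_lines(cube$tissue_mask),
    "absorbance", ab_lines
  )
  writeLines(lines, path)
  invisible(path)
}

#' Export per-pixel spectra as CSV
#'
#' Long-format interoperability export: one row per pixel, columns
#' `sample_id`, `row`, `col`, then one column per wavenumber (named
#' `wn_<value>`). Only pixels selected by `mask` are written.
#'
#' @inheritParams as_spectrum_matrix
#' @param cube A `spectral_cube`.
#' @param path Output CSV path.
#' @export
write_pixel_csv <- function(cube, path, mask = c("valid", "tissue")) {
  m <- as_spectrum_matrix(cube, mask = match.arg(mask))
  df <- cbind(m$origin, as.data.frame(m$spectra))
  names(df)[-(1:3)] <- paste0("wn_", format(as.numeric(m$axis), trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
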