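#' Read a spike-count matrix from CSV
#'
#' The interchange format: a header row of stimulus angles (degrees,
#' strictly increasing) and one row of non-negative integer counts per
#' block.
#'
#' @param path Path to the CSV file.
#' @param dt Counting-window length in seconds (default 1).
#' @param periodic Passed to [stimulus_grid()].
#' @return A [spike_count_matrix()].
#' @export
read_counts <- function(path, dt = 1, periodic = FALSE) {
  raw <- utils::read.csv(path, check.names = FALSE)
  angles <- suppressWarnings(as.numeric(colnames(raw)))
  if (anyNA(angles))
    stop("header must contain numeric stimulus angles")
  if (any(diff(angles) <= 0))
    stop("header angles must be strictly increasing")
  x <- as.matrix(raw)
  bad <- which(is.na(x) | x < 0 | x != round(x), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("invalid count at row %d, column '%s' (must be a non-negative integer)",
                 bad[1L, 1L], colnames(raw)[bad[1L, 2L]]))
  spike_count_matrix(x, stimulus_grid(angles, periodic), dt)
}

#' @rdname read_counts
#' @param x A [spike_count_matrix()] to write.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "spike_count_matrix"))
  df <- as.data.frame(x$counts, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a tuning decomposition to JSON
#'
#' Round-trips all model arrays (`grid`, `f`, `phis`, `sigma_k2`,
#' `sigma0_2`, `dt`) through a single structured text file.
#'
#' @param decomp A [tuning_decomposition()].
#' @param path Output path.
#' @export
write_decomposition <- function(decomp, path) {
  stopifnot(inherits(decomp, "tuning_decomposition"))
  obj <- list(grid = decomp$grid$values,
              periodic = decomp$grid$periodic,
              f = decomp$f,
              phis = unname(decomp$phis),
              sigma_k2 = decomp$sigma_k2,
              sigma0_2 = decomp$sigma0_2,
              dt = decomp$dt)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tuning_decomposition(stimulus_grid(obj$grid, isTRUE(obj$periodic)),
                       obj$f, as.matrix(obj$phis), obj$sigma_k2,
                       obj$sigma0_2, obj$dt)
}
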