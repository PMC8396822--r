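#' @useDynLib bruxmorph, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif rlnorm density setNames
#' @importFrom utils head read.csv write.csv
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the
#' previous RNG state so callers never observe a side effect. A `NULL` seed
#' evaluates `expr` under the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## lognormal parametrised by its arithmetic mean and coefficient of variation;
## cv = 0 degenerates to the point mass at m (exactness matters for the
## zero-variance parameter-recovery invariant).
rlnormMeanCV <- function(n, m, cv) {
  stopifnot(m > 0, cv >= 0)
  if (cv == 0) return(rep(m, n))
  sdlog <- sqrt(log1p(cv^2))
  meanlog <- log(m) - sdlog^2 / 2
  rlnorm(n, meanlog, sdlog)
}

## truncated normal by rejection; truncation points are far in the tail for
## all package defaults so this never loops meaningfully.
rtruncnorm1 <- function(n, mean, sd, lower) {
  if (!all(is.finite(c(mean, sd, lower))))
    stop("non-finite hyperparameters for truncated-normal draw", call. = FALSE)
  if (sd == 0) {
    if (mean < lower) stop("degenerate truncated normal below its bound", call. = FALSE)
    return(rep(mean, n))
  }
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower)
  guard <- 0L
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncated-normal rejection failed to converge", call. = FALSE)
  }
  out
}

assertGrayImage <- function(img, what = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(what, " must be a numeric matrix of gray levels", call. = FALSE)
  if (any(!is.finite(img)))
    stop(what, " contains non-finite pixels", call. = FALSE)
  invisible(img)
}

#' Otsu's threshold for an 8-bit grayscale image
#'
#' Maximises between-class variance over the 0..255 histogram. Used as the
#' default global threshold by [segmentCells()].
#'
#' @param img numeric matrix of gray levels in \[0, 255\].
#' @return A single threshold value; pixels strictly below it are foreground
#'   for dark-object segmentation.
#' @export
otsuThreshold <- function(img) {
  assertGrayImage(img)
  counts <- tabulate(pmin(pmax(as.integer(round(img)), 0L), 255L) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) - 1L + 0.5
}

#' Read / write 8-bit grayscale PNG images
#'
#' Thin wrappers around the \pkg{png} package mapping between the package's
#' integer gray-level matrices (0..255, rows = image rows) and PNG files.
#'
#' @param img numeric matrix of gray levels in \[0, 255\].
#' @param path file path.
#' @return `readGrayPNG` returns an integer matrix; `writeGrayPNG` returns
#'   `path` invisibly.
#' @export
writeGrayPNG <- function(img, path) {
  assertGrayImage(img)
  png::writePNG(pmin(pmax(img, 0), 255) / 255, target = path)
  invisible(path)
}

#' @rdname writeGrayPNG
#' @export
readGrayPNG <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  matrix(as.integer(round(x * 255)), nrow = nrow(x))
}
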