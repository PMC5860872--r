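# Double-centering of a Euclidean distance matrix (V-statistic convention).
.dcenter <- function(d) {
  rm <- rowMeans(d)
  sweep(sweep(d, 1, rm), 2, rm) + mean(d)
}

# U-centering (unbiased convention); requires n >= 4. Diagonal is zero.
.ucenter <- function(d) {
  n <- nrow(d)
  rm <- rowSums(d)
  out <- d - outer(rm, rep(1, n)) / (n - 2) -
    outer(rep(1, n), rm) / (n - 2) + sum(d) / ((n - 1) * (n - 2))
  diag(out) <- 0
  out
}

.uinner <- function(a, b) {
  n <- nrow(a)
  sum(a * b) / (n * (n - 3))
}

.distMat <- function(x) as.matrix(dist(as.numeric(x)))

#' Distance correlation
#'
#' Szekely's empirical distance correlation: the normalized inner product of
#' the double-centered pairwise Euclidean distance matrices of `x` and `y`.
#' The value lies in `[0, 1]`, is 0 exactly when the empirical distance
#' covariance vanishes, detects non-linear and non-monotone dependence, and
#' is invariant to shifts and positive rescalings of either variable.
#'
#' @param x,y numeric vectors of equal length (at least 4).
#' @return Distance correlation in `[0, 1]`. A constant vector yields 0
#'   with a warning.
#' @seealso [pdcor()], [bcdcor()]
#' @export
dcor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("need at least 4 observations")
  A <- .dcenter(.distMat(x))
  B <- .dcenter(.distMat(y))
  dvx <- mean(A * A)
  dvy <- mean(B * B)
  if (dvx <= .Machine$double.eps || dvy <= .Machine$double.eps) {
    warning("constant input; distance correlation undefined, returning 0")
    return(0)
  }
  dc2 <- mean(A * B) / sqrt(dvx * dvy)
  sqrt(max(dc2, 0))
}

#' Bias-corrected distance correlation
#'
#' The U-statistic (unbiased) version of the squared distance correlation,
#' signed: `R*` can be slightly negative for independent data. This is the
#' unconditional quantity that [pdcor()] partials.
#'
#' @inheritParams dcor
#' @return Bias-corrected distance correlation (in `[-1, 1]`).
#' @export
bcdcor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("need at least 4 observations")
  A <- .ucenter(.distMat(x))
  B <- .ucenter(.distMat(y))
  den <- sqrt(.uinner(A, A) * .uinner(B, B))
  if (!is.finite(den) || den <= .Machine$double.eps) return(0)
  .uinner(A, B) / den
}

#' Partial distance correlation
#'
#' Partial distance correlation of `x` and `y` removing `z`, computed from
#' pairwise bias-corrected distance correlations
#' (`(Rxy - Rxz Ryz) / sqrt((1 - Rxz^2)(1 - Ryz^2))`), equivalently the
#' cosine between the U-centered distance matrices of `x` and `y` after
#' projecting out that of `z`. Degenerate denominators (e.g. `z` identical
#' to `x` or `y`) yield 0.
#'
#' @param x,y,z numeric vectors of equal length (at least 4).
#' @return Partial distance correlation (in `[-1, 1]`).
#' @export
pdcor <- function(x, y, z) {
  stopifnot(length(x) == length(y), length(y) == length(z))
  if (length(x) < 4) stop("need at least 4 observations")
  rxy <- bcdcor(x, y)
  rxz <- bcdcor(x, z)
  ryz <- bcdcor(y, z)
  den <- sqrt((1 - rxz^2) * (1 - ryz^2))
  if (!is.finite(den) || den <= .Machine$double.eps) return(0)
  (rxy - rxz * ryz) / den
}
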