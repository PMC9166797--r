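#' Place restricted-cubic-spline knots at default quantiles
#'
#' Knot locations follow the conventional quantile placements for restricted
#' cubic splines: k = 3 uses the 0.10/0.50/0.90 quantiles, k = 4 uses
#' 0.05/0.35/0.65/0.95, k = 5 uses 0.05/0.275/0.50/0.725/0.95, k = 6 uses
#' 0.05/0.23/0.41/0.59/0.77/0.95 and k = 7 uses
#' 0.025/0.1833/0.3417/0.50/0.6583/0.8167/0.975.
#'
#' @param x numeric vector with at least `k` distinct values.
#' @param k number of knots, 3 to 7.
#' @return Strictly increasing numeric vector of `k` knot locations, in the
#'   units of `x`.
#' @export
#' @examples
#' place_knots(1:100, 3)
place_knots <- function(x, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 3L || k > 7L) {
    stop("k must be an integer in 3..7", call. = FALSE)
  }
  x <- x[is.finite(x)]
  if (length(unique(x)) < k) {
    stop("x has fewer than k = ", k, " distinct values; ",
         "spline expansion is not applicable", call. = FALSE)
  }
  probs <- switch(as.character(k),
                  "3" = c(0.10, 0.50, 0.90),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
                  "6" = c(0.05, 0.23, 0.41, 0.59, 0.77, 0.95),
                  "7" = c(0.025, 0.1833, 0.3417, 0.50, 0.6583, 0.8167, 0.975))
  knots <- unname(stats::quantile(x, probs, type = 7))
  if (any(diff(knots) <= 0)) {
    stop("knot quantiles are tied; cannot place ", k, " distinct knots",
         call. = FALSE)
  }
  knots
}

#' Restricted cubic spline basis
#'
#' Expands a predictor into the k - 1 column basis of a cubic spline
#' constrained to be linear beyond its boundary knots. Column 1 is `x`
#' itself; for j = 1..k-2, column j+1 is
#' \deqn{[(x-t_j)_+^3 - (x-t_{k-1})_+^3 (t_k-t_j)/(t_k-t_{k-1})
#'        + (x-t_k)_+^3 (t_{k-1}-t_j)/(t_k-t_{k-1})] / (t_k-t_1)^2}
#' with \eqn{(u)_+ = \max(u, 0)}. The \eqn{(t_k-t_1)^2} divisor puts the
#' nonlinear columns on roughly the scale of `x`.
#'
#' @param x numeric vector (any values; the basis is defined on the whole
#'   line).
#' @param knots strictly increasing knot vector of length >= 3, e.g. from
#'   [place_knots()].
#' @return Numeric matrix with `length(x)` rows and `length(knots) - 1`
#'   columns.
#' @export
rcs_basis <- function(x, knots) {
  knots <- as.numeric(knots)
  k <- length(knots)
  if (k < 3L || any(diff(knots) <= 0)) {
    stop("knots must be a strictly increasing vector of length >= 3",
         call. = FALSE)
  }
  t1 <- knots[1]; tkm1 <- knots[k - 1]; tk <- knots[k]
  norm <- (tk - t1)^2
  cube <- function(u) pmax(u, 0)^3
  B <- matrix(0, length(x), k - 1)
  B[, 1] <- x
  for (j in seq_len(k - 2)) {
    B[, j + 1] <- (cube(x - knots[j]) -
                     cube(x - tkm1) * (tk - knots[j]) / (tk - tkm1) +
                     cube(x - tk) * (tkm1 - knots[j]) / (tk - tkm1)) / norm
  }
  colnames(B) <- c("x", paste0("x'", seq_len(k - 2)))
  B
}
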