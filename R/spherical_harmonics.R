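#' Real even-order spherical-harmonic design matrix
#'
#' Evaluates the real, antipodally symmetric SH basis (even degrees l = 0, 2,
#' ..., `order`) at the given unit directions. Basis convention: for degree l
#' and order m,
#' \deqn{Y_{l0} = N_{l0} P_l^0(\cos\theta),\quad
#'       Y_{lm} = \sqrt{2} N_{lm} P_l^m(\cos\theta)\cos m\phi\ (m>0),\quad
#'       Y_{l,-m} = \sqrt{2} N_{lm} P_l^m(\cos\theta)\sin m\phi,}
#' with \eqn{N_{lm} = \sqrt{(2l+1)/(4\pi)\,(l-m)!/(l+m)!}} and associated
#' Legendre functions carrying the Condon–Shortley phase. The basis is
#' orthonormal on the sphere and \eqn{Y_{00} = 1/\sqrt{4\pi}}, which pins the
#' normalization of every coefficient.
#'
#' @param directions N x 3 matrix of unit vectors (rows).
#' @param order Maximum even SH degree L.
#' @return N x (L+1)(L+2)/2 matrix; columns ordered by (l, m), m = -l..l.
#' @export
sh_design_matrix <- function(directions, order) {
  directions <- rbind(directions)
  if (ncol(directions) != 3L) stop("'directions' must be an N x 3 matrix")
  if (length(order) != 1L || order < 0 || order %% 2 != 0)
    stop("'order' must be a single even non-negative integer")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-4))
    stop("directions must be unit vectors (norm within 1e-4 of 1)")
  directions <- directions / nrm
  ct <- pmin(pmax(directions[, 3], -1), 1)
  phi <- atan2(directions[, 2], directions[, 1])
  n <- nrow(directions)
  B <- matrix(0, n, sh_n_coefficients(order))
  col <- 1L
  for (l in seq(0L, order, by = 2L)) {
    P <- pracma::legendre(l, ct)           # (l+1) x n, rows m = 0..l
    if (is.vector(P)) P <- matrix(P, nrow = l + 1L)
    for (m in -l:l) {
      am <- abs(m)
      N <- sqrt((2 * l + 1) / (4 * pi) * factorial(l - am) / factorial(l + am))
      B[, col] <- if (m < 0) {
        sqrt(2) * N * P[am + 1L, ] * sin(am * phi)
      } else if (m == 0) {
        N * P[1L, ]
      } else {
        sqrt(2) * N * P[am + 1L, ] * cos(am * phi)
      }
      col <- col + 1L
    }
  }
  B
}

#' Number of coefficients of the even-order SH basis
#' @param order Even maximum degree L.
#' @return (L+1)(L+2)/2.
#' @export
sh_n_coefficients <- function(order) as.integer((order + 1) * (order + 2) / 2)

#' Default SH order for a given number of sample directions
#'
#' The largest even L whose even-degree basis has no more coefficients than
#' there are samples: N = 3..5 gives L = 0, N = 6..14 gives L = 2, and so on.
#' With this rule a 3-direction orthogonal acquisition reduces the SH
#' estimator exactly to the simplified closed form, and 6 well-spread
#' directions resolve degree 2 (the diffusion-tensor profile) exactly.
#'
#' @param n_directions Number of diffusion-encoding directions.
#' @return Even integer order.
#' @export
sh_order_for <- function(n_directions) {
  if (n_directions < 1) stop("need at least one direction")
  L <- 0L
  while (sh_n_coefficients(L + 2L) <= n_directions) L <- L + 2L
  L
}

# diagonal of the Laplace-Beltrami penalty, l^2 (l+1)^2 per coefficient
.sh_lb_diag <- function(order) {
  unlist(lapply(seq(0L, order, by = 2L), function(l) rep(l^2 * (l + 1)^2, 2 * l + 1)))
}

#' Penalized least-squares SH fit
#'
#' Fits spherical samples in the real even-order SH basis by minimizing
#' \deqn{\|B c - d\|^2 + \lambda \sum_{l,m} l^2 (l+1)^2 c_{lm}^2,}
#' the Laplace–Beltrami-penalized least-squares problem. The degree-0
#' coefficient is never penalized, so the spherical mean is estimated without
#' shrinkage at any \eqn{\lambda}.
#'
#' @param values Numeric vector of samples, one per direction.
#' @param directions N x 3 matrix of unit vectors.
#' @param order Even SH degree; defaults to [sh_order_for()] of N.
#' @param lambda Laplace–Beltrami penalty weight (default 0.006).
#' @return Object of class `sh_fit`: list with `coefficients` (ordered by
#'   (l, m)), `order` and `lambda`.
#' @export
fit_sh <- function(values, directions, order = NULL, lambda = 0.006) {
  directions <- rbind(directions)
  if (length(values) != nrow(directions))
    stop(sprintf("%d values but %d directions", length(values), nrow(directions)))
  if (!all(is.finite(values))) stop("'values' must be finite")
  if (lambda < 0) stop("'lambda' must be non-negative")
  if (is.null(order)) order <- sh_order_for(nrow(directions))
  B <- sh_design_matrix(directions, order)
  A <- crossprod(B) + diag(lambda * .sh_lb_diag(order), ncol(B))
  if (lambda == 0 && rcond(A) < 1e-10)
    stop("SH system is rank-deficient for these directions; ",
         "use lambda > 0 or a lower order")
  coef <- drop(solve(A, crossprod(B, values)))
  structure(list(coefficients = coef, order = order, lambda = lambda),
            class = "sh_fit")
}

#' Evaluate a fitted SH expansion at new directions
#' @param fit An `sh_fit`.
#' @param directions M x 3 matrix of unit vectors.
#' @return Numeric vector of length M.
#' @export
sh_eval <- function(fit, directions) {
  stopifnot(inherits(fit, "sh_fit"))
  drop(sh_design_matrix(directions, fit$order) %*% fit$coefficients)
}

#' The degree-0 SH coefficient
#'
#' For a function H on the sphere fitted in this basis, the degree-0
#' coefficient equals \eqn{\frac{1}{\sqrt{4\pi}} \int_S H(u)\,du}; the
#' spherical mean of the fit is `sh_c00(fit) / sqrt(4*pi)`.
#'
#' @param fit An `sh_fit`.
#' @return Scalar coefficient.
#' @export
sh_c00 <- function(fit) {
  stopifnot(inherits(fit, "sh_fit"))
  unname(fit$coefficients[1])
}

#' @export
print.sh_fit <- function(x, ...) {
  cat(sprintf("SH fit: order %d (%d coefficients), lambda = %g\n",
              x$order, length(x$coefficients), x$lambda))
  cat(sprintf("  C00 = %.6g (spherical mean %.6g)\n",
              x$coefficients[1], x$coefficients[1] / sqrt(4 * pi)))
  invisible(x)
}
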