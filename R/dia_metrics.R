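#' Diffusion Anisotropy from three orthogonal ADC samples
#'
#' The closed-form DiA for three orthogonal, axis-aligned diffusivity
#' samples:
#' \deqn{DiA = 1 - \frac{(D_x + D_y + D_z)^2}{3 (D_x^2 + D_y^2 + D_z^2)}.}
#' This is the degree-0 spherical-harmonics estimator specialized to an
#' orthogonal triplet; it needs no gradient directions at all. Values lie in
#' \[0, 2/3\]: 0 exactly when the three samples are equal (isotropy) and the
#' supremum 2/3 only when a single sample is non-zero. Background voxels
#' where all three samples are 0 are defined to have DiA = 0 so they render
#' black.
#'
#' @param dx,dy,dz Non-negative diffusivities (scalars or arrays of a common
#'   shape), one per axis.
#' @return DiA, same shape as the inputs, in \[0, 2/3\].
#' @examples
#' dia_simplified(1e-3, 0.3e-3, 0.3e-3)  # 0.27684
#' @export
dia_simplified <- function(dx, dy, dz) {
  if (any(dx < 0, na.rm = TRUE) || any(dy < 0, na.rm = TRUE) || any(dz < 0, na.rm = TRUE))
    stop("diffusivities must be non-negative")
  ss <- dx^2 + dy^2 + dz^2
  out <- 1 - (dx + dy + dz)^2 / (3 * ss)
  out[ss == 0] <- 0
  out[dx == dy & dy == dz] <- 0    # exact isotropy maps to exactly 0
  pmin(pmax(out, 0), 2 / 3)
}

#' Average diffusivity of three orthogonal samples
#'
#' The arithmetic mean (Dx + Dy + Dz)/3, the quantity fast clinical
#' trace-weighted protocols report as their diffusion map.
#'
#' @inheritParams dia_simplified
#' @return Mean diffusivity, same shape as the inputs (mm\eqn{^2}/s).
#' @export
average_diffusivity <- function(dx, dy, dz) {
  if (any(dx < 0, na.rm = TRUE) || any(dy < 0, na.rm = TRUE) || any(dz < 0, na.rm = TRUE))
    stop("diffusivities must be non-negative")
  (dx + dy + dz) / 3
}

# linear functional a such that C00 of the penalized SH fit of samples d
# equals sum(a * d); shared by the D and D^2 fits since both use the same
# directions, order and lambda.
.c00_functional <- function(directions, order, lambda) {
  B <- sh_design_matrix(directions, order)
  A <- crossprod(B) + diag(lambda * .sh_lb_diag(order), ncol(B))
  if (lambda == 0 && rcond(A) < 1e-10)
    stop("SH system is rank-deficient for these directions; ",
         "use lambda > 0 or a lower order")
  drop(solve(A, t(B))[1, ])
}

#' Diffusion Anisotropy via the spherical-harmonics estimator
#'
#' The general DiA estimator: the ADC samples D and their squares D^2 are
#' each fitted in the real even-order SH basis (same order and
#' Laplace–Beltrami penalty), and
#' \deqn{DiA = 1 - \frac{C_{00}^2\{D\}}{\sqrt{4\pi}\; C_{00}\{D^2\}},}
#' which evaluates the defining integral ratio
#' \eqn{1 - [\int_S D]^2 / (4\pi \int_S D^2)} through the fitted spherical
#' means. With three orthogonal samples and the default order rule this
#' reduces exactly to [dia_simplified()]. The squared samples are fitted
#' directly (rather than squaring the fitted expansion), so both integrals
#' are estimated from the data in the same basis.
#'
#' @param samples Numeric vector of ADC samples (one per direction), or a
#'   matrix with one row per voxel and one column per direction.
#' @param directions N x 3 matrix of unit vectors.
#' @param order Even SH degree; default [sh_order_for()] of N.
#' @param lambda Laplace–Beltrami penalty (default 0.006, applied to both
#'   the D and the D^2 fit).
#' @return Scalar DiA in \[0, 1), or a vector of per-voxel values for matrix
#'   input. Voxels whose samples are all zero return 0.
#' @export
dia_sh <- function(samples, directions, order = NULL, lambda = 0.006) {
  directions <- rbind(directions)
  if (nrow(directions) < 3L)
    stop("DiA needs at least 3 diffusion-encoding directions")
  vec_in <- is.null(dim(samples))
  S <- if (vec_in) matrix(samples, nrow = 1L) else as.matrix(samples)
  if (ncol(S) != nrow(directions))
    stop(sprintf("%d sample column(s) but %d directions", ncol(S), nrow(directions)))
  if (any(S < 0, na.rm = TRUE)) stop("ADC samples must be non-negative")
  if (is.null(order)) order <- sh_order_for(nrow(directions))
  a <- .c00_functional(directions, order, lambda)
  c00_d <- drop(S %*% a)
  c00_d2 <- drop(S^2 %*% a)
  dia <- 1 - c00_d^2 / (sqrt(4 * pi) * c00_d2)
  dia[c00_d2 <= 0] <- 0
  dia <- pmin(pmax(dia, 0), 1 - .Machine$double.eps)
  if (vec_in) unname(dia[1]) else dia
}

#' Product quadrature rule on the unit sphere
#'
#' A Gauss–Legendre rule in the polar cosine crossed with a uniform rule in
#' azimuth, with weights summing to \eqn{4\pi}. Exact for spherical
#' polynomials up to high degree and rotationally robust, it serves as the
#' dense ground-truth integrator behind [dia_quadrature()].
#'
#' @param n_points Requested number of nodes (the rule uses the smallest
#'   product grid with at least this many).
#' @return List with `points` (M x 3 unit vectors) and `weights` (length M,
#'   summing to 4 pi).
#' @export
sphere_quadrature <- function(n_points = 2562) {
  nt <- max(4L, as.integer(ceiling(sqrt(n_points / 2))))
  gl <- pracma::gaussLegendre(nt, -1, 1)
  np <- 2L * nt
  phi <- (seq_len(np) - 0.5) * 2 * pi / np
  ct <- rep(gl$x, each = np)
  w <- rep(gl$w, each = np) * (2 * pi / np)
  st <- sqrt(pmax(1 - ct^2, 0))
  ph <- rep(phi, times = nt)
  list(points = cbind(st * cos(ph), st * sin(ph), ct), weights = w)
}

#' Diffusion Anisotropy by dense spherical quadrature
#'
#' Evaluates the defining integral form
#' \deqn{DiA = 1 - \frac{[\int_S D(u)\,du]^2}{4\pi \int_S D^2(u)\,du}}
#' directly with a dense quadrature rule. This is the reference oracle the
#' sampled estimators are judged against; it is rotation-invariant to
#' numerical precision.
#'
#' @param adc_fn Function mapping an M x 3 matrix of unit directions to a
#'   vector of non-negative diffusivities.
#' @param n_points Quadrature density (default 2562).
#' @return Scalar DiA in \[0, 1).
#' @export
dia_quadrature <- function(adc_fn, n_points = 2562) {
  q <- sphere_quadrature(n_points)
  D <- adc_fn(q$points)
  if (length(D) != nrow(q$points))
    stop("'adc_fn' must return one value per direction")
  iD <- sum(q$weights * D)
  iD2 <- sum(q$weights * D^2)
  if (iD2 <= 0) return(0)
  max(0, 1 - iD^2 / (4 * pi * iD2))
}

#' RGB orientation color code
#'
#' Encodes the dominant diffusion axis as hue and the anisotropy as
#' luminance, the three-direction analogue of the standard directional FA
#' color map: red = x (left–right), green = y (anterior–posterior), blue =
#' z (superior–inferior), each channel
#' \deqn{r = DiA \cdot D_x / D_{AV}}
#' (and likewise g, b) clipped into \[0, 1\]. Because the channels are tied
#' to the acquisition axes, the code reads as orientation *relative to the
#' image axes* and assumes the three gradients are axis-aligned. Voxels with
#' zero average diffusivity map to black.
#'
#' @inheritParams dia_simplified
#' @param dia Optional precomputed DiA of the same shape; computed via
#'   [dia_simplified()] when missing.
#' @return Array with a trailing dimension of length 3 (RGB in \[0, 1\]).
#' @export
color_code <- function(dx, dy, dz, dia = NULL) {
  if (is.null(dia)) dia <- dia_simplified(dx, dy, dz)
  dav <- average_diffusivity(dx, dy, dz)
  safe <- ifelse(dav > 0, dav, 1)
  r <- ifelse(dav > 0, dia * dx / safe, 0)
  g <- ifelse(dav > 0, dia * dy / safe, 0)
  b <- ifelse(dav > 0, dia * dz / safe, 0)
  shape <- if (is.null(dim(dx))) length(dx) else dim(dx)
  out <- array(c(r, g, b), dim = c(shape, 3L))
  pmin(pmax(out, 0), 1)
}

#' Compute DiA, average-diffusivity and color maps from an ADC map
#'
#' The map-level driver behind the command line. With `estimator = "auto"`
#' the simplified closed form is used iff the acquisition has exactly 3
#' mutually orthogonal directions (within `ortho_tol_deg`); otherwise the SH
#' estimator runs at the default order for the direction count. The RGB map
#' is produced only on the 3-direction orthogonal path, where the channel
#' axes are well defined; each sample is assigned to the image axis its
#' direction is closest to. A warning is issued when that triplet is
#' orthogonal but visibly tilted away from the axes, since the color code
#' then no longer reads as axis orientation.
#'
#' @param adc An `adc_map` from [compute_adc()].
#' @param estimator `"auto"`, `"simplified"` or `"sh"`.
#' @param lambda Laplace–Beltrami penalty for the SH path.
#' @param order SH order override (default: rule of [sh_order_for()]).
#' @param ortho_tol_deg Orthogonality tolerance in degrees for the auto /
#'   simplified path (default 2).
#' @return List of class `dia_maps`: `dia` (3-D), `dav` (3-D, mean
#'   diffusivity), `rgb` (4-D or NULL), `estimator`, `n_directions`, `mask`,
#'   `affine`.
#' @export
dia_compute <- function(adc, estimator = c("auto", "simplified", "sh"),
                        lambda = 0.006, order = NULL, ortho_tol_deg = 2) {
  stopifnot(inherits(adc, "adc_map"))
  estimator <- match.arg(estimator)
  dirs <- adc$directions
  n <- nrow(dirs)
  if (n < 3L) stop("DiA needs at least 3 diffusion-encoding directions")
  ortho3 <- .is_orthogonal_triplet(dirs, ortho_tol_deg)
  if (estimator == "auto") estimator <- if (ortho3) "simplified" else "sh"
  if (estimator == "simplified" && !ortho3)
    stop("the simplified estimator requires exactly 3 mutually orthogonal directions; ",
         "use estimator = 'sh'")

  d3 <- dim(adc$D)[1:3]
  maskv <- as.vector(adc$mask)
  dia <- array(0, d3)
  dav <- array(0, d3)
  rgb <- NULL

  if (estimator == "simplified") {
    ax <- apply(abs(dirs), 1, which.max)
    if (anyDuplicated(ax))
      stop("cannot assign the 3 directions to distinct image axes")
    tilt <- max(acos(pmin(apply(abs(dirs), 1, max), 1))) * 180 / pi
    if (tilt > ortho_tol_deg)
      warning(sprintf(paste0("orthogonal triplet is tilted %.1f degrees from the image axes; ",
                             "interpret the color code with caution"), tilt))
    ord <- order(ax)   # columns reordered to x, y, z
    Dx <- adc$D[, , , ord[1], drop = TRUE] * maskv
    Dy <- adc$D[, , , ord[2], drop = TRUE] * maskv
    Dz <- adc$D[, , , ord[3], drop = TRUE] * maskv
    dia <- dia_simplified(Dx, Dy, Dz)
    dav <- average_diffusivity(Dx, Dy, Dz)
    rgb <- color_code(Dx, Dy, Dz, dia)
  } else {
    S <- matrix(adc$D, nrow = prod(d3), ncol = n)
    S[!maskv, ] <- 0
    if (is.null(order)) order <- sh_order_for(n)
    a <- .c00_functional(dirs, order, lambda)
    c00_d <- drop(S %*% a)
    c00_d2 <- drop(S^2 %*% a)
    v <- 1 - c00_d^2 / (sqrt(4 * pi) * c00_d2)
    v[c00_d2 <= 0] <- 0
    dia <- array(pmin(pmax(v, 0), 1 - .Machine$double.eps), d3)
    # spherical mean of the fitted ADC profile, the N-direction analogue of
    # the three-sample average diffusivity
    dav <- array(pmax(c00_d / sqrt(4 * pi), 0), d3)
  }
  dia[!adc$mask] <- 0
  dav[!adc$mask] <- 0
  structure(list(dia = dia, dav = dav, rgb = rgb, estimator = estimator,
                 n_directions = n, order = if (estimator == "sh") order else 0L,
                 mask = adc$mask, affine = adc$affine),
            class = "dia_maps")
}

.is_orthogonal_triplet <- function(dirs, tol_deg = 2) {
  if (nrow(dirs) != 3L) return(FALSE)
  dots <- abs(c(sum(dirs[1, ] * dirs[2, ]), sum(dirs[1, ] * dirs[3, ]),
                sum(dirs[2, ] * dirs[3, ])))
  all(dots <= sin(tol_deg * pi / 180))
}

#' @export
print.dia_maps <- function(x, ...) {
  cat(sprintf("DiA maps (%s estimator, %d directions)\n", x$estimator, x$n_directions))
  inm <- x$dia[x$mask]
  if (length(inm))
    cat(sprintf("  DiA in mask: median %.4f, IQR %.4f-%.4f (%d voxels)\n",
                stats::median(inm), stats::quantile(inm, 0.25),
                stats::quantile(inm, 0.75), length(inm)))
  invisible(x)
}
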