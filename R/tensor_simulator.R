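#' Construct a diffusion tensor
#'
#' Assembles the 3 x 3 symmetric positive-semidefinite tensor V diag(lambda)
#' V' from eigenvalues and an optional orthonormal eigenvector matrix
#' (default: the identity, i.e. principal axes aligned with the image axes).
#'
#' @param eigenvalues Three non-negative diffusivities (mm\eqn{^2}/s),
#'   stored sorted in decreasing order.
#' @param eigenvectors Optional 3 x 3 orthonormal matrix, columns matching
#'   the eigenvalue order as given.
#' @return Object of class `diffusion_tensor`: list with `matrix`,
#'   `eigenvalues` (decreasing) and `eigenvectors`.
#' @examples
#' make_tensor(c(1, 0.3, 0.3) * 1e-3)   # the axis-aligned reference tensor
#' @export
make_tensor <- function(eigenvalues, eigenvectors = NULL) {
  eigenvalues <- as.numeric(eigenvalues)
  if (length(eigenvalues) != 3L || any(!is.finite(eigenvalues)))
    stop("'eigenvalues' must be three finite values")
  if (any(eigenvalues < 0)) stop("eigenvalues must be non-negative")
  if (is.null(eigenvectors)) eigenvectors <- diag(3)
  eigenvectors <- as.matrix(eigenvectors)
  if (!all(dim(eigenvectors) == c(3L, 3L)) ||
      max(abs(crossprod(eigenvectors) - diag(3))) > 1e-8)
    stop("'eigenvectors' must be a 3 x 3 orthonormal matrix")
  ord <- order(eigenvalues, decreasing = TRUE)
  eigenvalues <- eigenvalues[ord]
  eigenvectors <- eigenvectors[, ord, drop = FALSE]
  M <- eigenvectors %*% diag(eigenvalues) %*% t(eigenvectors)
  M <- (M + t(M)) / 2
  structure(list(matrix = M, eigenvalues = eigenvalues,
                 eigenvectors = eigenvectors),
            class = "diffusion_tensor")
}

#' @export
print.diffusion_tensor <- function(x, ...) {
  cat("Diffusion tensor, eigenvalues",
      paste(format(x$eigenvalues, digits = 4), collapse = ", "),
      sprintf("mm^2/s (FA = %.4f)\n", tensor_fa(x)))
  invisible(x)
}

#' Rotation matrices of the two simulation schemes
#'
#' `"plane"` rotates in the x–z plane, keeping the tensor's second axis
#' aligned with y:
#' \deqn{R = \begin{pmatrix} \cos\theta & 0 & \sin\theta \\ 0 & 1 & 0 \\
#'   -\sin\theta & 0 & \cos\theta \end{pmatrix}.}
#' `"spatial"` rotates about the diagonal axis (1,1,1)/\eqn{\sqrt 3}
#' (Rodrigues form), so that for \eqn{\theta > 0} none of the tensor axes
#' stays aligned with any image axis; its diagonal entries are
#' \eqn{1/3 + (2/3)\cos\theta} and at \eqn{\theta = 2\pi/3} it reduces to a
#' cyclic coordinate permutation.
#'
#' @param scheme `"plane"` or `"spatial"`.
#' @param theta Rotation angle in radians.
#' @return A proper 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(scheme = c("plane", "spatial"), theta) {
  scheme <- match.arg(scheme)
  if (scheme == "plane") {
    matrix(c(cos(theta), 0, -sin(theta),
             0, 1, 0,
             sin(theta), 0, cos(theta)), 3L, 3L)
  } else {
    k <- c(1, 1, 1) / sqrt(3)
    K <- matrix(c(0, k[3], -k[2],
                  -k[3], 0, k[1],
                  k[2], -k[1], 0), 3L, 3L)
    diag(3) * cos(theta) + sin(theta) * K + (1 - cos(theta)) * tcrossprod(k)
  }
}

#' Rotate a diffusion tensor
#'
#' Conjugates the tensor by a rotation, R T R'; eigenvalues (and hence FA
#' and any rotation-invariant anisotropy) are preserved.
#'
#' @param tensor A `diffusion_tensor`.
#' @param R A proper 3 x 3 rotation matrix.
#' @return The rotated `diffusion_tensor`.
#' @export
rotate_tensor <- function(tensor, R) {
  stopifnot(inherits(tensor, "diffusion_tensor"))
  R <- as.matrix(R)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || det(R) < 0)
    stop("'R' must be a proper rotation matrix")
  make_tensor(tensor$eigenvalues, R %*% tensor$eigenvectors)
}

#' Apparent diffusion coefficient of a tensor along directions
#'
#' The tensor-model ADC, D(u) = u' T u.
#'
#' @param tensor A `diffusion_tensor`.
#' @param directions Unit 3-vector or N x 3 matrix of unit rows.
#' @return Diffusivity, one value per direction (mm\eqn{^2}/s).
#' @export
tensor_adc <- function(tensor, directions) {
  stopifnot(inherits(tensor, "diffusion_tensor"))
  U <- rbind(directions)
  nrm <- sqrt(rowSums(U^2))
  if (any(abs(nrm - 1) > 1e-4)) stop("directions must be unit vectors")
  U <- U / nrm
  unname(drop(rowSums((U %*% tensor$matrix) * U)))
}

#' Fractional anisotropy of a tensor
#'
#' The standard diffusion-tensor FA,
#' \deqn{FA = \sqrt{\tfrac{3}{2}} \frac{\|\lambda - \bar\lambda\|}{\|\lambda\|},}
#' used as the reference anisotropy index the DiA is compared against. The
#' reference tensor with eigenvalues (1, 0.3, 0.3) x 1e-3 mm\eqn{^2}/s has
#' FA = 0.6444.
#'
#' @param tensor A `diffusion_tensor`.
#' @return FA in \[0, 1\].
#' @export
tensor_fa <- function(tensor) {
  stopifnot(inherits(tensor, "diffusion_tensor"))
  l <- tensor$eigenvalues
  if (all(l == 0)) stop("FA is undefined for the zero tensor")
  sqrt(3 / 2) * sqrt(sum((l - mean(l))^2)) / sqrt(sum(l^2))
}

#' Deterministic gradient direction schemes
#'
#' Named direction sets used by the simulator and the experiments:
#' \describe{
#'   \item{`"axes"` / 3}{the Cartesian axes x, y, z.}
#'   \item{4}{cube-diagonal (tetrahedral) set, the electrostatic-repulsion
#'     optimum for 4 antipodal directions.}
#'   \item{5}{a fixed electrostatic-repulsion-optimized 5-direction set
#'     (coordinates committed below).}
#'   \item{6}{the icosahedral 6-direction set classical in DTI; as a
#'     spherical 5-design it integrates the squared tensor profile exactly,
#'     which is why 6 directions yield an orientation-independent DiA.}
#'   \item{other n}{a spherical Fibonacci hemisphere set of n points,
#'     uniform and free of antipodal duplicates.}
#' }
#'
#' @param n Number of directions (or the string `"axes"`).
#' @return N x 3 matrix of unit direction vectors with a `name` attribute.
#' @export
direction_scheme <- function(n) {
  if (identical(n, "axes")) n <- 3L
  n <- as.integer(n)
  if (n < 3L) stop("direction schemes need n >= 3")
  dirs <- switch(as.character(n),
    "3" = diag(3),
    "4" = matrix(c(1, 1, 1,   1, 1, -1,   1, -1, 1,   1, -1, -1),
                 4L, 3L, byrow = TRUE) / sqrt(3),
    "5" = matrix(c( 0.779173, -0.458263, 0.427650,
                   -0.544561,  0.660888, 0.516411,
                   -0.823960, -0.476283, 0.306992,
                    0.446231,  0.672025, 0.590982,
                   -0.066619, -0.344169, 0.936541),
                 5L, 3L, byrow = TRUE),
    "6" = {
      gr <- (1 + sqrt(5)) / 2
      m <- matrix(c(0, 1, gr,   0, 1, -gr,   1, gr, 0,
                    1, -gr, 0,  gr, 0, 1,   -gr, 0, 1),
                  6L, 3L, byrow = TRUE)
      m
    },
    fibonacci_directions(n)
  )
  dirs <- dirs / sqrt(rowSums(dirs^2))
  nm <- switch(as.character(n), "3" = "axes", "4" = "tetrahedral",
               "5" = "repulsion5", "6" = "icosahedral", "fibonacci")
  structure(dirs, name = nm)
}

#' Spherical Fibonacci hemisphere directions
#'
#' The first n points of a 2n-point spherical Fibonacci lattice — all on the
#' upper hemisphere, near-uniform after antipodal identification. Used as
#' the deterministic stand-in for dense acquisition schemes (e.g. a
#' 64-direction shell).
#'
#' @param n Number of directions.
#' @return N x 3 matrix of unit vectors, all with z > 0.
#' @export
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - i / n                      # upper half of the 2n-point lattice
  th <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(th), r * sin(th), z)
}

#' Synthesize a diffusion-weighted phantom
#'
#' Generates the single-shell mono-exponential signal
#' S = S0 exp(-b u' T u) for every voxel and direction of a tensor layout,
#' prepends b0 volume(s), and optionally corrupts the magnitudes with Rician
#' noise (modulus of a complex Gaussian perturbation, the magnitude-MRI
#' noise model). The simulation experiments run noiseless; noise is opt-in.
#'
#' @param tensors A single `diffusion_tensor`, or a list of them.
#' @param layout 3-D integer array indexing into `tensors` per voxel, with 0
#'   meaning empty background (signal 0). Default: a single voxel when one
#'   tensor is given.
#' @param directions N x 3 matrix of unit gradient directions (e.g. from
#'   [direction_scheme()]).
#' @param b Shell b-value (s/mm\eqn{^2}), default 1000.
#' @param s0 Baseline signal, default 1000.
#' @param noise_sigma Rician noise level (signal units); 0 disables noise.
#' @param n_b0 Number of baseline volumes to prepend (default 1).
#' @param seed Optional RNG seed applied locally for the noise draw.
#' @return A [dwi_volume()] with an identity affine and matching
#'   [gradient_table()].
#' @export
synthesize_phantom <- function(tensors, layout = NULL, directions,
                               b = 1000, s0 = 1000, noise_sigma = 0,
                               n_b0 = 1L, seed = NULL) {
  if (inherits(tensors, "diffusion_tensor")) tensors <- list(tensors)
  if (!length(tensors) || !all(vapply(tensors, inherits, TRUE, "diffusion_tensor")))
    stop("'tensors' must be one or more diffusion_tensor objects")
  if (is.null(layout)) layout <- array(1L, c(1L, 1L, 1L))
  layout <- array(as.integer(layout), dim = dim(layout))
  if (length(dim(layout)) != 3L) stop("'layout' must be a 3-D index array")
  if (max(layout) > length(tensors) || min(layout) < 0L)
    stop("'layout' indexes outside the tensor list")
  if (b <= 0) stop("'b' must be positive")
  if (noise_sigma < 0) stop("'noise_sigma' must be non-negative")
  directions <- rbind(directions)
  ndir <- nrow(directions)

  # attenuation per tensor population x direction
  att <- vapply(tensors, function(tn) exp(-b * tensor_adc(tn, directions)),
                numeric(ndir))
  att <- matrix(att, nrow = ndir)

  d3 <- dim(layout)
  nvox <- prod(d3)
  idx <- as.vector(layout)
  S <- matrix(0, nvox, ndir + n_b0)
  fg <- idx > 0L
  S[fg, seq_len(n_b0)] <- s0
  if (any(fg))
    S[fg, n_b0 + seq_len(ndir)] <- s0 * t(att[, idx[fg], drop = FALSE])

  if (noise_sigma > 0) {
    runner <- function() {
      re <- S + stats::rnorm(length(S), 0, noise_sigma)
      im <- matrix(stats::rnorm(length(S), 0, noise_sigma), nrow(S))
      sqrt(re^2 + im^2)
    }
    S <- if (is.null(seed)) runner() else withr::with_seed(seed, runner())
  }

  tab <- gradient_table(c(rep(0, n_b0), rep(b, ndir)),
                        rbind(matrix(0, n_b0, 3L), directions))
  dwi_volume(array(S, c(d3, ndir + n_b0)), affine = diag(4), table = tab)
}

#' Uniformly distributed random rotation matrix
#'
#' Haar-uniform proper rotation, drawn by QR-orthogonalizing a Gaussian
#' matrix with the sign correction that makes the distribution uniform.
#'
#' @param seed Optional seed applied locally.
#' @return A proper 3 x 3 rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  draw <- function() {
    qr_ <- qr(matrix(stats::rnorm(9), 3L, 3L))
    Q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Multi-population phantom of randomly oriented tensors
#'
#' Builds the synthetic stand-in for white-matter tissue used by the
#' angular-resolution study: several tensor populations of graded
#' anisotropy, each voxel holding a prolate tensor with eigenvalues
#' (1, r, r) x 1e-3 mm\eqn{^2}/s at an independent, uniformly random
#' orientation — fiber bundles take arbitrary orientations in tissue, and
#' it is exactly this orientation spread that drives the underestimation of
#' DiA at low direction counts. The default ratios give dense-sampling DiA
#' levels spanning roughly 0.13 to 0.37, all above the usual DiA >= 0.1
#' white-matter mask.
#'
#' @param ratios Radial-to-axial eigenvalue ratio per population
#'   (decreasing ratio = increasing anisotropy).
#' @param voxels_per Voxels per population (default 400).
#' @param directions Gradient scheme (default 64-direction Fibonacci set).
#' @param b,s0,noise_sigma,n_b0 Forwarded to [synthesize_phantom()].
#' @param seed Seed for the per-voxel orientations (and noise, if any).
#' @return A [dwi_volume()] with attribute `population` (3-D integer array
#'   of ground-truth population labels, 1 = least anisotropic).
#' @export
population_phantom <- function(ratios = c(0.30, 0.25, 0.20, 0.15, 0.10, 0.05),
                               voxels_per = 400,
                               directions = fibonacci_directions(64),
                               b = 1000, s0 = 1000, noise_sigma = 0,
                               n_b0 = 1L, seed = 1L) {
  npop <- length(ratios)
  tensors <- withr::with_seed(seed, {
    unlist(lapply(ratios, function(r) {
      lapply(seq_len(voxels_per), function(i)
        make_tensor(c(1, r, r) * 1e-3, random_rotation()))
    }), recursive = FALSE)
  })
  dims <- c(voxels_per, npop, 1L)
  layout <- array(seq_along(tensors), dims)
  phantom <- synthesize_phantom(tensors, layout = layout,
                                directions = directions, b = b, s0 = s0,
                                noise_sigma = noise_sigma, n_b0 = n_b0,
                                seed = seed + 1L)
  attr(phantom, "population") <- array(rep(seq_len(npop), each = voxels_per), dims)
  phantom
}
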