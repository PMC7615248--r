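#' Rotation sweep of the DiA estimator
#'
#' Rotates a ground-truth tensor through a grid of angles under the plane
#' and/or spatial rotation scheme, samples its ADC on each gradient scheme,
#' and records the estimated DiA. With 3 axis-aligned directions the DiA is
#' strongly orientation-dependent (90-degree periodic under plane rotation,
#' minimal at 45 degrees where the principal axis is diagonal to the
#' acquisition axes); with the icosahedral 6-direction scheme the value is
#' orientation-independent.
#'
#' @param eigenvalues Tensor eigenvalues (mm\eqn{^2}/s).
#' @param n_directions Integer vector of scheme sizes (see
#'   [direction_scheme()]); default 3:6.
#' @param thetas Angle grid in radians (default 0 to 2 pi in 1-degree steps).
#' @param rotation_schemes Subset of `c("plane", "spatial")`.
#' @param lambda Laplace–Beltrami penalty for the SH estimator.
#' @return Data frame with columns `n_directions`, `scheme`,
#'   `rotation_scheme`, `theta`, `theta_deg`, `dia`.
#' @export
rotation_sweep <- function(eigenvalues = c(1, 0.3, 0.3) * 1e-3,
                           n_directions = 3:6,
                           thetas = seq(0, 2 * pi, by = pi / 180),
                           rotation_schemes = c("plane", "spatial"),
                           lambda = 0.006) {
  rotation_schemes <- match.arg(rotation_schemes, several.ok = TRUE)
  tensor <- make_tensor(eigenvalues)
  out <- list()
  for (n in n_directions) {
    dirs <- direction_scheme(n)
    # the C00 functional is fixed per scheme; precompute it once
    a <- .c00_functional(dirs, sh_order_for(nrow(dirs)), lambda)
    for (rs in rotation_schemes) {
      dia <- vapply(thetas, function(th) {
        Tr <- rotate_tensor(tensor, rotation_matrix(rs, th))
        d <- tensor_adc(Tr, dirs)
        c1 <- sum(a * d); c2 <- sum(a * d^2)
        if (c2 <= 0) 0 else max(0, 1 - c1^2 / (sqrt(4 * pi) * c2))
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        n_directions = nrow(dirs), scheme = attr(dirs, "name"),
        rotation_scheme = rs, theta = thetas,
        theta_deg = round(thetas * 180 / pi, 9), dia = dia)
    }
  }
  do.call(rbind, out)
}

#' Downsample a gradient scheme by angular uniformity
#'
#' Greedy farthest-point subset selection under the antipodal angular
#' metric: starting from the first direction, each step adds the candidate
#' maximizing its minimum angle (identifying u with -u) to the directions
#' already chosen. Deterministic given the input order, and close to the
#' electrostatic-repulsion subsets used to downsample acquisition shells.
#'
#' @param directions N x 3 matrix of unit vectors.
#' @param n_target Subset size, 3 <= n_target <= N.
#' @return `n_target` x 3 matrix with attribute `indices` (rows selected).
#' @export
downsample_directions <- function(directions, n_target) {
  directions <- rbind(directions)
  n <- nrow(directions)
  if (n_target < 3L) stop("'n_target' must be at least 3")
  if (n_target > n) stop(sprintf("cannot select %d of %d directions", n_target, n))
  if (n_target == n) {
    out <- directions
    attr(out, "indices") <- seq_len(n)
    return(out)
  }
  # pairwise antipodal angles
  G <- abs(tcrossprod(directions))
  ang <- acos(pmin(G, 1))
  chosen <- 1L
  mind <- ang[1L, ]
  while (length(chosen) < n_target) {
    mind[chosen] <- -Inf
    nxt <- which.max(mind)
    chosen <- c(chosen, nxt)
    mind <- pmin(mind, ang[nxt, ])
  }
  out <- directions[chosen, , drop = FALSE]
  attr(out, "indices") <- chosen
  out
}

#' Angular-resolution consistency of DiA
#'
#' Quantifies how the DiA of a dense single-shell acquisition degrades as
#' the gradient scheme is uniformly downsampled. The reference DiA is
#' computed on the full scheme, voxels below `dia_min` are removed, the
#' survivors are clustered on their reference DiA by 1-D k-means (k groups
#' of increasing anisotropy), and the per-cluster median DiA is then
#' recomputed for each downsampled direction count. On tissue whose fibers
#' take arbitrary orientations, the medians shrink as the direction count
#' drops — the underestimation is strongest at 3 directions — while the
#' ordering of the clusters is preserved.
#'
#' k-means runs on 1-D data initialized at evenly spaced quantiles of the
#' reference DiA, which makes the clustering deterministic.
#'
#' @param phantom A [dwi_volume()] with a dense scheme (>= max of `n_list`).
#' @param n_list Direction counts to evaluate (default c(3, 6, 15, 24, 35, 48)).
#' @param k Number of clusters (default 6).
#' @param dia_min Mask threshold on the reference DiA (default 0.1).
#' @param lambda Laplace–Beltrami penalty.
#' @param mask Optional 3-D logical mask forwarded to [normalize_dwi()].
#' @return List of class `angular_consistency`: `centroids` (ascending),
#'   `medians` (data frame cluster x n_directions), `reference_n`,
#'   `assignment` (cluster index per surviving voxel), `dia_reference`.
#' @export
angular_consistency <- function(phantom, n_list = c(3, 6, 15, 24, 35, 48),
                                k = 6, dia_min = 0.1, lambda = 0.006,
                                mask = NULL) {
  stopifnot(inherits(phantom, "dwi_volume"))
  adc <- compute_adc(normalize_dwi(phantom, mask = mask))
  dirs <- adc$directions
  nfull <- nrow(dirs)
  if (any(n_list > nfull))
    stop("n_list exceeds the number of acquired directions")
  d3 <- dim(adc$D)[1:3]
  S <- matrix(adc$D, nrow = prod(d3), ncol = nfull)

  dia_for <- function(sub) {
    a <- .c00_functional(sub, sh_order_for(nrow(sub)), lambda)
    Ssub <- S[, attr(sub, "indices"), drop = FALSE]
    c1 <- drop(Ssub %*% a); c2 <- drop(Ssub^2 %*% a)
    v <- 1 - c1^2 / (sqrt(4 * pi) * c2)
    v[c2 <= 0] <- 0
    pmin(pmax(v, 0), 1)
  }

  full <- downsample_directions(dirs, nfull)
  ref <- dia_for(full)
  keep <- as.vector(adc$mask) & ref >= dia_min
  if (sum(keep) < k)
    stop(sprintf("only %d voxel(s) survive the DiA >= %g mask; need at least k = %d",
                 sum(keep), dia_min, k))
  refk <- ref[keep]
  centers <- stats::quantile(refk, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  centers <- matrix(sort(unique(centers)), ncol = 1)
  if (nrow(centers) < k)
    stop("reference DiA has too few distinct levels for k clusters")
  km <- stats::kmeans(matrix(refk, ncol = 1), centers = centers, iter.max = 100)
  ord <- order(km$centers[, 1])
  relabel <- match(seq_len(k), ord)
  assignment <- relabel[km$cluster]
  centroids <- sort(km$centers[, 1])

  med <- expand.grid(cluster = seq_len(k), n_directions = sort(n_list))
  med$median_dia <- NA_real_
  for (n in sort(unique(n_list))) {
    sub <- downsample_directions(dirs, n)
    v <- dia_for(sub)[keep]
    for (cl in seq_len(k))
      med$median_dia[med$cluster == cl & med$n_directions == n] <-
        stats::median(v[assignment == cl])
  }
  structure(list(centroids = centroids, medians = med, reference_n = nfull,
                 assignment = assignment, dia_reference = refk),
            class = "angular_consistency")
}

#' @export
print.angular_consistency <- function(x, ...) {
  cat(sprintf("Angular consistency: %d clusters, reference %d directions\n",
              length(x$centroids), x$reference_n))
  cat("  centroids:", paste(format(x$centroids, digits = 3), collapse = ", "), "\n")
  print(stats::xtabs(median_dia ~ cluster + n_directions, data = x$medians))
  invisible(x)
}

#' Orientation variability of 3-direction DiA
#'
#' For each ground-truth tensor, enumerates 3-direction subsets of a dense
#' scheme and summarizes the spread of the 3-sample DiA across subset
#' orientations against the tensor's FA. The default `"orthogonal"` rule
#' keeps triplets whose pairwise (antipodal) angles are all within
#' `tol_deg` of 90 degrees — the configurations a fast orthogonal protocol
#' could have acquired; `"all"` enumerates every triplet (optionally capped
#' by a seeded subsample).
#'
#' @param tensors A `diffusion_tensor` or list of them.
#' @param directions Dense scheme to draw triplets from (>= 16 directions).
#' @param triplet_rule `"orthogonal"` or `"all"`.
#' @param tol_deg Orthogonality tolerance in degrees (default 15).
#' @param max_triplets Cap on enumerated triplets for `"all"` (default 5000).
#' @param seed Seed for the capped subsample.
#' @return Data frame with one row per tensor: `fa`, `median_dia`, `sd_dia`,
#'   `min_dia`, `max_dia`, `n_triplets`. The per-triplet DiA uses the
#'   degree-0 estimator, which for any 3 directions equals the simplified
#'   closed form.
#' @export
orientation_variability <- function(tensors, directions = fibonacci_directions(64),
                                    triplet_rule = c("orthogonal", "all"),
                                    tol_deg = 15, max_triplets = 5000,
                                    seed = NULL) {
  triplet_rule <- match.arg(triplet_rule)
  if (inherits(tensors, "diffusion_tensor")) tensors <- list(tensors)
  directions <- rbind(directions)
  n <- nrow(directions)
  if (n < 16L) stop("need a dense scheme of at least 16 directions")

  trips <- utils::combn(n, 3L)
  if (triplet_rule == "orthogonal") {
    G <- abs(tcrossprod(directions))
    ok <- apply(trips, 2, function(ix) {
      a <- acos(pmin(c(G[ix[1], ix[2]], G[ix[1], ix[3]], G[ix[2], ix[3]]), 1)) * 180 / pi
      all(abs(a - 90) <= tol_deg)
    })
    if (!any(ok))
      stop("no near-orthogonal triplet found; increase 'tol_deg'")
    trips <- trips[, ok, drop = FALSE]
  } else if (ncol(trips) > max_triplets) {
    pick <- function() sample.int(ncol(trips), max_triplets)
    ix <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
    trips <- trips[, sort(ix), drop = FALSE]
  }

  rows <- lapply(tensors, function(tn) {
    D <- tensor_adc(tn, directions)
    dia <- apply(trips, 2, function(ix) {
      d <- D[ix]
      s <- sum(d^2)
      if (s == 0) 0 else max(0, 1 - sum(d)^2 / (3 * s))
    })
    data.frame(fa = tensor_fa(tn), median_dia = stats::median(dia),
               sd_dia = stats::sd(dia), min_dia = min(dia), max_dia = max(dia),
               n_triplets = ncol(trips))
  })
  do.call(rbind, rows)
}
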