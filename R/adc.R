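#' Normalize a DWI series against its baseline
#'
#' Divides each diffusion-weighted volume by the baseline signal S0 to obtain
#' the normalized attenuation E = S/S0 of the mono-exponential model
#' E(u) = exp(-b D(u)). Noise can push S above S0; such values are clamped to
#' 1 (giving D = 0 downstream), and values at or below `epsilon` are clamped
#' to `epsilon` so the log stays finite.
#'
#' The foreground mask defaults to Otsu thresholding of S0 (all voxels when
#' S0 is constant); a user mask overrides it. Voxels where S0 = 0 cannot be
#' normalized and are dropped from the mask with a reported count.
#'
#' @param dwi A [dwi_volume()] with at least one b0 volume.
#' @param b0_policy How to combine multiple b0 volumes into S0:
#'   `"mean"` (default), `"median"` or `"first"`.
#' @param mask Optional 3-D logical array overriding the Otsu mask.
#' @param epsilon Lower clamp for E (default 1e-8).
#' @return An object of class `normalized_signal`: list with `E` (4-D array,
#'   one volume per non-b0 direction, clamped into (0, 1\]), `mask` (3-D
#'   logical), `clamped_high` (4-D logical marking E clamped to 1),
#'   `directions` (unit vectors of the retained volumes), `b` (shell
#'   b-value) and `affine`.
#' @export
normalize_dwi <- function(dwi, b0_policy = c("mean", "median", "first"),
                          mask = NULL, epsilon = 1e-8) {
  stopifnot(inherits(dwi, "dwi_volume"))
  b0_policy <- match.arg(b0_policy)
  tab <- dwi$table
  if (!any(tab$b0)) stop("no b0 volume found (all b-values above b0_tolerance)")
  if (sum(!tab$b0) < 3L)
    stop(sprintf("need at least 3 diffusion-weighted volumes, found %d", sum(!tab$b0)))
  d <- dim(dwi$data)
  b0_idx <- which(tab$b0)
  s0 <- switch(b0_policy,
    mean   = .vol4_reduce(dwi$data, b0_idx, rowMeans),
    median = .vol4_reduce(dwi$data, b0_idx, function(m) apply(m, 1, stats::median)),
    first  = dwi$data[, , , b0_idx[1], drop = TRUE]
  )
  s0 <- array(s0, dim = d[1:3])

  if (is.null(mask)) {
    mask <- .otsu_mask(s0)
  } else {
    mask <- array(as.logical(mask), dim = d[1:3])
  }
  zero_s0 <- mask & (s0 <= 0)
  if (any(zero_s0)) {
    message(sprintf("normalize_dwi: excluded %d voxel(s) with S0 = 0 from the mask",
                    sum(zero_s0)))
    mask <- mask & !zero_s0
  }

  dw_idx <- which(!tab$b0)
  b_shell <- tab$bvals[dw_idx]
  if (diff(range(b_shell)) > 0.05 * mean(b_shell))
    warning("non-b0 b-values span more than one shell; treating them as one shell at their mean")

  E <- dwi$data[, , , dw_idx, drop = FALSE]
  s0_safe <- ifelse(s0 > 0, s0, 1)
  E <- sweep(E, 1:3, s0_safe, "/")
  clamped_high <- E >= 1
  E <- pmin(pmax(E, epsilon), 1)

  structure(list(E = E, mask = mask, clamped_high = clamped_high,
                 directions = tab$bvecs[dw_idx, , drop = FALSE],
                 b = mean(b_shell), s0 = s0, affine = dwi$affine),
            class = "normalized_signal")
}

.vol4_reduce <- function(data, idx, fn) {
  d <- dim(data)
  m <- matrix(data[, , , idx, drop = FALSE], nrow = prod(d[1:3]))
  fn(m)
}

# Otsu threshold of the baseline image; degenerate (constant) images are
# treated as all-foreground so synthetic phantoms without background pass
# through unmasked.
.otsu_mask <- function(s0) {
  rng <- range(s0)
  if (diff(rng) <= 0 || !all(is.finite(rng)))
    return(array(TRUE, dim = dim(s0)))
  thr <- EBImage::otsu(s0, range = rng)
  s0 > thr
}

#' Per-direction apparent diffusion coefficients
#'
#' Inverts the mono-exponential signal model: D(u) = -ln(E(u)) / b, one
#' diffusivity volume per diffusion-encoding direction. Where E was clamped
#' to 1 (signal at or above baseline), D is exactly 0.
#'
#' @param ns A `normalized_signal` from [normalize_dwi()].
#' @param b Shell b-value in s/mm\eqn{^2}; defaults to the value carried by
#'   `ns`. Must be positive.
#' @return An object of class `adc_map`: list with `D` (4-D array, mm\eqn{^2}/s),
#'   `directions`, `b`, `mask` and `affine`.
#' @export
compute_adc <- function(ns, b = NULL) {
  stopifnot(inherits(ns, "normalized_signal"))
  if (is.null(b)) b <- ns$b
  if (!is.numeric(b) || length(b) != 1L || b <= 0)
    stop("'b' must be a single positive b-value (s/mm^2)")
  D <- -log(ns$E) / b
  D[ns$clamped_high] <- 0
  structure(list(D = D, directions = ns$directions, b = b,
                 mask = ns$mask, affine = ns$affine),
            class = "adc_map")
}
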