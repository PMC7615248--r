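#' Construct a gradient table
#'
#' A gradient table pairs a per-volume b-value (s/mm\eqn{^2}) with a unit
#' diffusion-encoding direction. Volumes with b-value at or below
#' `b0_tolerance` are flagged as baseline (b0) volumes; their direction may be
#' the zero vector. All other directions are renormalized to unit length.
#'
#' Directions are interpreted in the image coordinate frame (the FSL bvec
#' convention), not the scanner/world frame. The RGB orientation code produced
#' downstream therefore refers to image axes; see [color_code()].
#'
#' @param bvals Numeric vector of b-values, one per volume (s/mm\eqn{^2}).
#' @param bvecs Numeric matrix with one row per volume and 3 columns.
#' @param b0_tolerance b-value at or below which a volume counts as b0.
#'   Default 50 s/mm\eqn{^2}, a common community choice that also covers
#'   tables where the baseline is written as exactly 0.
#' @return An object of class `gradient_table`: a list with elements `bvals`,
#'   `bvecs` (N x 3, unit rows for non-b0 entries), `b0` (logical) and
#'   `b0_tolerance`.
#' @seealso [read_gradient_table()] to read FSL-style bval/bvec files.
#' @export
gradient_table <- function(bvals, bvecs, b0_tolerance = 50) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L)
    stop("'bvecs' must have 3 columns (one unit direction per row)")
  if (length(bvals) != nrow(bvecs))
    stop(sprintf("gradient table length mismatch: %d b-values but %d directions",
                 length(bvals), nrow(bvecs)))
  if (anyNA(bvals) || anyNA(bvecs))
    stop("gradient table contains missing values")
  if (any(bvals < 0))
    stop("negative b-values are not meaningful")
  b0 <- bvals <= b0_tolerance
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(!b0 & nrm < 1e-12))
    stop("zero direction vector on a diffusion-weighted (non-b0) volume")
  scale <- ifelse(nrm < 1e-12, 1, nrm)
  bvecs <- bvecs / scale
  bvecs[b0 & nrm < 1e-12, ] <- 0
  structure(
    list(bvals = bvals, bvecs = unname(bvecs), b0 = b0,
         b0_tolerance = b0_tolerance),
    class = "gradient_table"
  )
}

#' @export
print.gradient_table <- function(x, ...) {
  cat(sprintf("Gradient table: %d volumes (%d b0, %d diffusion-weighted)\n",
              length(x$bvals), sum(x$b0), sum(!x$b0)))
  if (any(!x$b0))
    cat(sprintf("  shell b-values: %s s/mm^2\n",
                paste(unique(round(x$bvals[!x$b0])), collapse = ", ")))
  invisible(x)
}

#' Number of volumes in a gradient table
#' @param x A `gradient_table`.
#' @export
length.gradient_table <- function(x) length(x$bvals)

.read_numeric_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[[i]]), "[ \t,]+")[[1]]
    val <- suppressWarnings(as.numeric(tok))
    if (anyNA(val)) {
      bad <- tok[is.na(val)][1]
      stop(sprintf("non-numeric token '%s' on line %d of %s", bad, i, path))
    }
    val
  })
  rows
}

#' Read an FSL-style bval/bvec gradient table
#'
#' Reads whitespace-separated b-value and direction files as written by most
#' diffusion pipelines. The bvec layout is auto-detected: both the FSL 3-row
#' (3 x N) and the transposed N x 3 dialect are accepted; when the table has
#' exactly 3 volumes and both layouts are plausible, the FSL 3-row convention
#' is assumed.
#'
#' @inheritParams gradient_table
#' @param bval_path,bvec_path Paths to the text files.
#' @return A [gradient_table()].
#' @export
read_gradient_table <- function(bval_path, bvec_path, b0_tolerance = 50) {
  if (!file.exists(bval_path)) stop("bval file not found: ", bval_path)
  if (!file.exists(bvec_path)) stop("bvec file not found: ", bvec_path)
  bvals <- unlist(.read_numeric_table(bval_path))
  rows <- .read_numeric_table(bvec_path)
  nper <- lengths(rows)
  if (length(unique(nper)) != 1L)
    stop("ragged bvec file: rows of differing length in ", bvec_path)
  M <- do.call(rbind, rows)
  # layout auto-detection; FSL writes 3 rows x N columns
  if (nrow(M) == 3L) {
    bvecs <- t(M)
  } else if (ncol(M) == 3L) {
    bvecs <- M
  } else {
    stop(sprintf("bvec file is %d x %d; expected 3 x N or N x 3", nrow(M), ncol(M)))
  }
  if (length(bvals) != nrow(bvecs))
    stop(sprintf("length mismatch: %d b-values in %s but %d directions in %s",
                 length(bvals), bval_path, nrow(bvecs), bvec_path))
  gradient_table(bvals, bvecs, b0_tolerance)
}

#' Write a gradient table as FSL bval/bvec files
#'
#' @param table A [gradient_table()].
#' @param bval_path,bvec_path Output paths. bvecs are written in the FSL
#'   3-row layout.
#' @return Invisibly, the two paths.
#' @export
write_gradient_table <- function(table, bval_path, bvec_path) {
  stopifnot(inherits(table, "gradient_table"))
  writeLines(paste(format(table$bvals, trim = TRUE), collapse = " "), bval_path)
  tx <- t(table$bvecs)
  writeLines(apply(tx, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Construct a diffusion-weighted volume
#'
#' @param data 4-D numeric array of signal intensities (scanner units).
#' @param affine 4 x 4 voxel-to-world transform.
#' @param table [gradient_table()] whose length matches the 4th dimension.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, affine = diag(4), table) {
  data <- unclass(data)
  attributes(data) <- list(dim = dim(data))
  if (length(dim(data)) != 4L)
    stop("'data' must be a 4-D array (x, y, z, volume)")
  if (any(dim(data)[1:3] < 1L)) stop("spatial dimensions must all be >= 1")
  stopifnot(inherits(table, "gradient_table"))
  if (dim(data)[4] != length(table))
    stop(sprintf("4th dimension (%d volumes) does not match gradient table (%d entries)",
                 dim(data)[4], length(table)))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("'affine' must be an invertible 4 x 4 matrix")
  structure(list(data = data, affine = affine, table = table),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DWI volume: %d x %d x %d voxels, %d volumes\n", d[1], d[2], d[3], d[4]))
  print(x$table)
  invisible(x)
}

#' Read a 4-D diffusion-weighted NIfTI volume
#'
#' @param nifti_path Path to a 4-D NIfTI-1 file (.nii or .nii.gz).
#' @param table The matching [gradient_table()].
#' @return A [dwi_volume()] carrying the data, the NIfTI affine and the table.
#' @export
read_dwi <- function(nifti_path, table) {
  img <- RNifti::readNifti(nifti_path)
  d <- dim(img)
  if (length(d) == 3L)
    stop("3-D NIfTI given; a 4-D diffusion series is required ",
         "(for a single volume, add a 4th dimension of length 1)")
  if (length(d) != 4L)
    stop(sprintf("expected a 4-D NIfTI, got %d dimensions", length(d)))
  if (d[4] != length(table))
    stop(sprintf("NIfTI has %d volumes but gradient table has %d entries",
                 d[4], length(table)))
  dwi_volume(array(as.numeric(img), dim = d), affine = unclass(RNifti::xform(img)),
             table = table)
}

#' Write a scalar or RGB map as NIfTI
#'
#' Scalar (3-D) maps are written as float32. RGB maps (4-D with last dimension
#' 3) are stored as float values clipped into \[0, 1\] — lossless and portable
#' across viewers, unlike packed 24-bit triples.
#'
#' @param volume 3-D numeric array, or 4-D with last dimension 3 for RGB.
#' @param affine 4 x 4 voxel-to-world transform to carry into the header.
#' @param out_path Output path (.nii or .nii.gz).
#' @param allow_nan If `TRUE`, non-finite voxels are mapped to 0 and their
#'   count reported; otherwise any non-finite value is an error.
#' @return Invisibly, `out_path`.
#' @export
write_map <- function(volume, affine, out_path, allow_nan = FALSE) {
  volume <- unclass(volume)
  nd <- length(dim(volume))
  if (!nd %in% c(3L, 4L))
    stop("'volume' must be a 3-D scalar map or a 4-D RGB map")
  if (nd == 4L && dim(volume)[4] != 3L)
    stop("4-D maps must have last dimension 3 (RGB)")
  bad <- !is.finite(volume)
  if (any(bad)) {
    if (!allow_nan)
      stop(sprintf("map contains %d non-finite voxel value(s); use allow_nan = TRUE to zero them",
                   sum(bad)))
    message(sprintf("write_map: zeroed %d non-finite voxel value(s)", sum(bad)))
    volume[bad] <- 0
  }
  if (nd == 4L) volume <- pmin(pmax(volume, 0), 1)
  img <- RNifti::asNifti(volume)
  affine <- structure(as.matrix(affine), code = 2L)
  RNifti::qform(img) <- affine
  RNifti::sform(img) <- affine
  RNifti::writeNifti(img, out_path, datatype = "float")
  invisible(out_path)
}

#' Write a DWI volume plus its gradient table
#'
#' Convenience writer pairing [write_map()]-style NIfTI output with FSL
#' bval/bvec files, producing `<prefix>.nii.gz`, `<prefix>.bval`,
#' `<prefix>.bvec`.
#'
#' @param dwi A [dwi_volume()].
#' @param prefix Output path prefix.
#' @return Invisibly, the three paths written.
#' @export
write_dwi <- function(dwi, prefix) {
  stopifnot(inherits(dwi, "dwi_volume"))
  nii <- paste0(prefix, ".nii.gz")
  img <- RNifti::asNifti(dwi$data)
  affine <- structure(dwi$affine, code = 2L)
  RNifti::qform(img) <- affine
  RNifti::sform(img) <- affine
  RNifti::writeNifti(img, nii, datatype = "float")
  write_gradient_table(dwi$table, paste0(prefix, ".bval"), paste0(prefix, ".bvec"))
  invisible(c(nii, paste0(prefix, ".bval"), paste0(prefix, ".bvec")))
}
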