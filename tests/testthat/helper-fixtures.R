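# shared fixtures: the reference prolate tensor and small phantom builders

ref_eigenvalues <- c(1, 0.3, 0.3) * 1e-3   # mm^2/s, FA 0.6444
ref_tensor <- function() make_tensor(ref_eigenvalues)

# closed-form DiA of a tensor: 1 - 5 (tr T)^2 / (3 ((tr T)^2 + 2 tr(T^2)))
dia_closed_form <- function(tensor) {
  M <- tensor$matrix
  trT <- sum(diag(M))
  trT2 <- sum(M^2)
  1 - 5 * trT^2 / (3 * (trT^2 + 2 * trT2))
}

# Haar-ish random rotation for property loops (seeded by the caller)
rand_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# random orthonormal triad (rows of a random rotation)
rand_triad <- function() t(rand_rotation())

# small uniform phantom of one tensor on the 3-axis scheme
axes_phantom <- function(tensor = ref_tensor(), dims = c(4, 4, 4), ...) {
  synthesize_phantom(tensor, layout = array(1L, dims),
                     directions = direction_scheme("axes"), ...)
}
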