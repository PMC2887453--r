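#' Normal (relaxation) modes of the linearized dynamics
#'
#' Diagonalizes the linearization matrix of the gradient flow at the reference
#' state. In overdamped dynamics each eigenvector decays exponentially with
#' rate equal to its eigenvalue, so the spectrum is a set of inverse decay
#' times: the slowest nonzero mode ("soft mode") dominates late-time linear
#' relaxation. Six eigenvalues vanish for a generic connected 3-D network,
#' corresponding to free translations and rotations.
#'
#' @param H Symmetric 3N x 3N matrix from [enm_hessian()].
#' @param zero_tol Relative threshold below which an eigenvalue counts as
#'   zero, as a fraction of the largest eigenvalue (default 1e-8).
#' @return An object of class `mode_spectrum`: list with `values` (ascending
#'   eigenvalues), `vectors` (orthonormal columns, matching order), `n_zero`,
#'   and `zero_tol`. Eigenvector signs are fixed so the first component larger
#'   than 1e-6 in absolute value is positive.
#' @export
compute_modes <- function(H, zero_tol = 1e-8) {
  if (max(abs(H - t(H))) > 1e-10) stop("matrix is not symmetric")
  eig <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(eig$values)
  values <- eig$values[ord]
  vectors <- eig$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(vectors))) {
    lead <- which(abs(vectors[, k]) > 1e-6)[1L]
    if (!is.na(lead) && vectors[lead, k] < 0) vectors[, k] <- -vectors[, k]
  }
  spec <- structure(
    list(values = values, vectors = vectors, zero_tol = zero_tol),
    class = "mode_spectrum"
  )
  spec$n_zero <- count_zero_modes(spec, zero_tol)
  spec
}

#' @export
print.mode_spectrum <- function(x, ...) {
  nz <- x$values[x$values >= x$zero_tol * max(x$values)]
  cat("Mode spectrum:", length(x$values), "modes,", x$n_zero, "zero;",
      "lambda_1 =", signif(nz[1L], 5),
      "gap lambda_2/lambda_1 =", signif(nz[2L] / nz[1L], 4), "\n")
  invisible(x)
}

#' Count numerically zero modes
#'
#' @param spec A `mode_spectrum`.
#' @param zero_tol Relative threshold (fraction of the largest eigenvalue).
#' @return Integer count; 6 for a connected, non-collinear 3-D network (rigid
#'   translations and rotations), more for disconnected or collinear ones.
#' @export
count_zero_modes <- function(spec, zero_tol = spec$zero_tol) {
  sum(spec$values < zero_tol * max(spec$values))
}

nonzero_mode_values <- function(spec) {
  spec$values[spec$values >= spec$zero_tol * max(spec$values)]
}

#' Analytic linear (superposition-of-modes) relaxation
#'
#' The general solution of the linearized dynamics: the initial deviation is
#' expanded over the eigenvectors and each amplitude decays as
#' exp(-lambda_alpha t). The component lying in the zero-mode subspace
#' (rigid motions) is projected out, since it neither decays nor costs energy.
#' Valid only inside the harmonic domain; outside it the nonlinear flow of
#' [relax()] departs from this superposition.
#'
#' @param spec A `mode_spectrum` of the network's Hessian.
#' @param net The `elastic_network` (supplies the reference state and energy).
#' @param deviation N x 3 matrix of initial displacements from the reference.
#' @param times Vector of times (must start at 0 or be positive).
#' @return A `relax_trajectory` whose frames are R0 + deviation(t).
#' @export
linear_mode_relaxation <- function(spec, net, deviation, times) {
  dev <- as.numeric(t(check_conformation(net, deviation)))  # per-particle xyz
  n <- net$n_particles
  # Hessian rows are ordered (x_1,y_1,z_1,...), matching t(R)
  nz <- spec$values >= spec$zero_tol * max(spec$values)
  V <- spec$vectors[, nz, drop = FALSE]
  lam <- spec$values[nz]
  c0 <- drop(crossprod(V, dev))
  frames <- lapply(times, function(t) {
    dr <- V %*% (c0 * exp(-lam * t))
    net$R0 + matrix(dr, n, 3L, byrow = TRUE)
  })
  energies <- vapply(frames, function(fr) elastic_energy(net, fr), numeric(1))
  new_trajectory(times, frames, energies, converged = TRUE, force_tol = NA_real_)
}

#' Direction of the soft mode in the label-distance plane
#'
#' First-order change of the two monitored label distances (l_AB, l_BC) under
#' a displacement along the slowest nonzero mode, normalized to a unit
#' 2-vector. This is the straight line along which purely exponential
#' soft-mode relaxation would proceed in the distance plane; as an undirected
#' line, both orientations are equivalent.
#'
#' @param spec A `mode_spectrum`.
#' @param net The `elastic_network`.
#' @param labels Integer vector `c(A, B, C)` of particle indices.
#' @return Unit 2-vector `(dl_AB, dl_BC)`. Warns when the spectral gap
#'   lambda_2/lambda_1 < 1.05 (soft mode nearly degenerate) and when both
#'   first-order changes vanish (degenerate direction).
#' @export
soft_mode_distance_direction <- function(spec, net, labels) {
  labels <- check_labels(net, labels)
  nzv <- nonzero_mode_values(spec)
  if (length(nzv) >= 2L && nzv[2L] / nzv[1L] < 1.05) {
    warning("soft mode nearly degenerate: lambda_2/lambda_1 = ",
            signif(nzv[2L] / nzv[1L], 4))
  }
  nz <- which(spec$values >= spec$zero_tol * max(spec$values))[1L]
  e1 <- matrix(spec$vectors[, nz], net$n_particles, 3L, byrow = TRUE)
  dldir <- function(i, j) {
    u <- net$R0[i, ] - net$R0[j, ]
    u <- u / sqrt(sum(u * u))
    sum(u * (e1[i, ] - e1[j, ]))
  }
  v <- c(dldir(labels[1L], labels[2L]), dldir(labels[2L], labels[3L]))
  nrm <- sqrt(sum(v * v))
  if (nrm < 1e-12) {
    warning("soft mode leaves both label distances unchanged at first order")
    return(c(0, 0))
  }
  v / nrm
}

#' Export a mode spectrum as a plain-text table
#'
#' @param spec A `mode_spectrum`.
#' @param file Output path.
#' @return Invisibly, the path. Columns: `alpha`, `lambda`,
#'   `lambda_over_lambda1` (normalized to the lowest nonzero eigenvalue).
#' @export
write_spectrum <- function(spec, file) {
  lam1 <- nonzero_mode_values(spec)[1L]
  tab <- data.frame(alpha = seq_along(spec$values), lambda = spec$values,
                    lambda_over_lambda1 = spec$values / lam1)
  utils::write.table(format(tab, digits = 10), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
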