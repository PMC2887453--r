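#' Random static forces of fixed modulus
#'
#' Draws one force vector per particle with an independent, uniformly random
#' direction on the sphere and modulus exactly `magnitude` — the constraint
#' |f_i| = f0 used when preparing strongly deformed initial conditions. The
#' generator is R's Mersenne-Twister; results are reproducible from `seed`.
#'
#' @param n_particles Number of particles.
#' @param magnitude Force modulus f0 (rescaled units).
#' @param seed Integer seed.
#' @return N x 3 matrix of forces, each row of Euclidean norm `magnitude`.
#' @export
random_static_force_set <- function(n_particles, magnitude, seed) {
  stopifnot(n_particles >= 1L, magnitude >= 0)
  set.seed(seed, kind = "Mersenne-Twister")
  g <- matrix(stats::rnorm(3L * n_particles), n_particles, 3L)
  nrm <- sqrt(rowSums(g * g))
  # a 3-D standard normal has essentially zero mass at the origin; regenerate
  while (any(nrm == 0)) {
    zero <- nrm == 0
    g[zero, ] <- stats::rnorm(3L * sum(zero))
    nrm <- sqrt(rowSums(g * g))
  }
  g / nrm * magnitude
}

#' Random displacement of a conformation with exact RMS amplitude
#'
#' Shifts every particle by an independent isotropic Gaussian offset, then
#' rescales the whole offset field so the realized root-mean-square
#' displacement over particles equals `rms` exactly. Used to probe the
#' robustness of a relaxation path against perturbations of its starting
#' conformation.
#'
#' @param conf N x 3 coordinate matrix.
#' @param rms Target RMS displacement a (Angstrom).
#' @param seed Integer seed.
#' @return Perturbed N x 3 conformation.
#' @export
random_rms_displacement <- function(conf, rms, seed) {
  stopifnot(rms >= 0)
  conf <- as.matrix(conf)
  if (rms == 0) return(conf)
  set.seed(seed, kind = "Mersenne-Twister")
  d <- matrix(stats::rnorm(length(conf)), nrow(conf), 3L)
  realized <- sqrt(mean(rowSums(d * d)))
  conf + d * (rms / realized)
}

#' Map an alternate crystallographic conformation onto a network
#'
#' Takes the coordinates of a second structure (e.g. the nucleotide-free state
#' when the network was built from the ATP-bound state) for exactly the
#' residues paired with the network's particles, ordered as the particles.
#' No superposition is applied: the dynamics is invariant under rigid
#' translations and rotations, so the raw coordinates are a valid start.
#'
#' @param net An `elastic_network` whose particles follow the A-side order of
#'   `pairing`.
#' @param other A `calpha_structure` holding the alternate conformation.
#' @param pairing A `residue_pairing` between the network's source structure
#'   and `other`; its A-side must cover every network particle.
#' @return N x 3 conformation matrix.
#' @export
conformation_as_initial_condition <- function(net, other, pairing) {
  if (nrow(pairing) != net$n_particles ||
      !identical(as.integer(pairing$index_a), seq_len(net$n_particles))) {
    stop("pairing does not cover all ", net$n_particles,
         " network particles exactly once")
  }
  coords(other)[pairing$index_b, , drop = FALSE]
}

#' Generate a bundle of force-prepared random initial conditions
#'
#' Applies the static-force protocol `n` times with per-replicate seeds
#' derived from `seed` (seed + replicate index), returning the deformed
#' conformations ready for relaxation runs.
#'
#' @param net An `elastic_network`.
#' @param n Number of initial conditions.
#' @param magnitude Force modulus f0.
#' @param duration Pulling time t0.
#' @param seed Base integer seed.
#' @param max_stretch Unfolding guard passed to
#'   [apply_static_forces_and_relax()].
#' @return List of `n` conformation matrices; each carries its seed as
#'   attribute `"seed"`.
#' @export
forced_initial_conditions <- function(net, n, magnitude, duration, seed,
                                      max_stretch = 2) {
  lapply(seq_len(n), function(k) {
    sk <- seed + k
    f <- random_static_force_set(net$n_particles, magnitude, seed = sk)
    conf <- apply_static_forces_and_relax(net, net$R0, f, duration,
                                          max_stretch = max_stretch)
    attr(conf, "seed") <- sk
    conf
  })
}
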