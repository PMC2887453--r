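#' Integrate the overdamped relaxation dynamics of an elastic network
#'
#' Solves the gradient flow dR_i/dt = F_i(R) (plus optional constant external
#' forces), where F_i are the elastic forces and time is measured in rescaled
#' units (stiffness and mobility absorbed). Without external forces the flow
#' strictly dissipates the elastic energy, dE/dt = -sum_i |dR_i/dt|^2, so the
#' recorded energies must be non-increasing; any increase beyond the
#' integrator tolerance is treated as divergence and raised as an error.
#'
#' Integration uses an adaptive, stiffness-switching solver (`deSolve`'s
#' `lsodar`) with a termination root at the point where the maximum particle
#' force drops below `force_tol` (the convergence criterion).
#'
#' @param net An `elastic_network`.
#' @param start N x 3 starting coordinates.
#' @param t_max Maximum integration time (rescaled units).
#' @param n_frames Number of recorded frames (default 120).
#' @param schedule `"log"` (default; frame times log-spaced between
#'   `t_max * 1e-4` and `t_max`, plus t = 0 — early dynamics is fast, the tail
#'   exponential) or `"linear"`.
#' @param ext_forces Optional N x 3 matrix of constant external forces.
#' @param force_tol Convergence threshold on the max-norm of total particle
#'   forces (default 1e-8, rescaled units).
#' @param rtol,atol Relative/absolute integrator tolerances.
#' @return An object of class `relax_trajectory`: list with `times`, `frames`
#'   (list of N x 3 matrices), `energies`, `converged` (logical), and
#'   `force_tol`.
#' @export
relax <- function(net, start, t_max, n_frames = 120L, schedule = c("log", "linear"),
                  ext_forces = NULL, force_tol = 1e-8, rtol = 1e-8, atol = 1e-10) {
  schedule <- match.arg(schedule)
  stopifnot(t_max > 0)
  R <- check_conformation(net, start)
  n <- net$n_particles
  field <- force_field(net)
  Fext <- if (is.null(ext_forces)) matrix(0, n, 3L) else check_conformation(net, ext_forces)

  total_force <- function(R) field(R) + Fext

  F0 <- total_force(R)
  if (max(abs(F0)) < force_tol) {
    traj <- new_trajectory(0, list(R), elastic_energy(net, R), TRUE, force_tol)
    return(traj)
  }

  times <- frame_times(t_max, n_frames, schedule)
  deriv <- function(t, y, parms) {
    list(as.numeric(total_force(matrix(y, n, 3L))))
  }
  root <- function(t, y, parms) {
    max(abs(total_force(matrix(y, n, 3L)))) - force_tol
  }
  out <- deSolve::lsodar(y = as.numeric(R), times = times, func = deriv,
                         parms = NULL, rootfunc = root, rtol = rtol, atol = atol,
                         maxsteps = 100000L)
  t_out <- out[, 1L]
  frames <- lapply(seq_len(nrow(out)), function(k) matrix(out[k, -1L], n, 3L))
  energies <- vapply(frames, function(fr) elastic_energy(net, fr), numeric(1))
  converged <- !is.null(attr(out, "troot")) ||
    max(abs(total_force(frames[[length(frames)]]))) < force_tol

  if (is.null(ext_forces)) {
    dE <- diff(energies)
    bad <- which(dE > atol + rtol * pmax(1, abs(energies[-length(energies)])))
    if (length(bad) > 0L) {
      stop("energy increased between recorded frames ", bad[1L], " and ",
           bad[1L] + 1L, " (t = ", signif(t_out[bad[1L] + 1L], 4), "): ",
           "integration diverged")
    }
  }
  new_trajectory(t_out, frames, energies, converged, force_tol)
}

new_trajectory <- function(times, frames, energies, converged, force_tol) {
  structure(list(times = times, frames = frames, energies = energies,
                 converged = converged, force_tol = force_tol),
            class = "relax_trajectory")
}

#' @export
print.relax_trajectory <- function(x, ...) {
  cat("Relaxation trajectory: ", length(x$times), " frames, t in [0, ",
      signif(max(x$times), 4), "], E ", signif(x$energies[1L], 4), " -> ",
      signif(x$energies[length(x$energies)], 4),
      if (x$converged) " (converged)\n" else " (not converged)\n", sep = "")
  invisible(x)
}

frame_times <- function(t_max, n_frames, schedule) {
  if (schedule == "linear") return(seq(0, t_max, length.out = n_frames))
  # floor six decades below t_max so the stiff early transient is resolved
  c(0, 10^seq(log10(t_max * 1e-6), log10(t_max), length.out = n_frames - 1L))
}

#' Prepare a random initial condition by forced relaxation
#'
#' Integrates the dynamics in the presence of constant static forces for a
#' fixed time and returns the conformation reached — the protocol used to
#' generate strongly deformed but unfolded starting states. A guard rejects
#' preparations in which any link exceeds `max_stretch` times its natural
#' length (unfolding).
#'
#' @inheritParams relax
#' @param forces N x 3 matrix of static forces held constant during the pull.
#' @param duration Pulling time t0 (rescaled units).
#' @param max_stretch Maximum allowed link stretch factor (default 2).
#' @return N x 3 conformation matrix.
#' @export
apply_static_forces_and_relax <- function(net, start, forces, duration,
                                          max_stretch = 2, rtol = 1e-8,
                                          atol = 1e-10) {
  stopifnot(duration > 0)
  R <- check_conformation(net, start)
  Fext <- check_conformation(net, forces)
  if (any(!is.finite(Fext))) stop("non-finite external forces")
  n <- net$n_particles
  field <- force_field(net)
  deriv <- function(t, y, parms) {
    list(as.numeric(field(matrix(y, n, 3L)) + Fext))
  }
  out <- deSolve::lsoda(y = as.numeric(R), times = c(0, duration), func = deriv,
                        parms = NULL, rtol = rtol, atol = atol,
                        maxsteps = 100000L)
  Rend <- matrix(out[nrow(out), -1L], n, 3L)
  stretch <- link_lengths(net, Rend) / net$d0
  if (max(stretch) > max_stretch) {
    stop("forced preparation unfolded the network: max link stretch ",
         signif(max(stretch), 4), " exceeds ", max_stretch)
  }
  Rend
}

#' Kabsch-superposed RMSD between two conformations
#'
#' Root-mean-square deviation after optimal rigid-body (proper rotation +
#' translation) superposition; mirror reflections are excluded, so enantiomeric
#' conformations have a strictly positive RMSD.
#'
#' @param a,b N x 3 coordinate matrices.
#' @return RMSD in Angstrom.
#' @export
superposed_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(identical(dim(a), dim(b)))
  ac <- sweep(a, 2L, colMeans(a))
  bc <- sweep(b, 2L, colMeans(b))
  sv <- svd(crossprod(ac, bc))
  d <- sign(det(sv$u) * det(sv$v))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  sqrt(mean(rowSums((ac %*% rot - bc)^2)))
}

#' Classify where a relaxation trajectory ended
#'
#' A trajectory ends at the `"reference"` state when its final frame lies
#' within `rmsd_tol` (after rigid superposition) of the network's equilibrium
#' coordinates; at a `"metastable"` state when the forces have converged
#' elsewhere; otherwise it is `"nonconverged"`.
#'
#' @param traj A `relax_trajectory`.
#' @param net The `elastic_network` it was integrated on.
#' @param rmsd_tol RMSD threshold in Angstrom (default 0.5).
#' @return One of `"reference"`, `"metastable"`, `"nonconverged"`.
#' @export
classify_endpoint <- function(traj, net, rmsd_tol = 0.5) {
  final <- traj$frames[[length(traj$frames)]]
  if (!traj$converged &&
      max(abs(elastic_forces(net, final))) >= traj$force_tol) {
    return("nonconverged")
  }
  if (superposed_rmsd(final, net$R0) < rmsd_tol) "reference" else "metastable"
}

#' Export a trajectory as a tab-separated table
#'
#' Writes one row per frame with time, elastic energy and, optionally, the two
#' label distances; a `#`-prefixed header records the seed and settings given.
#'
#' @param traj A `relax_trajectory`.
#' @param file Output path.
#' @param labels Optional integer vector `c(A, B, C)` of label particles; when
#'   given, columns `l_AB` and `l_BC` are added.
#' @param header Optional named character vector written as `# key: value`
#'   comment lines.
#' @return Invisibly, the path.
#' @export
write_trajectory <- function(traj, file, labels = NULL, header = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  for (k in names(header)) writeLines(paste0("# ", k, ": ", header[[k]]), con)
  tab <- data.frame(time = traj$times, energy = traj$energies)
  if (!is.null(labels)) {
    tr <- label_distance_series(traj, labels)
    tab$l_AB <- tr$l_AB
    tab$l_BC <- tr$l_BC
  }
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
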