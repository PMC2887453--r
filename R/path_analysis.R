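check_labels <- function(net, labels) {
  labels <- as.integer(labels)
  if (length(labels) != 3L || anyDuplicated(labels) ||
      any(labels < 1L | labels > net$n_particles)) {
    stop("labels must be 3 distinct particle indices in 1..", net$n_particles)
  }
  labels
}

#' Resolve residue identifiers to network particle indices
#'
#' Translates labels given as `"chain:resno"` (e.g. `"A:122"`) into particle
#' indices of a network built from a `calpha_structure`.
#'
#' @param net An `elastic_network` carrying residue identifiers.
#' @param ids Character vector like `c("A:122", "B:22", "B:135")`.
#' @return Integer vector of particle indices.
#' @export
resolve_labels <- function(net, ids) {
  if (is.null(net$residues)) stop("network carries no residue identifiers")
  key <- paste(net$residues$chain, net$residues$resno, sep = ":")
  idx <- match(ids, key)
  if (anyNA(idx)) stop("label(s) not found in network: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  idx
}

#' Distances between three label particles along a trajectory
#'
#' Reduces a trajectory to the two monitored distances l_AB(t) and l_BC(t)
#' used to visualize relaxation paths in a plane. The choice of labels is
#' arbitrary in principle; informative labels have distances that vary
#' substantially during relaxation.
#'
#' @param traj A `relax_trajectory`.
#' @param labels Integer vector `c(A, B, C)` of particle indices.
#' @return An object of class `distance_trace`: data frame with columns
#'   `time`, `l_AB`, `l_BC` (Angstrom), one row per frame.
#' @export
label_distance_series <- function(traj, labels) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == 3L, !anyDuplicated(labels))
  dd <- function(fr, i, j) sqrt(sum((fr[i, ] - fr[j, ])^2))
  out <- data.frame(
    time = traj$times,
    l_AB = vapply(traj$frames, dd, numeric(1), labels[1L], labels[2L]),
    l_BC = vapply(traj$frames, dd, numeric(1), labels[2L], labels[3L])
  )
  class(out) <- c("distance_trace", "data.frame")
  out
}

#' Mechanical coordinate and energy profile of a relaxation trajectory
#'
#' The collective mechanical coordinate s is the configuration-space arc
#' length remaining to the equilibrium endpoint along the trajectory: s
#' decreases monotonically to 0 and E(s) is the profile of the elastic energy
#' along the bottom of the relaxation valley. Along the gradient flow
#' dE/dt = -sum_i |dR_i/dt|^2, so the same coordinate can be obtained from
#' the energies alone as the quadrature of sqrt(-dE/dt); both estimators are
#' available and agree on densely sampled trajectories.
#'
#' @param traj A converged `relax_trajectory` (the s -> 0 endpoint must
#'   exist).
#' @param net The `elastic_network` (needed for the `"energy-flux"` method,
#'   which evaluates particle speeds from forces).
#' @param method `"arc"` (default): chord-summed arc length in full 3N
#'   configuration space; `"energy-flux"`: trapezoidal quadrature of the
#'   particle speed |dR/dt| = sqrt(-dE/dt) over time.
#' @return An object of class `energy_profile`: data frame with columns
#'   `time`, `s` (Angstrom), `E`, one row per frame.
#' @export
mechanical_coordinate <- function(traj, net = NULL,
                                  method = c("arc", "energy-flux")) {
  method <- match.arg(method)
  if (!traj$converged) {
    stop("trajectory did not converge; the s -> 0 endpoint is undefined")
  }
  nf <- length(traj$frames)
  if (nf == 1L) {
    out <- data.frame(time = traj$times, s = 0, E = traj$energies)
    class(out) <- c("energy_profile", "data.frame")
    return(out)
  }
  if (method == "arc") {
    steps <- vapply(seq_len(nf - 1L), function(k) {
      sqrt(sum((traj$frames[[k + 1L]] - traj$frames[[k]])^2))
    }, numeric(1))
  } else {
    if (is.null(net)) stop("method = 'energy-flux' needs the network")
    speed <- vapply(traj$frames, function(fr) {
      sqrt(sum(elastic_forces(net, fr)^2))   # |dR/dt| = |F| = sqrt(-dE/dt)
    }, numeric(1))
    dt <- diff(traj$times)
    v1 <- speed[-nf]; v2 <- speed[-1L]
    # logarithmic-mean quadrature: exact for exponentially decaying speed,
    # which is what the late-time relaxation tail delivers
    plain <- v2 <= 0 | v1 <= 0 | abs(v1 - v2) < 1e-12 * pmax(v1, v2)
    steps <- ifelse(plain, (v1 + v2) / 2, (v1 - v2) / log(v1 / v2)) * dt
  }
  s <- rev(cumsum(rev(c(steps, 0))))
  out <- data.frame(time = traj$times, s = s, E = traj$energies)
  class(out) <- c("energy_profile", "data.frame")
  out
}

#' Fit the harmonic well of an energy profile
#'
#' Least-squares fit of E = k s^2 through the origin over the profile points
#' with s below `s_window` — the quadratic approximation corresponding to the
#' slowest normal mode predicts k = lambda_1 / 2 when relaxation has collapsed
#' onto the soft mode. Also reports the harmonic-domain radius: the largest s
#' at which the profile deviates from the fitted parabola by less than 10%
#' in relative terms (contiguously from the origin).
#'
#' @param profile An `energy_profile`.
#' @param s_window Fit window on s (Angstrom).
#' @param rel_tol Relative deviation defining the harmonic domain
#'   (default 0.1).
#' @return List with `k` (curvature coefficient), `harmonic_radius`, and
#'   `n_points` used in the fit.
#' @export
fit_quadratic_well <- function(profile, s_window, rel_tol = 0.1) {
  sel <- profile$s < s_window & profile$s > 0
  if (sum(sel) < 5L) stop("need at least 5 profile points with s < s_window")
  s2 <- profile$s[sel]^2
  k <- sum(profile$E[sel] * s2) / sum(s2 * s2)
  # scan outward in s over points with meaningful energy (a relative-error
  # criterion is vacuous at the E -> 0 endpoint); the harmonic domain is
  # contiguous from the origin
  ok <- which(profile$E > 1e-9 * max(profile$E) & profile$s > 0)
  ok <- ok[order(profile$s[ok])]
  rel <- abs(profile$E[ok] - k * profile$s[ok]^2) / profile$E[ok]
  first_bad <- which(rel >= rel_tol)
  radius <- if (length(first_bad) == 0L) max(profile$s) else {
    if (first_bad[1L] == 1L) 0 else profile$s[ok[first_bad[1L] - 1L]]
  }
  list(k = k, harmonic_radius = radius, n_points = sum(sel))
}

#' Dispersion and branching of a bundle of label-distance traces
#'
#' Aligns traces by progress — each trace's own remaining arc length in the
#' (l_AB, l_BC) plane, as a fraction of its total length — and measures at
#' each progress value the cross-trace spread (RMS distance to the bundle
#' medoid). A well-defined attractive relaxation path shows spread decreasing
#' to zero as progress -> 0. The branch report flags bimodality: progress
#' values where a 2-means split of the bundle separates two clusters whose
#' center distance exceeds `branch_factor` times the pooled within-cluster
#' RMS spread, and reports the progress below which the clusters have merged.
#'
#' @param traces List of `distance_trace` objects ending at the same point of
#'   the distance plane (checked to `endpoint_tol`).
#' @param progress_grid Numeric vector of progress fractions in (0, 1];
#'   default 20 evenly spaced values.
#' @param branch_factor Separation-to-spread ratio declaring two branches
#'   (default 3).
#' @param endpoint_tol Maximum spread of trace endpoints (Angstrom,
#'   default 1).
#' @return List with `progress`, `dispersion` (RMS spread, Angstrom),
#'   `bimodal` (logical per grid point), `branched` (any bimodality), and
#'   `merge_progress` (largest progress below which no bimodality is seen;
#'   0 if never bimodal).
#' @export
bundle_dispersion <- function(traces, progress_grid = seq(0.05, 1, length.out = 20L),
                              branch_factor = 3, endpoint_tol = 1) {
  stopifnot(length(traces) >= 2L)
  ends <- t(vapply(traces, function(tr) {
    c(tr$l_AB[nrow(tr)], tr$l_BC[nrow(tr)])
  }, numeric(2)))
  center <- colMeans(ends)
  if (max(sqrt(rowSums((ends - rep(center, each = nrow(ends)))^2))) > endpoint_tol) {
    stop("traces do not share a common endpoint in the distance plane")
  }

  # position of one trace at a given remaining-arc-length fraction
  at_progress <- function(tr, p) {
    xy <- cbind(tr$l_AB, tr$l_BC)
    steps <- sqrt(rowSums(diff(xy)^2))
    remaining <- rev(cumsum(rev(c(steps, 0))))
    total <- remaining[1L]
    if (total == 0) return(xy[nrow(xy), ])
    target <- p * total
    k <- which(remaining <= target)[1L]       # remaining is non-increasing
    if (is.na(k)) return(xy[nrow(xy), ])
    if (k == 1L || remaining[k] == target) return(xy[k, ])
    w <- (remaining[k - 1L] - target) / (remaining[k - 1L] - remaining[k])
    xy[k - 1L, ] * (1 - w) + xy[k, ] * w
  }

  disp <- numeric(length(progress_grid))
  bimodal <- logical(length(progress_grid))
  for (g in seq_along(progress_grid)) {
    pts <- t(vapply(traces, at_progress, numeric(2), p = progress_grid[g]))
    dmat <- as.matrix(stats::dist(pts))
    medoid <- pts[which.min(colSums(dmat)), ]
    disp[g] <- sqrt(mean(rowSums((pts - rep(medoid, each = nrow(pts)))^2)))
    min_size <- max(2L, ceiling(0.1 * nrow(pts)))
    if (nrow(unique(pts)) >= 2L * min_size && disp[g] > 0) {
      km <- tryCatch(stats::kmeans(pts, centers = 2L, nstart = 5L),
                     error = function(e) NULL)
      if (!is.null(km) && min(km$size) >= min_size) {
        # a branched bundle shows an empty corridor between the two
        # families: the closest cross-cluster pair is much farther apart
        # than points are from their within-cluster neighbours
        in1 <- km$cluster == 1L
        gap <- min(dmat[in1, !in1])
        nn_within <- vapply(seq_len(nrow(pts)), function(r) {
          same <- km$cluster == km$cluster[r]
          same[r] <- FALSE
          min(dmat[r, same])
        }, numeric(1))
        spread <- stats::median(nn_within)
        separated <- spread > 0 && gap > branch_factor * spread
        if (separated) {
          # two clusters on opposite sides of the endpoint are the two arms
          # of a single undirected valley line (the soft-mode line), not a
          # branched path: require the clusters to subtend < 120 degrees at
          # the common endpoint
          v1 <- km$centers[1L, ] - center
          v2 <- km$centers[2L, ] - center
          n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
          separated <- n1 > spread && n2 > spread &&
            sum(v1 * v2) / (n1 * n2) > -0.5
        }
        bimodal[g] <- separated
      }
    }
  }
  merge_progress <- if (any(bimodal)) {
    below <- progress_grid[progress_grid < min(progress_grid[bimodal])]
    if (length(below) == 0L) min(progress_grid) else max(below)
  } else 0
  list(progress = progress_grid, dispersion = disp, bimodal = bimodal,
       branched = any(bimodal), merge_progress = merge_progress)
}

#' Export an energy profile as a tab-separated table
#'
#' @param profile An `energy_profile`.
#' @param file Output path.
#' @return Invisibly, the path. Columns: `t`, `s`, `E`.
#' @export
write_profile <- function(profile, file) {
  tab <- data.frame(t = profile$time, s = profile$s, E = profile$E)
  utils::write.table(format(tab, digits = 10), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
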