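#' Wrap a coordinate matrix as a C-alpha structure
#'
#' @param R N x 3 coordinate matrix (Angstrom).
#' @param chain Chain identifier(s), recycled to N.
#' @param resno Residue numbers (default 1..N).
#' @return A `calpha_structure` (residue name `GLY` throughout).
#' @export
structure_from_coords <- function(R, chain = "A", resno = NULL) {
  R <- as.matrix(R)
  n <- nrow(R)
  if (is.null(resno)) resno <- seq_len(n)
  out <- data.frame(chain = rep_len(chain, n), resno = as.integer(resno),
                    insert = "", resid = "GLY",
                    x = R[, 1L], y = R[, 2L], z = R[, 3L],
                    stringsAsFactors = FALSE)
  class(out) <- c("calpha_structure", "data.frame")
  out
}

#' Toy chain and helix structures
#'
#' Beads at fixed spacing along a straight line or an alpha-helix-like curve
#' (radius 2.3 A, 100 degrees and 1.5 A rise per residue, rescaled so
#' consecutive beads sit `spacing` apart). Deterministic.
#'
#' @param n Number of beads (>= 2).
#' @param spacing Consecutive-bead distance in Angstrom (default 3.8,
#'   C-alpha-like).
#' @param kind `"chain"` (straight line) or `"helix"`.
#' @return A `calpha_structure`.
#' @export
make_toy_chain <- function(n, spacing = 3.8, kind = c("chain", "helix")) {
  kind <- match.arg(kind)
  stopifnot(n >= 2L, spacing > 0)
  if (kind == "chain") {
    R <- cbind(spacing * (seq_len(n) - 1L), 0, 0)
  } else {
    theta <- (seq_len(n) - 1L) * 100 * pi / 180
    R <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (seq_len(n) - 1L))
    step <- sqrt(sum((R[2L, ] - R[1L, ])^2))
    R <- R * (spacing / step)
  }
  structure_from_coords(R)
}

# Compact FCC-like blob: lattice sites with even coordinate sum, scaled so the
# nearest-neighbour distance equals `spacing`; the `n` sites closest to the
# origin form a non-collinear, non-planar cluster.
fcc_blob <- function(n, spacing = 3.8) {
  s <- spacing / sqrt(2)
  rng <- -4:4
  g <- as.matrix(expand.grid(i = rng, j = rng, k = rng))
  g <- g[(g[, 1L] + g[, 2L] + g[, 3L]) %% 2L == 0L, , drop = FALSE]
  X <- g * s
  d2 <- rowSums(X * X)
  # deterministic tie-break so the blob is reproducible across platforms
  ord <- order(d2, X[, 1L], X[, 2L], X[, 3L])
  X[ord[seq_len(n)], , drop = FALSE]
}

rotate_about <- function(X, pivot, axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -a[3L], a[2L], a[3L], 0, -a[1L], -a[2L], a[1L], 0),
              3L, 3L, byrow = TRUE)
  Rm <- diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(X, 2L, pivot) %*% t(Rm), 2L, pivot, `+`)
}

#' Two-domain hinge fixture: a reference/deformed conformation pair
#'
#' Two compact FCC-like bead clusters face each other across a waist narrow
#' enough that cross-domain springs form under the cutoff. The deformed state
#' twists the second domain rigidly about the inter-domain axis, which strains
#' only the cross-domain springs — emulating a ligand-induced conformational
#' change under the elastic assumption that the contact topology is identical
#' in both states. Topology preservation is verified at generation time; if
#' the requested angle changes the link set, the angle is reduced
#' geometrically until it no longer does (error if that fails).
#'
#' @param n Total number of beads (>= 12; split between the two domains).
#' @param angle Hinge twist in degrees between the states.
#' @param spacing Lattice bead spacing (Angstrom, default 3.8).
#' @param gap Surface-to-surface waist width (Angstrom, default 4.5).
#' @param cutoff Cutoff used for the topology check and intended for
#'   downstream [build_network()] (default 10).
#' @return List with `reference` and `deformed` (`calpha_structure`s),
#'   `labels` (three particle indices: off-axis beads — one per flank of
#'   domain 1 and one on domain 2 — chosen so both monitored distances move
#'   under the twist), `cutoff`, and `angle` (the angle actually used).
#' @export
make_two_domain_hinge <- function(n = 40L, angle = 25, spacing = 3.8,
                                  gap = 4.5, cutoff = 10) {
  stopifnot(n >= 12L)
  n_a <- ceiling(n / 2); n_b <- n - n_a
  A <- fcc_blob(n_a, spacing)
  B0 <- fcc_blob(n_b, spacing)
  shift <- max(A[, 1L]) - min(B0[, 1L]) + gap
  B <- sweep(B0, 2L, c(shift, 0, 0), `+`)
  ref <- rbind(A, B)
  pivot <- c(max(A[, 1L]) + gap / 2, 0, 0)

  topology_equal <- function(ang) {
    Brot <- rotate_about(B, pivot, c(1, 0, 0), ang)
    def <- rbind(A, Brot)
    da <- as.matrix(stats::dist(ref)) < cutoff
    db <- as.matrix(stats::dist(def)) < cutoff
    if (identical(da, db)) def else NULL
  }
  ang <- angle
  def <- topology_equal(ang)
  tries <- 0L
  while (is.null(def) && tries < 25L) {
    ang <- ang * 0.85
    def <- topology_equal(ang)
    tries <- tries + 1L
  }
  if (is.null(def)) {
    stop("could not preserve contact topology even at hinge angle ",
         signif(ang, 3), " degrees")
  }

  # labels off the twist axis so both monitored distances respond to the
  # soft (torsional) motion
  rad_a <- sqrt(A[, 2L]^2 + A[, 3L]^2)
  rad_b <- sqrt(B[, 2L]^2 + B[, 3L]^2)
  lab_a <- which.max(rad_a - A[, 1L])                   # domain-1 far flank
  lab_b <- n_a + which.max(rad_b + 0.2 * B[, 1L])       # domain-2 off-axis
  lab_c <- which.max(abs(A[, 2L]) - A[, 3L])            # domain-1 -z flank
  if (lab_c == lab_a) {
    lab_c <- order(abs(A[, 2L]) - A[, 3L], decreasing = TRUE)[2L]
  }
  list(reference = structure_from_coords(ref),
       deformed = structure_from_coords(def),
       labels = c(lab_a, lab_b, lab_c),
       cutoff = cutoff, angle = ang)
}

#' Five-particle network with two isolated energy minima
#'
#' A rigid tetrahedral base (four beads, all six edges linked) plus a flap
#' bead tethered by exactly three springs. The three sphere constraints on the
#' flap admit two isolated solutions — the reference position and its mirror
#' image through the plane of its three anchors — so the network has two
#' zero-energy minima that are enantiomeric and hence separated by a positive
#' Kabsch RMSD. Relaxations started in the second basin converge there,
#' giving a clean `"metastable"` endpoint.
#'
#' @return List with `structure` (`calpha_structure`, flap is particle 5),
#'   `cutoff` (4.5 A, linking exactly the intended pairs), `mirror`
#'   (N x 3 coordinates of the second minimum), and `labels` `c(3, 5, 4)`
#'   monitoring the flap against two base beads.
#' @export
make_bistable_network <- function() {
  P <- rbind(c(0, 0, 0),
             c(3.8, 0, 0),
             c(1.9, 3.2909, 0),
             c(1.9, 1.0970, 3.1027),   # apex: regular tetrahedron with 1-3
             c(1.9, -1.8, 2.6))        # flap, anchored to beads 1, 2, 4
  nrm <- c(0, -3.1027, 1.0970)
  nrm <- nrm / sqrt(sum(nrm^2))        # normal of anchor plane (1,2,4)
  mirror <- P
  mirror[5L, ] <- P[5L, ] - 2 * sum(P[5L, ] * nrm) * nrm
  list(structure = structure_from_coords(P), cutoff = 4.5,
       mirror = mirror, labels = c(3L, 5L, 4L))
}

#' Six-particle network with two relaxation valleys merging at the minimum
#'
#' A rigid tetrahedral base carries two flaps. The slow flap (particle 5, the
#' same bead as in [make_bistable_network()] but tethered by a fourth spring
#' under the larger cutoff) moves on a soft angular coordinate whose energy
#' profile has a single minimum and one high barrier, so relaxations slide
#' into the reference along it. The fast flap (particle 6) is anchored by
#' four springs on the opposite face; displacing it to either side of its
#' rest azimuth creates two distinct relaxation valleys that run parallel in
#' the label-distance plane while the slow coordinate completes, and merge
#' only near the equilibrium point — the geometry underlying a branched
#' relaxation path. A shallow metastable shoulder on the slow flap's circle
#' traps relaxations started directly inside it.
#'
#' @return List with `structure` (`calpha_structure`, 6 beads), `cutoff`
#'   (6 A), `labels` `c(6, 5, 4)` (fast flap, slow flap, base apex), and
#'   three starting conformations: `near_start` and `side_start` (slow flap
#'   at azimuth 100 degrees, fast flap displaced to either side of its rest
#'   azimuth), whose relaxation bundles exhibit the two merging valleys, and
#'   `shoulder_start` (slow flap at azimuth 45 degrees), which relaxes into
#'   the metastable shoulder.
#' @export
make_two_valley_network <- function() {
  P <- coords(make_bistable_network()$structure)
  m <- (P[2L, ] + P[3L, ]) / 2
  ax <- (P[3L, ] - P[2L, ]) / sqrt(sum((P[3L, ] - P[2L, ])^2))
  u <- c(0, 0, 1); v <- c(ax[2L], -ax[1L], 0)
  gpos <- function(psi_deg) {
    psi <- psi_deg * pi / 180
    m + 2.94 * (cos(psi) * u + sin(psi) * v)
  }
  dpos <- function(phi_deg) {
    phi <- phi_deg * pi / 180
    c(1.9, sqrt(10) * cos(phi), sqrt(10) * sin(phi))
  }
  X <- rbind(P, gpos(200))
  state <- function(phi, psi) {
    Y <- X; Y[5L, ] <- dpos(phi); Y[6L, ] <- gpos(psi); Y
  }
  list(structure = structure_from_coords(X), cutoff = 6,
       labels = c(6L, 5L, 4L),
       near_start = state(100, 165), side_start = state(100, 235),
       shoulder_start = state(45, 200))
}
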