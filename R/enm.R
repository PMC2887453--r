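#' Build an elastic network from a reference structure
#'
#' Two beads are connected by a Hookean spring when their distance in the
#' reference conformation is strictly less than the cutoff length; the natural
#' length of every spring equals that reference distance, so the reference
#' state is a global minimum of the elastic energy with E = 0. All springs
#' share the same stiffness constant, fixed at kappa = 1 in the rescaled units
#' used throughout (the particle mobility is absorbed into the time unit).
#'
#' @param reference A `calpha_structure` or an N x 3 coordinate matrix giving
#'   the equilibrium bead positions (Angstrom).
#' @param cutoff Cutoff length r_c in Angstrom (default 10).
#' @return An object of class `elastic_network` with fields `R0` (N x 3
#'   equilibrium coordinates), `edges` (M x 2 integer matrix of linked pairs,
#'   i < j), `d0` (natural lengths, Angstrom), `cutoff`, `n_particles`,
#'   `n_links`, and `residues` (identifier data frame when built from a
#'   structure, else NULL). Warns when the contact graph is disconnected or
#'   when any particle has fewer than two links.
#' @export
build_network <- function(reference, cutoff = 10) {
  stopifnot(cutoff > 0)
  residues <- NULL
  if (inherits(reference, "calpha_structure")) {
    residues <- reference[, c("chain", "resno", "insert", "resid")]
    R0 <- coords(reference)
  } else {
    R0 <- as.matrix(reference)
  }
  stopifnot(ncol(R0) == 3L)
  n <- nrow(R0)
  if (n < 2L) stop("an elastic network needs at least 2 particles")
  if (any(!is.finite(R0))) stop("non-finite reference coordinates")

  d <- as.matrix(stats::dist(R0))
  adj <- d < cutoff
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  edges <- which(adj, arr.ind = TRUE)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  colnames(edges) <- c("i", "j")
  d0 <- d[edges]

  net <- structure(
    list(R0 = R0, edges = edges, d0 = d0, cutoff = cutoff,
         n_particles = n, n_links = nrow(edges), stiffness = 1,
         residues = residues),
    class = "elastic_network"
  )

  deg <- tabulate(edges, nbins = n)
  if (any(deg < 2L)) {
    warning(sum(deg < 2L), " particle(s) have fewer than 2 links")
  }
  if (nrow(edges) > 0L) {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    if (igraph::components(g)$no > 1L) {
      warning("network contact graph is disconnected (",
              igraph::components(g)$no, " components)")
    }
  } else {
    warning("network has no links at cutoff ", cutoff)
  }
  net
}

#' @export
print.elastic_network <- function(x, ...) {
  cat("Elastic network:", x$n_particles, "particles,", x$n_links,
      "links (cutoff", x$cutoff, "A, kappa = 1)\n")
  invisible(x)
}

#' Dense adjacency matrix of a network
#'
#' @param net An `elastic_network`.
#' @return Symmetric N x N 0/1 matrix with zero diagonal.
#' @export
adjacency_matrix <- function(net) {
  A <- matrix(0L, net$n_particles, net$n_particles)
  A[net$edges] <- 1L
  A[net$edges[, c(2L, 1L), drop = FALSE]] <- 1L
  A
}

check_conformation <- function(net, R) {
  R <- as.matrix(R)
  if (nrow(R) != net$n_particles || ncol(R) != 3L) {
    stop("conformation has ", nrow(R), " x ", ncol(R),
         " coordinates; network expects ", net$n_particles, " x 3")
  }
  if (any(!is.finite(R))) stop("non-finite coordinates in conformation")
  R
}

link_lengths <- function(net, R) {
  dv <- R[net$edges[, 1L], , drop = FALSE] - R[net$edges[, 2L], , drop = FALSE]
  sqrt(rowSums(dv * dv))
}

#' Total elastic energy of a conformation
#'
#' E = (kappa/2) * sum over linked pairs of (d_ij - d0_ij)^2, where d_ij is the
#' instantaneous distance and d0_ij the natural length. The energy is invariant
#' under rigid translations and rotations of the conformation; it is zero
#' exactly when every link is at its natural length.
#'
#' @param net An `elastic_network`.
#' @param conf N x 3 coordinate matrix.
#' @return Scalar energy in rescaled (dimensionless) units.
#' @export
elastic_energy <- function(net, conf) {
  R <- check_conformation(net, conf)
  dl <- link_lengths(net, R) - net$d0
  0.5 * net$stiffness * sum(dl * dl)
}

#' Elastic forces on every particle
#'
#' The force on particle i is minus the gradient of [elastic_energy()]:
#' F_i = -kappa * sum_j A_ij (d_ij - d0_ij) (R_i - R_j) / d_ij.
#' Forces sum to zero (translation invariance) and carry zero net torque about
#' the centroid (rotation invariance).
#'
#' @inheritParams elastic_energy
#' @return N x 3 matrix of force vectors (rescaled units).
#' @export
elastic_forces <- function(net, conf) {
  R <- check_conformation(net, conf)
  force_field(net)(R)
}

# Closure evaluating forces via a precomputed sparse incidence matrix B
# (M x N, +1/-1 per edge endpoint): bond vectors are B R, forces -t(B) (c * BR).
force_field <- function(net) {
  m <- net$n_links
  B <- Matrix::sparseMatrix(
    i = c(seq_len(m), seq_len(m)),
    j = c(net$edges[, 1L], net$edges[, 2L]),
    x = c(rep(1, m), rep(-1, m)),
    dims = c(m, net$n_particles)
  )
  d0 <- net$d0
  kappa <- net$stiffness
  function(R) {
    dv <- as.matrix(B %*% R)
    d <- sqrt(rowSums(dv * dv))
    if (any(d == 0)) {
      stop("linked particles coincide (zero separation); force direction undefined")
    }
    -as.matrix(Matrix::crossprod(B, dv * (kappa * (d - d0) / d)))
  }
}

#' Hessian of the elastic energy at the reference state
#'
#' The 3N x 3N second-derivative (linearization) matrix of the elastic energy,
#' evaluated at the equilibrium coordinates. At equilibrium every link is at
#' its natural length, so each link contributes the rank-one block
#' kappa * u u^T along its unit bond vector u. The matrix is symmetric,
#' positive semidefinite, and its 3 x 3 row blocks sum to zero (translation
#' invariance); for a generic non-degenerate 3-D network exactly six
#' eigenvalues vanish (rigid translations and rotations).
#'
#' @param net An `elastic_network`.
#' @return Dense symmetric 3N x 3N matrix. Coordinates of particle i occupy
#'   rows/columns `3i-2, 3i-1, 3i`.
#' @export
enm_hessian <- function(net) {
  n <- net$n_particles
  H <- matrix(0, 3L * n, 3L * n)
  for (k in seq_len(net$n_links)) {
    i <- net$edges[k, 1L]; j <- net$edges[k, 2L]
    u <- net$R0[i, ] - net$R0[j, ]
    u <- u / sqrt(sum(u * u))
    blk <- net$stiffness * tcrossprod(u)
    ii <- (3L * i - 2L):(3L * i); jj <- (3L * j - 2L):(3L * j)
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
  }
  H
}

#' Export or import a network as a plain-text edge list
#'
#' The format is a two-line header (`# particles N cutoff r_c` and a column
#' header) followed by one `i j d0` row per link; coordinates are written in a
#' companion section so that a write/read round trip reconstructs the network.
#'
#' @param net An `elastic_network`.
#' @param file Output path.
#' @return Invisibly, the path (`write_network`) or the network
#'   (`read_network`).
#' @export
write_network <- function(net, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# elastic_network particles %d links %d cutoff %.6f",
                     net$n_particles, net$n_links, net$cutoff), con)
  writeLines("# coordinates x y z", con)
  utils::write.table(format(net$R0, digits = 17), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines("# edges i j d0", con)
  utils::write.table(data.frame(net$edges, d0 = format(net$d0, digits = 17)),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_network
#' @export
read_network <- function(file) {
  lines <- readLines(file)
  hdr <- strsplit(lines[1L], " +")[[1]]
  n <- as.integer(hdr[4L]); cutoff <- as.numeric(hdr[8L])
  R0 <- matrix(scan(text = lines[3:(2 + n)], quiet = TRUE), ncol = 3L,
               byrow = TRUE)
  build_network(R0, cutoff = cutoff)
}
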