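# Shared fixtures and independent oracles for the test suite.

# Two-particle network with one spring of natural length 1 along x.
spring_net <- function() {
  suppressWarnings(build_network(rbind(c(0, 0, 0), c(1, 0, 0)), cutoff = 1.5))
}

# Stretched single-spring conformation (separation d along x).
spring_conf <- function(d) rbind(c(0, 0, 0), c(d, 0, 0))

# Central finite-difference gradient of a scalar function of an N x 3
# conformation; the independent oracle for elastic_forces.
num_grad <- function(f, R, h = 1e-5) {
  g <- matrix(0, nrow(R), 3L)
  for (i in seq_len(nrow(R))) {
    for (k in 1:3) {
      Rp <- R; Rp[i, k] <- Rp[i, k] + h
      Rm <- R; Rm[i, k] <- Rm[i, k] - h
      g[i, k] <- (f(Rp) - f(Rm)) / (2 * h)
    }
  }
  g
}

# Deterministic random rotation matrix (proper, det = +1).
random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Minimal PDB writer for hand-built test records (wwPDB v3.3 columns).
pdb_atom_line <- function(serial, name, resid, chain, resno, xyz,
                          alt = " ", icode = " ", occ = 1, type = "ATOM  ") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          type, serial, paste0(" ", name), alt, resid, chain, resno, icode,
          xyz[1], xyz[2], xyz[3], occ, 0)
}

write_pdb_file <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}

# Three standard fixture networks used by the force/Hessian oracle suites.
oracle_networks <- function() {
  helix <- suppressWarnings(build_network(make_toy_chain(10, kind = "helix"),
                                          cutoff = 6))
  hinge <- make_two_domain_hinge(n = 16, angle = 20)
  hinge_net <- suppressWarnings(build_network(hinge$reference, cutoff = 10))
  tv <- make_two_valley_network()
  tv_net <- suppressWarnings(build_network(tv$structure, cutoff = tv$cutoff))
  list(helix = helix, hinge = hinge_net, two_valley = tv_net)
}
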