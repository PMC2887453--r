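#' Default experiment configuration
#'
#' Returns the configuration skeleton understood by [run_experiment()], with
#' the fixture-scale defaults documented in the package vignette. Protein-scale
#' runs must supply `reference_pdb`/`initial_pdb` paths and the per-protein
#' protocol parameters (`f0`, `t0`, `rms_a`) explicitly — these have no
#' defaults.
#'
#' @param ... Named overrides merged over the defaults.
#' @return Named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    fixture = list(kind = "two_domain_hinge", n_particles = 40L, angle = 25),
    reference_pdb = NULL, initial_pdb = NULL, chain_map = NULL, chains = NULL,
    cutoff = 10, labels = NULL,
    n_random_ics = 100L, f0 = 0.6, t0 = 10, max_stretch = 2,
    rms_a = 0.3,
    t_max = 2000, n_frames = 160L, force_tol = 1e-8,
    rtol = 1e-8, atol = 1e-10, rmsd_tol = 0.5,
    s_window_frac = 0.3, branch_factor = 3,
    compute_modes = TRUE, seed = 1L, outdir = NULL
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read an experiment configuration from a YAML file
#'
#' @param file Path to a YAML document whose keys follow [default_config()].
#' @return Named list (defaults filled in for absent keys).
#' @export
read_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  do.call(default_config, cfg)
}

config_hash <- function(cfg) {
  cfg$outdir <- NULL   # where results land does not change what they are
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = 12, null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full relaxation-analysis experiment
#'
#' Orchestrates, from one configuration, the three numerical experiments the
#' package is built around: (i) the functional transition — relaxation from an
#' alternate ("initial") conformation on the reference network, reduced to a
#' label-distance trace and an energy profile with a harmonic-well fit;
#' (ii) a bundle of relaxations from `n_random_ics` force-prepared random
#' initial conditions, with endpoint classification and bundle
#' dispersion/branching; (iii) the same bundle size of relaxations from
#' RMS-perturbed copies of the functional start (path robustness); plus the
#' normal-mode spectrum and the soft-mode direction in the distance plane.
#'
#' @param config A list as from [default_config()] / [read_config()], or a
#'   path to a YAML file.
#' @return A summary list (network size, endpoint tallies, fitted curvature
#'   and soft-mode eigenvalue, spectral gap, branch reports, seed and config
#'   hash), invisibly written as `summary.json` plus per-stage TSV tables when
#'   `config$outdir` is set.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- do.call(default_config, config)
  outdir <- cfg$outdir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  emit <- function(name, writer) {
    if (!is.null(outdir)) writer(file.path(outdir, name))
  }
  hash <- config_hash(cfg)
  hdr <- c(config_md5 = hash, seed = cfg$seed,
           package = as.character(utils::packageVersion("enmrelax")))

  ## ---- inputs: structures and network -----------------------------------
  if (!is.null(cfg$reference_pdb)) {
    ref_struct <- read_calpha(cfg$reference_pdb, chains = cfg$chains)
    ini_struct <- read_calpha(cfg$initial_pdb, chains = cfg$chains)
    pairing <- match_common_residues(ref_struct, ini_struct,
                                     chain_map = cfg$chain_map)
    ref_struct <- ref_struct[pairing$index_a, ]
    class(ref_struct) <- c("calpha_structure", "data.frame")
    net <- build_network(ref_struct, cutoff = cfg$cutoff)
    pairing_net <- data.frame(index_a = seq_len(nrow(pairing)),
                              index_b = pairing$index_b)
    class(pairing_net) <- c("residue_pairing", "data.frame")
    start0 <- conformation_as_initial_condition(net, ini_struct, pairing_net)
    for (p in c("f0", "t0", "rms_a")) {
      if (is.null(config[[p]])) {
        stop("protein-scale runs require explicit ", p, " in the config")
      }
    }
  } else {
    fx <- cfg$fixture
    if (!identical(fx$kind, "two_domain_hinge")) {
      stop("unknown fixture kind: ", fx$kind)
    }
    hinge <- make_two_domain_hinge(n = fx$n_particles, angle = fx$angle,
                                   cutoff = cfg$cutoff)
    net <- build_network(hinge$reference, cutoff = cfg$cutoff)
    start0 <- coords(hinge$deformed)
    if (is.null(cfg$labels)) cfg$labels <- hinge$labels
  }
  if (is.null(cfg$labels)) {
    stop("labels (three residue identifiers or particle indices) are required")
  }
  labels <- if (is.character(cfg$labels)) resolve_labels(net, cfg$labels)
            else check_labels(net, cfg$labels)

  summary <- list(
    config_md5 = hash, seed = cfg$seed,
    n_particles = net$n_particles, n_links = net$n_links,
    cutoff = cfg$cutoff, labels = labels
  )

  ## ---- normal modes ------------------------------------------------------
  if (isTRUE(cfg$compute_modes)) {
    spec <- compute_modes(enm_hessian(net))
    nz <- nonzero_mode_values(spec)
    dir1 <- soft_mode_distance_direction(spec, net, labels)
    summary$n_zero_modes <- spec$n_zero
    summary$lambda1 <- nz[1L]
    summary$gap_lambda2_over_lambda1 <- nz[2L] / nz[1L]
    summary$soft_mode_direction <- dir1
    emit("spectrum.tsv", function(f) write_spectrum(spec, f))
  }

  ## ---- functional transition --------------------------------------------
  traj_fun <- relax(net, start0, t_max = cfg$t_max, n_frames = cfg$n_frames,
                    force_tol = cfg$force_tol, rtol = cfg$rtol,
                    atol = cfg$atol)
  summary$functional_endpoint <- classify_endpoint(traj_fun, net,
                                                   rmsd_tol = cfg$rmsd_tol)
  summary$functional_converged <- traj_fun$converged
  summary$functional_E0 <- traj_fun$energies[1L]
  emit("traj_functional.tsv", function(f) {
    write_trajectory(traj_fun, f, labels = labels, header = hdr)
  })
  if (traj_fun$converged) {
    prof <- mechanical_coordinate(traj_fun)
    fit <- fit_quadratic_well(prof, s_window = cfg$s_window_frac * max(prof$s))
    summary$quadratic_k <- fit$k
    summary$harmonic_radius <- fit$harmonic_radius
    if (!is.null(summary$lambda1)) {
      summary$k_over_half_lambda1 <- fit$k / (summary$lambda1 / 2)
    }
    emit("profile_functional.tsv", function(f) write_profile(prof, f))
  }

  ## ---- bundles -----------------------------------------------------------
  run_bundle <- function(starts, tag) {
    trajs <- lapply(starts, function(st) {
      relax(net, st, t_max = cfg$t_max, n_frames = cfg$n_frames,
            force_tol = cfg$force_tol, rtol = cfg$rtol, atol = cfg$atol)
    })
    classes <- vapply(trajs, classify_endpoint, character(1), net = net,
                      rmsd_tol = cfg$rmsd_tol)
    n_meta <- sum(classes == "metastable")
    if (n_meta > 0L) {
      warning(n_meta, " ", tag, " trajectorie(s) ended in metastable states")
    }
    keep <- classes == "reference"
    traces <- lapply(trajs[keep], label_distance_series, labels = labels)
    bundle <- if (sum(keep) >= 2L) {
      bundle_dispersion(traces, branch_factor = cfg$branch_factor)
    }
    if (length(traces) > 0L) {
      emit(paste0("traces_", tag, ".tsv"), function(f) {
        tab <- do.call(rbind, lapply(seq_along(traces), function(k) {
          cbind(ic = which(keep)[k], as.data.frame(traces[[k]]))
        }))
        utils::write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
      })
    }
    list(classes = table(factor(classes, levels = c("reference", "metastable",
                                                    "nonconverged"))),
         bundle = bundle)
  }

  if (cfg$n_random_ics > 0L) {
    ics <- forced_initial_conditions(net, cfg$n_random_ics, cfg$f0, cfg$t0,
                                     seed = cfg$seed,
                                     max_stretch = cfg$max_stretch)
    rnd <- run_bundle(ics, "random_ic")
    summary$random_ic_endpoints <- as.list(rnd$classes)
    if (!is.null(rnd$bundle)) {
      summary$random_ic_dispersion <- rnd$bundle$dispersion
      summary$random_ic_progress <- rnd$bundle$progress
      summary$random_ic_branched <- rnd$bundle$branched
      summary$random_ic_merge_progress <- rnd$bundle$merge_progress
    }

    perturbed <- lapply(seq_len(cfg$n_random_ics), function(k) {
      random_rms_displacement(start0, cfg$rms_a, seed = cfg$seed + 10000L + k)
    })
    per <- run_bundle(perturbed, "perturbed")
    summary$perturbed_endpoints <- as.list(per$classes)
    if (!is.null(per$bundle)) {
      summary$perturbed_dispersion <- per$bundle$dispersion
      summary$perturbed_branched <- per$bundle$branched
      summary$perturbed_merge_progress <- per$bundle$merge_progress
    }
  }

  if (!is.null(outdir)) {
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  summary
}

#' Build the elastic network shared by two crystallographic states
#'
#' Convenience wrapper for the protein workflow: read the C-alpha sets of a
#' reference and an alternate PDB entry, keep only the residues present in
#' both, build the network from the reference coordinates of those residues,
#' and map the alternate conformation onto it as a starting state.
#'
#' @param reference_pdb,initial_pdb Paths to the two PDB files.
#' @param cutoff Cutoff length in Angstrom (default 10).
#' @param chain_map,chains Passed to [match_common_residues()] and
#'   [read_calpha()].
#' @return List with `network` (an `elastic_network` over the common
#'   residues), `pairing` (the `residue_pairing` used), and `start` (the
#'   alternate conformation as an N x 3 matrix).
#' @export
network_from_pdb_pair <- function(reference_pdb, initial_pdb, cutoff = 10,
                                  chain_map = NULL, chains = NULL) {
  a <- read_calpha(reference_pdb, chains = chains)
  b <- read_calpha(initial_pdb, chains = chains)
  pairing <- match_common_residues(a, b, chain_map = chain_map)
  common <- a[pairing$index_a, ]
  class(common) <- c("calpha_structure", "data.frame")
  net <- build_network(common, cutoff = cutoff)
  renum <- data.frame(index_a = seq_len(nrow(pairing)),
                      index_b = pairing$index_b)
  class(renum) <- c("residue_pairing", "data.frame")
  start <- conformation_as_initial_condition(net, b, renum)
  list(network = net, pairing = pairing, start = start)
}
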