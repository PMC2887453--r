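#' Read C-alpha coordinates from a PDB file
#'
#' Reduces a PDB entry to the residue-level representation used by elastic
#' network models: one bead per residue, placed at the C-alpha position of the
#' reference structure. Only `ATOM` records with atom name `CA` are consumed;
#' `HETATM` records (including waters and nucleotide analogs) and all other
#' atoms are ignored.
#'
#' Alternate locations are resolved per residue: records with altloc `' '` or
#' `'A'` are preferred, ties are broken by highest occupancy and then by file
#' order, so exactly one bead per residue identifier survives.
#'
#' @param file Path to a PDB file.
#' @param model For multi-model files, the 1-based model to read (default 1).
#' @param chains Optional character vector restricting the chains kept.
#' @return An object of class `calpha_structure`: a data frame with columns
#'   `chain`, `resno`, `insert`, `resid` (residue name) and coordinates
#'   `x`, `y`, `z` in Angstrom, one row per residue in file order.
#' @seealso [match_common_residues()], [build_network()], [write_calpha_pdb()]
#' @export
read_calpha <- function(file, model = 1L, chains = NULL) {
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  n_models <- nrow(pdb$xyz)
  if (is.null(n_models)) n_models <- 1L
  if (model < 1L || model > n_models) {
    stop("model ", model, " requested but file has ", n_models, " model(s)")
  }
  if (n_models > 1L) {
    xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
    atoms$x <- xyz[, 1L]; atoms$y <- xyz[, 2L]; atoms$z <- xyz[, 3L]
  }

  keep <- atoms$type == "ATOM" & atoms$elety == "CA"
  if (!is.null(chains)) keep <- keep & atoms$chain %in% chains
  ca <- atoms[keep, , drop = FALSE]
  if (nrow(ca) == 0L) stop("no CA ATOM records found in ", file)

  ca$insert[is.na(ca$insert)] <- ""
  ca$alt[is.na(ca$alt)] <- ""
  ca$chain[is.na(ca$chain)] <- ""
  occ <- ca$o
  occ[is.na(occ)] <- 1

  # altloc rule: ' '/'A' preferred, then occupancy, then record order
  pref <- ifelse(ca$alt %in% c("", "A"), 0L, 1L)
  ord <- order(pref, -occ, seq_len(nrow(ca)))
  ca <- ca[ord, , drop = FALSE]
  id <- paste(ca$chain, ca$resno, ca$insert, sep = "\r")
  ca <- ca[!duplicated(id), , drop = FALSE]
  ca <- ca[order(match(ca$eleno, atoms$eleno)), , drop = FALSE]  # restore file order

  out <- data.frame(
    chain = ca$chain, resno = as.integer(ca$resno), insert = ca$insert,
    resid = ca$resid, x = ca$x, y = ca$y, z = ca$z,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("calpha_structure", "data.frame")
  out
}

#' @export
print.calpha_structure <- function(x, ...) {
  cat("C-alpha structure:", nrow(x), "residues,",
      length(unique(x$chain)), "chain(s)\n")
  NextMethod()
  invisible(x)
}

#' Coordinate matrix of a structure
#'
#' @param structure A `calpha_structure`.
#' @return Numeric N x 3 matrix of coordinates (Angstrom).
#' @export
coords <- function(structure) {
  as.matrix(structure[, c("x", "y", "z")])
}

residue_ids <- function(structure) {
  paste(structure$chain, structure$resno, structure$insert, sep = "\r")
}

#' Pair residues present in two structures of the same protein
#'
#' Matches residues by identifier (chain, residue number, insertion code);
#' residue names are deliberately ignored so that mutant or analog-bound
#' structures of the same protein still pair. Only residues whose C-alpha
#' positions are contained in both structures enter the elastic network.
#'
#' @param a,b `calpha_structure` objects.
#' @param chain_map Optional named character vector translating chain
#'   identifiers of `b` into those of `a` (e.g. `c(X = "A")` treats chain X of
#'   `b` as chain A). Defaults to the identity mapping.
#' @return An object of class `residue_pairing`: a data frame with columns
#'   `index_a`, `index_b` (row indices into `a` and `b`), ordered as in `a`.
#' @export
match_common_residues <- function(a, b, chain_map = NULL) {
  stopifnot(nrow(a) > 0L, nrow(b) > 0L)
  chain_b <- b$chain
  if (!is.null(chain_map)) {
    hit <- chain_b %in% names(chain_map)
    chain_b[hit] <- unname(chain_map[chain_b[hit]])
  }
  id_a <- residue_ids(a)
  id_b <- paste(chain_b, b$resno, b$insert, sep = "\r")
  index_b <- match(id_a, id_b)
  keep <- !is.na(index_b)
  if (!any(keep)) stop("no residues in common between the two structures")
  out <- data.frame(index_a = which(keep), index_b = index_b[keep])
  class(out) <- c("residue_pairing", "data.frame")
  out
}

#' Write a CA-only PDB file, optionally with multiple models
#'
#' Emits minimal wwPDB v3.3 `ATOM` records carrying the bead coordinates, one
#' `MODEL`/`ENDMDL` block per frame when `frames` is given. Coordinates use the
#' PDB fixed-width `%8.3f` fields, so a read/write round trip preserves them to
#' three decimals.
#'
#' @param structure A `calpha_structure` providing residue identifiers.
#' @param file Output path.
#' @param frames Optional list of N x 3 coordinate matrices (trajectory
#'   snapshots). When `NULL`, the structure's own coordinates are written as a
#'   single model.
#' @return Invisibly, the output path.
#' @export
write_calpha_pdb <- function(structure, file, frames = NULL) {
  n <- nrow(structure)
  resid <- structure$resid
  resid[is.na(resid) | resid == ""] <- "GLY"
  fmt_block <- function(xyz) {
    sprintf("ATOM  %5d  CA  %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            seq_len(n), resid, substr(paste0(structure$chain, " "), 1L, 1L),
            structure$resno, substr(paste0(structure$insert, " "), 1L, 1L),
            xyz[, 1L], xyz[, 2L], xyz[, 3L], 1, 0)
  }
  if (is.null(frames)) {
    lines <- c(fmt_block(coords(structure)), "END")
  } else {
    lines <- unlist(lapply(seq_along(frames), function(k) {
      c(sprintf("MODEL     %4d", k), fmt_block(frames[[k]]), "ENDMDL")
    }))
    lines <- c(lines, "END")
  }
  writeLines(lines, file)
  invisible(file)
}
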