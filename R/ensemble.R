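#' Conformer ensembles
#'
#' A \code{ConformerEnsemble} holds an ordered set of atomic models sharing
#' one topology (same atoms, same order) together with simplex weights
#' \eqn{w_c} (non-negative, summing to one) and a per-conformer provenance
#' tag.  Coordinates follow the bio3d convention: one row per conformer of
#' the flattened \code{(x1, y1, z1, x2, ...)} vector, in Angstrom.
#'
#' @param atoms data.frame with columns \code{elety} (atom name),
#'   \code{resno} (1-based residue number), \code{chain}, \code{elesy}
#'   (element symbol).
#' @param xyz numeric matrix, one row per conformer, \code{3 * natom}
#'   columns.
#' @param weights optional numeric vector of conformer weights; defaults to
#'   uniform.  Renormalised to sum to one.
#' @param provenance optional character vector of free-text tags, recycled
#'   to the number of conformers.
#'
#' @return An object of class \code{ConformerEnsemble}.
#' @export
conformer_ensemble <- function(atoms, xyz, weights = NULL, provenance = "pool") {
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1L)
  stopifnot(is.matrix(xyz), nrow(xyz) >= 1L)
  natom <- nrow(atoms)
  if (ncol(xyz) != 3L * natom)
    stop("xyz has ", ncol(xyz), " columns; expected 3 * ", natom)
  nc <- nrow(xyz)
  if (is.null(weights)) weights <- rep(1 / nc, nc)
  if (length(weights) != nc)
    stop("weight count (", length(weights), ") != conformer count (", nc, ")")
  if (any(weights < 0)) stop("negative conformer weight")
  s <- sum(weights)
  if (s <= 0) stop("weights sum to zero")
  obj <- structure(list(
    atoms = atoms,
    xyz = unname(xyz),
    weights = as.numeric(weights / s),
    provenance = rep_len(as.character(provenance), nc)
  ), class = "ConformerEnsemble")
  obj
}

#' @export
print.ConformerEnsemble <- function(x, ...) {
  cat(sprintf("ConformerEnsemble: %d conformers, %d atoms, max weight %.3g\n",
              n_conformers(x), n_atoms(x), max(x$weights)))
  invisible(x)
}

#' Number of conformers in an ensemble
#' @param ens a \code{ConformerEnsemble}
#' @return integer count
#' @export
n_conformers <- function(ens) nrow(ens$xyz)

#' Number of atoms per conformer
#' @param ens a \code{ConformerEnsemble}
#' @return integer count
#' @export
n_atoms <- function(ens) nrow(ens$atoms)

#' Coordinates of one conformer as an n x 3 matrix
#' @param ens a \code{ConformerEnsemble}
#' @param i conformer index
#' @return numeric matrix with one row per atom
#' @export
conformer_coords <- function(ens, i) {
  matrix(ens$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Subset an ensemble by conformer index
#'
#' Weights of the retained conformers are renormalised to sum to one;
#' provenance tags travel with their conformers.
#'
#' @param ens a \code{ConformerEnsemble}
#' @param idx integer vector of conformer indices
#' @param weights optional replacement weights for the subset
#' @return a \code{ConformerEnsemble}
#' @export
subset_ensemble <- function(ens, idx, weights = NULL) {
  if (length(idx) < 1L) stop("empty conformer subset")
  w <- if (is.null(weights)) ens$weights[idx] else weights
  conformer_ensemble(ens$atoms, ens$xyz[idx, , drop = FALSE], w,
                     ens$provenance[idx])
}

#' Replace the weights of an ensemble
#' @param ens a \code{ConformerEnsemble}
#' @param weights numeric vector, one per conformer; renormalised
#' @return a \code{ConformerEnsemble}
#' @export
set_weights <- function(ens, weights) {
  conformer_ensemble(ens$atoms, ens$xyz, weights, ens$provenance)
}

#' Indices of the Calpha atoms
#' @param ens a \code{ConformerEnsemble}
#' @return integer vector of atom indices
#' @export
calpha_indices <- function(ens) which(ens$atoms$elety == "CA")

# --- file I/O ---------------------------------------------------------------

#' Read a conformer ensemble from a multi-model PDB file
#'
#' Models are read with \code{bio3d::read.pdb(multi = TRUE)} and checked for
#' identical topology.  Weights come from an optional sidecar table
#' (two whitespace-delimited columns: 1-based conformer index, weight);
#' without one, weights default to uniform.  Weights are renormalised to
#' sum to one.
#'
#' @param path multi-model PDB file (MODEL/ENDMDL records)
#' @param weights_path optional sidecar weight file
#' @param provenance provenance tag recorded on every conformer
#' @return a \code{ConformerEnsemble}
#' @export
read_ensemble <- function(path, weights_path = NULL, provenance = basename(path)) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- data.frame(
    elety = pdb$atom$elety,
    resno = pdb$atom$resno,
    chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
    elesy = ifelse(is.na(pdb$atom$elesy) | pdb$atom$elesy == "",
                   substr(trimws(pdb$atom$elety), 1L, 1L), pdb$atom$elesy),
    stringsAsFactors = FALSE
  )
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1L)
  w <- NULL
  if (!is.null(weights_path)) {
    w <- read_weights(weights_path)
    if (length(w) != nrow(xyz))
      stop("weight count (", length(w), ") != model count (", nrow(xyz),
           ") in ", path)
  }
  conformer_ensemble(atoms, xyz, w, provenance)
}

#' Write a conformer ensemble as a multi-model PDB file
#'
#' @param ens a \code{ConformerEnsemble}
#' @param path output PDB path
#' @param weights_path optional path for the sidecar weight table
#' @return \code{path}, invisibly
#' @export
write_ensemble <- function(ens, path, weights_path = NULL) {
  a <- ens$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_conformers(ens))) {
    co <- conformer_coords(ens, i)
    writeLines(sprintf("MODEL     %4d", i), con)
    nm <- ifelse(nchar(a$elety) < 4L, paste0(" ", a$elety), a$elety)
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(a)), nm, "ALA", a$chain, a$resno,
      co[, 1], co[, 2], co[, 3], a$elesy), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  if (!is.null(weights_path)) write_weights(ens$weights, weights_path)
  invisible(path)
}

#' Read a sidecar conformer-weight table
#'
#' Two whitespace-delimited columns (1-based conformer index, weight);
#' comment lines start with '#'.  Weights are renormalised to sum to one.
#'
#' @param path file path
#' @return numeric weight vector ordered by conformer index
#' @export
read_weights <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#")
  if (ncol(tab) < 2L) stop("weight file needs two columns (index, weight)")
  idx <- as.integer(tab[[1]])
  if (anyDuplicated(idx)) stop("duplicate conformer index in weight file")
  w <- numeric(max(idx))
  w[idx] <- as.numeric(tab[[2]])
  if (any(w < 0)) stop("negative weight in ", path)
  w / sum(w)
}

#' Write a sidecar conformer-weight table
#' @param weights numeric vector of weights
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_weights <- function(weights, path) {
  writeLines(c("# conformer_index weight",
               sprintf("%d %.12g", seq_along(weights), weights)), path)
  invisible(path)
}

#' Verify that every conformer shares one topology
#'
#' For ensembles built through \code{\link{conformer_ensemble}} the atom
#' table is shared by construction; this check compares two ensembles that
#' are about to be pooled.
#'
#' @param a,b \code{ConformerEnsemble} objects
#' @return \code{TRUE}, or an error naming the first divergent atom
#' @export
check_topology <- function(a, b) {
  if (n_atoms(a) != n_atoms(b))
    stop("topology mismatch: ", n_atoms(a), " vs ", n_atoms(b), " atoms")
  same <- a$atoms$elety == b$atoms$elety & a$atoms$resno == b$atoms$resno
  if (!all(same)) {
    i <- which(!same)[1]
    stop(sprintf("topology mismatch at atom %d: %s/%d vs %s/%d", i,
                 a$atoms$elety[i], a$atoms$resno[i],
                 b$atoms$elety[i], b$atoms$resno[i]))
  }
  TRUE
}

# --- amide proton reconstruction -------------------------------------------

#' Reconstruct backbone amide protons from heavy-atom geometry
#'
#' Protonless models (e.g. structure predictions) lack the amide H needed
#' as PRE target.  One H is placed per eligible backbone N: in the peptide
#' plane, along the negative bisector of the unit vectors N->CA and
#' N->C(previous residue), at an N-H bond length of 1.01 Angstrom.  The
#' first residue, prolines and residues already carrying an H are skipped;
#' residues with collinear N/CA/C(prev) are skipped with a warning.
#'
#' @param atoms atom table (columns \code{elety}, \code{resno}, \code{chain},
#'   \code{elesy}, optionally \code{resid})
#' @param coords n x 3 coordinate matrix matching \code{atoms}
#' @return list with updated \code{atoms} and \code{coords} (H rows appended
#'   after each residue's N)
#' @export
reconstruct_amide_protons <- function(atoms, coords) {
  resid <- if ("resid" %in% names(atoms)) atoms$resid else rep("ALA", nrow(atoms))
  res <- sort(unique(atoms$resno))
  out_a <- list(); out_c <- list()
  row_of <- function(rn, name) which(atoms$resno == rn & atoms$elety == name)[1]
  for (rn in res) {
    rows <- which(atoms$resno == rn)
    out_a[[length(out_a) + 1L]] <- atoms[rows, , drop = FALSE]
    out_c[[length(out_c) + 1L]] <- coords[rows, , drop = FALSE]
    has_h <- any(atoms$elety[rows] %in% c("H", "HN"))
    is_pro <- any(resid[rows] == "PRO")
    if (has_h || is_pro || rn == res[1]) next
    iN <- row_of(rn, "N"); iCA <- row_of(rn, "CA"); iC <- row_of(rn - 1L, "C")
    if (anyNA(c(iN, iCA, iC))) next
    n <- coords[iN, ]; u <- coords[iCA, ] - n; v <- coords[iC, ] - n
    u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
    b <- u + v
    nb <- sqrt(sum(b^2))
    if (nb < 1e-8) {
      warning("collinear N/CA/C(prev) at residue ", rn, "; H skipped")
      next
    }
    h <- n - 1.01 * b / nb
    ha <- atoms[iN, , drop = FALSE]
    ha$elety <- "H"; ha$elesy <- "H"
    out_a[[length(out_a) + 1L]] <- ha
    out_c[[length(out_c) + 1L]] <- matrix(h, 1L)
  }
  list(atoms = do.call(rbind, out_a), coords = do.call(rbind, out_c))
}
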