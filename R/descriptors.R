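# Ensemble-level structural descriptors: weighted radius of gyration,
# distance-RMSD matrices, the abstract-conformer-space disorder parameter,
# contact maps, binding-pose checks and merged-pool cluster analysis.

#' Radius of gyration of an ensemble
#'
#' Per-conformer radii over Calpha positions, combined as the
#' weight-averaged RMS \eqn{R_g = \sqrt{\sum_c w_c R_{g,c}^2}}.
#'
#' @param ens a \code{ConformerEnsemble}
#' @return list with \code{rg} (ensemble, Angstrom) and \code{per_conformer}
#' @export
radius_of_gyration <- function(ens) {
  ca <- calpha_indices(ens)
  if (!length(ca)) stop("no Calpha atoms")
  per <- vapply(seq_len(n_conformers(ens)), function(i) {
    x <- conformer_coords(ens, i)[ca, , drop = FALSE]
    mu <- colMeans(x)
    sqrt(mean(rowSums(sweep(x, 2L, mu, "-")^2)))
  }, numeric(1))
  list(rg = sqrt(sum(ens$weights * per^2)), per_conformer = per)
}

# matrix of per-conformer internal Calpha-pair distances (C x n_pairs)
.internal_distances <- function(ens, stride = 1L) {
  ca <- calpha_indices(ens)
  ca <- ca[seq(1L, length(ca), by = stride)]
  nc <- n_conformers(ens)
  t(vapply(seq_len(nc), function(i) {
    x <- conformer_coords(ens, i)[ca, , drop = FALSE]
    as.vector(stats::dist(x))
  }, numeric(length(ca) * (length(ca) - 1L) / 2L)))
}

#' Distance-RMSD matrix between all conformer pairs
#'
#' \eqn{D_{kl}} is the RMS over all Calpha index pairs (i < j) of the
#' difference of internal distances \eqn{d_{ij}(k) - d_{ij}(l)}: a
#' superposition-free measure of global shape difference with the
#' properties of a Euclidean distance.
#'
#' @param ens a \code{ConformerEnsemble} with >= 2 conformers
#' @param stride keep every stride-th Calpha (1 = all)
#' @return symmetric matrix (Angstrom) with zero diagonal
#' @export
drmsd_matrix <- function(ens, stride = 1L) {
  if (n_conformers(ens) < 2L) stop("need at least two conformers")
  V <- .internal_distances(ens, stride)
  P <- ncol(V)
  sq <- rowSums(V^2)
  g <- tcrossprod(V)
  d2 <- (outer(sq, rep(1, length(sq))) + outer(rep(1, length(sq)), sq) -
           2 * g) / P
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Disorder parameter via abstract conformer space
#'
#' The \eqn{D_{kl}} matrix is embedded by classical multidimensional
#' scaling (double-centred squared distances, eigendecomposition, negative
#' eigenvalues truncated to zero).  The embedded point set's weighted
#' radius of gyration \eqn{R_{g,ACS}} (weighted centroid, weights
#' \eqn{w_c}) measures global shape diversity; the dimensionless disorder
#' parameter is \eqn{\delta = R_{g,ACS} / R_g}.  Roughly 0.1 for rigid
#' folded ensembles and 0.6-0.8 for random-coil-like ensembles.
#'
#' @param ens a \code{ConformerEnsemble}
#' @param d_kl optional precomputed \code{\link{drmsd_matrix}}
#' @param stride passed to \code{\link{drmsd_matrix}}
#' @return list with \code{rg_acs}, \code{delta}, \code{rg}
#' @export
disorder_parameter <- function(ens, d_kl = NULL, stride = 1L) {
  nc <- n_conformers(ens)
  if (nc < 2L) return(list(rg_acs = 0, delta = 0,
                           rg = radius_of_gyration(ens)$rg))
  if (is.null(d_kl)) d_kl <- drmsd_matrix(ens, stride)
  if (max(d_kl) < 1e-12) {
    # all conformers identical: no spread, not an error
    return(list(rg_acs = 0, delta = 0, rg = radius_of_gyration(ens)$rg))
  }
  mds <- stats::cmdscale(d_kl, k = nc - 1L, eig = TRUE)
  keep <- which(mds$eig > 1e-9 * max(mds$eig))
  X <- mds$points[, keep, drop = FALSE]
  w <- ens$weights
  centre <- colSums(X * w)
  rg_acs <- sqrt(sum(w * rowSums(sweep(X, 2L, centre, "-")^2)))
  rg <- radius_of_gyration(ens)$rg
  list(rg_acs = rg_acs, delta = rg_acs / rg, rg = rg)
}

#' Weighted inter-group contact map
#'
#' Residue pair (a in A, b in B) is in contact in a conformer iff the
#' minimum atom-pair distance is at or below the cutoff (default 3
#' Angstrom).  The reported fraction is the summed weight of contacting
#' conformers; with uniform weights this equals count / C.
#'
#' @param ens a \code{ConformerEnsemble}
#' @param group_a,group_b residue-number sets (non-empty, non-overlapping
#'   groups are the intended use)
#' @param cutoff contact cutoff (Angstrom, > 0)
#' @return list with \code{pairs} (data.frame res_a, res_b, fraction, for
#'   pairs with non-zero fraction), \code{per_residue_a},
#'   \code{per_residue_b} (total contact fraction by residue)
#' @export
contact_map <- function(ens, group_a, group_b, cutoff = 3.0) {
  if (!length(group_a) || !length(group_b)) stop("empty residue group")
  if (cutoff < 0) stop("cutoff must be >= 0")
  atoms <- ens$atoms
  ia <- which(atoms$resno %in% group_a)
  ib <- which(atoms$resno %in% group_b)
  if (!length(ia) || !length(ib)) stop("residue group matches no atoms")
  ra <- atoms$resno[ia]; rb <- atoms$resno[ib]
  ua <- sort(unique(ra)); ub <- sort(unique(rb))
  frac <- matrix(0, length(ua), length(ub), dimnames = list(ua, ub))
  for (c_ in seq_len(n_conformers(ens))) {
    co <- conformer_coords(ens, c_)
    pa <- co[ia, , drop = FALSE]; pb <- co[ib, , drop = FALSE]
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
    d2[d2 < 0] <- 0
    hit <- sqrt(d2) <= cutoff
    # residue-level contact: any atom pair within cutoff
    agg <- rowsum(1 * hit, ra)                     # residues a x atoms b
    agg <- t(rowsum(t(agg), rb))                   # residues a x residues b
    frac <- frac + ens$weights[c_] * (agg[as.character(ua), as.character(ub),
                                         drop = FALSE] > 0)
  }
  nz <- which(frac > 0, arr.ind = TRUE)
  pairs <- data.frame(res_a = ua[nz[, 1]], res_b = ub[nz[, 2]],
                      fraction = frac[nz])
  pairs <- pairs[order(-pairs$fraction), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       per_residue_a = rowSums(frac),
       per_residue_b = colSums(frac),
       fraction_matrix = frac)
}

#' Format a contact fraction as a report percentage
#' @param fraction numeric fraction in [0, 1]
#' @return character, one decimal percent (e.g. "2.9 %")
#' @export
format_contact_fraction <- function(fraction) {
  sprintf("%.1f %%", 100 * fraction)
}

#' Binding-pose check by shortest cross-set distance
#'
#' The shortest atom-atom distance between a binding-motif atom set and a
#' domain atom set; the pose passes if it is below the threshold
#' (default 7.5 Angstrom).
#'
#' @param coords_motif,coords_domain non-empty n x 3 coordinate matrices
#' @param threshold pass threshold (Angstrom)
#' @return list with \code{min_distance} and \code{pass}
#' @export
binding_pose_check <- function(coords_motif, coords_domain, threshold = 7.5) {
  if (!nrow(coords_motif) || !nrow(coords_domain)) stop("empty atom set")
  d2 <- outer(rowSums(coords_motif^2), rowSums(coords_domain^2), "+") -
    2 * tcrossprod(coords_motif, coords_domain)
  mind <- sqrt(max(0, min(d2)))
  list(min_distance = mind, pass = mind < threshold)
}

#' Ensemble summary of binding-pose checks
#'
#' Runs \code{\link{binding_pose_check}} on every conformer for one or two
#' motif/domain set pairs and reports the count and weight fraction of
#' conformers passing all checks.
#'
#' @param ens a \code{ConformerEnsemble}
#' @param checks list of entries \code{list(motif = residues, domain =
#'   residues)}
#' @param threshold pass threshold (Angstrom)
#' @return list with \code{per_conformer} (data.frame of min distances and
#'   pass flags), \code{n_pass}, \code{weight_fraction}
#' @export
binding_pose_summary <- function(ens, checks, threshold = 7.5) {
  atoms <- ens$atoms
  rows <- lapply(seq_len(n_conformers(ens)), function(c_) {
    co <- conformer_coords(ens, c_)
    res <- vapply(checks, function(ch) {
      im <- which(atoms$resno %in% ch$motif)
      idm <- which(atoms$resno %in% ch$domain)
      binding_pose_check(co[im, , drop = FALSE], co[idm, , drop = FALSE],
                         threshold)$min_distance
    }, numeric(1))
    data.frame(conformer = c_, t(res), pass = all(res < threshold))
  })
  per <- do.call(rbind, rows)
  list(per_conformer = per,
       n_pass = sum(per$pass),
       weight_fraction = sum(ens$weights[per$pass]))
}

#' Cluster analysis of two merged ensembles
#'
#' Pools two ensembles (compatible topology), computes the distance-RMSD
#' matrix, cuts an average-linkage dendrogram into round(C / mean cluster
#' size) clusters and classifies each cluster as mixed, A-only or B-only
#' by member provenance.  Reported class fractions are summed member
#' weights, normalised within each source ensemble.
#'
#' @param ens_a,ens_b \code{ConformerEnsemble} objects
#' @param mean_cluster_size target mean conformers per cluster (default 12)
#' @param stride Calpha stride for the distance matrix
#' @return list with \code{clusters} (per-conformer assignment and
#'   source), \code{classes} (per-cluster class), \code{fractions}
#'   (weight fraction of each class: mixed, a_only, b_only)
#' @export
merged_cluster_analysis <- function(ens_a, ens_b, mean_cluster_size = 12L,
                                    stride = 1L) {
  check_topology(ens_a, ens_b)
  merged <- conformer_ensemble(
    ens_a$atoms, rbind(ens_a$xyz, ens_b$xyz),
    c(ens_a$weights, ens_b$weights) / 2,
    c(rep("A", n_conformers(ens_a)), rep("B", n_conformers(ens_b))))
  nc <- n_conformers(merged)
  k <- max(2L, round(nc / mean_cluster_size))
  if (nc < 2L) stop("need at least 2 conformers for clustering")
  d <- drmsd_matrix(merged, stride)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(hc, k = k)
  src <- merged$provenance
  classes <- vapply(seq_len(k), function(i) {
    s <- unique(src[cl == i])
    if (length(s) == 2L) "mixed" else if (s == "A") "a_only" else "b_only"
  }, character(1))
  # per-source normalised weights
  wa <- ens_a$weights; wb <- ens_b$weights
  w_src <- c(wa / sum(wa), wb / sum(wb)) / 2   # each source contributes 1/2
  frac <- c(mixed = 0, a_only = 0, b_only = 0)
  for (i in seq_len(k))
    frac[classes[i]] <- frac[classes[i]] + sum(w_src[cl == i])
  list(clusters = data.frame(conformer = seq_len(nc), source = src,
                             cluster = cl),
       classes = classes,
       fractions = frac / sum(frac))
}
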