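# Spin-label site model and forward prediction of DEER distance
# distributions and PRE rates.  The label is a pluggable point cloud
# standing in for a full rotamer library: each registered model maps
# (conformer geometry, attachment residue) to weighted positions of the
# unpaired electron.

.label_models <- new.env(parent = emptyenv())

#' Register a spin-label cloud model
#'
#' A model is a function \code{f(ca, direction, seed, ...)} returning a
#' list with \code{points} (n x 3 matrix, Angstrom) and \code{weights}
#' (summing to one), where \code{ca} is the attachment-residue Calpha
#' position and \code{direction} the unit outward direction.
#'
#' @param name model name
#' @param fn generator function
#' @return \code{name}, invisibly
#' @export
register_label_model <- function(name, fn) {
  assign(name, fn, envir = .label_models)
  invisible(name)
}

#' Names of registered label models
#' @return character vector
#' @export
label_models <- function() ls(.label_models)

# run expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.default_models <- function() {
  register_label_model("gauss_cloud", function(ca, direction, seed,
                                               n_points = 64L,
                                               sigma = 2.5, offset = 7.0) {
    centre <- ca + offset * direction
    pts <- with_seed(seed, matrix(stats::rnorm(3L * n_points, sd = sigma),
                                  ncol = 3L, byrow = TRUE))
    pts <- sweep(pts, 2L, centre, "+")
    list(points = pts, weights = rep(1 / n_points, n_points))
  })
  register_label_model("point", function(ca, direction, seed, offset = 7.0) {
    list(points = matrix(ca + offset * direction, 1L), weights = 1)
  })
}

#' Attach a spin-label cloud to one conformer
#'
#' The default \code{gauss_cloud} model draws 64 points from an isotropic
#' Gaussian (sigma 2.5 Angstrom) centred 7 Angstrom from the attachment
#' residue's Calpha along the local outward direction (Calpha minus the
#' centroid of the residue's domain, unit-normalised), with uniform point
#' weights.  Deterministic given the seed.
#'
#' @param atoms atom table of the conformer
#' @param coords n x 3 coordinate matrix
#' @param residue attachment residue number
#' @param model registered model name
#' @param seed integer seed
#' @param domain_residues residue numbers defining the site's domain (for
#'   the outward direction); defaults to all residues
#' @param ... passed to the model generator
#' @return list with \code{points}, \code{weights}, \code{residue}
#' @export
attach_label <- function(atoms, coords, residue, model = "gauss_cloud",
                         seed = 1L, domain_residues = NULL, ...) {
  if (!model %in% label_models())
    stop("unknown label model '", model, "'; registered: ",
         paste(label_models(), collapse = ", "))
  ica <- which(atoms$resno == residue & atoms$elety == "CA")
  if (length(ica) != 1L) stop("no unique CA for residue ", residue)
  ca <- coords[ica, ]
  dom <- if (is.null(domain_residues)) unique(atoms$resno) else domain_residues
  idom <- which(atoms$resno %in% dom & atoms$elety == "CA")
  centroid <- colMeans(coords[idom, , drop = FALSE])
  dir <- ca - centroid
  nd <- sqrt(sum(dir^2))
  dir <- if (nd < 1e-8) c(1, 0, 0) else dir / nd
  fn <- get(model, envir = .label_models)
  cl <- fn(ca, dir, seed, ...)
  cl$residue <- residue
  cl
}

# deterministic seed offset from conformer geometry (rounded to PDB
# precision), so a cloud is a function of the conformer like a rotamer
# library, not of the conformer's position in an ensemble
.coord_hash <- function(coords) {
  v <- round(as.vector(coords), 2L)
  as.integer(round(sum(abs(v)) * 100) %% 900000L)
}

#' Build a label site across all conformers of an ensemble
#'
#' Calls \code{\link{attach_label}} on every conformer.  The per-conformer
#' seed is derived from the conformer geometry, so identical conformers
#' get identical clouds regardless of which ensemble they sit in (the
#' behaviour of a deterministic rotamer library).
#'
#' @param ens a \code{ConformerEnsemble}
#' @param residue attachment residue number
#' @param id site id
#' @param model registered label model name
#' @param seed base seed
#' @param domain_residues residue numbers of the site's domain
#' @param ... passed to the model generator
#' @return object of class \code{LabelSite}: list with \code{id},
#'   \code{residue}, \code{model}, \code{clouds} (one per conformer)
#' @export
label_site <- function(ens, residue, id = paste0("R", residue),
                       model = "gauss_cloud", seed = 1L,
                       domain_residues = NULL, ...) {
  clouds <- lapply(seq_len(n_conformers(ens)), function(i) {
    co <- conformer_coords(ens, i)
    attach_label(ens$atoms, co, residue, model,
                 seed = seed + .coord_hash(co),
                 domain_residues = domain_residues, ...)
  })
  structure(list(id = id, residue = residue, model = model, clouds = clouds),
            class = "LabelSite")
}

#' Centroid of a spin-label cloud and its anchor distances
#'
#' The centroid is the point-weighted mean of the cloud (the analogue of a
#' dummy atom placed at the centre of the spin cloud).  Anchor distances
#' are the distances from the centroid to a chosen set of reference Calpha
#' atoms; they are used to pin the centroid in the domain frame.
#'
#' @param cloud label cloud (list with \code{points}, \code{weights})
#' @param atoms atom table of the conformer
#' @param coords conformer coordinates (n x 3)
#' @param anchors residue numbers of the anchor Calpha atoms (>= 1)
#' @return list with \code{centroid} (length-3), \code{anchor_distances}
#'   (named by residue)
#' @export
cloud_centroid <- function(cloud, atoms, coords, anchors) {
  if (length(anchors) < 1L) stop("need at least one anchor residue")
  centroid <- colSums(cloud$points * cloud$weights)
  d <- vapply(anchors, function(rn) {
    i <- which(atoms$resno == rn & atoms$elety == "CA")
    if (length(i) != 1L) stop("no unique CA for anchor residue ", rn)
    sqrt(sum((coords[i, ] - centroid)^2))
  }, numeric(1))
  names(d) <- anchors
  list(centroid = centroid, anchor_distances = d)
}

#' Verify a centroid placement against recorded anchor distances
#'
#' Asserts that a placed centroid reproduces each recorded anchor distance
#' within a tolerance (default +-0.2 Angstrom, the restraint width used to
#' pin spin-cloud centres in rigid frames).
#'
#' @param centroid placed centroid position (length-3)
#' @param atoms,coords conformer the anchors live on
#' @param anchor_distances named vector (residue -> distance) as produced
#'   by \code{\link{cloud_centroid}}
#' @param tol tolerance in Angstrom
#' @return \code{TRUE} or an error naming the first violated anchor
#' @export
verify_centroid_placement <- function(centroid, atoms, coords,
                                      anchor_distances, tol = 0.2) {
  for (rn in names(anchor_distances)) {
    i <- which(atoms$resno == as.integer(rn) & atoms$elety == "CA")
    d <- sqrt(sum((coords[i, ] - centroid)^2))
    if (abs(d - anchor_distances[[rn]]) > tol)
      stop(sprintf("anchor %s: placed distance %.3f A deviates from %.3f A by more than %.2f A",
                   rn, d, anchor_distances[[rn]], tol))
  }
  TRUE
}

# --- forward prediction -----------------------------------------------------

# mass vector on `grid` from weighted distances, by linear (first-moment
# preserving) binning followed by discrete Gaussian smoothing
.smooth_mass <- function(d, w, grid, sigma) {
  step <- grid[2] - grid[1]
  nb <- length(grid)
  pos <- (d - grid[1]) / step
  lo <- floor(pos)
  frac <- pos - lo
  m <- numeric(nb)
  ok <- lo >= 0 & lo < nb - 1L
  exact <- lo == nb - 1L & frac < 1e-12
  if (any(ok)) {
    i <- lo[ok] + 1L
    m_add <- w[ok]
    tab1 <- tapply(m_add * (1 - frac[ok]), i, sum)
    tab2 <- tapply(m_add * frac[ok], i + 1L, sum)
    m[as.integer(names(tab1))] <- m[as.integer(names(tab1))] + tab1
    m[as.integer(names(tab2))] <- m[as.integer(names(tab2))] + tab2
  }
  if (any(exact)) m[nb] <- m[nb] + sum(w[exact])
  outside <- 1 - sum(m) / sum(w)
  if (sigma > 0) {
    half <- max(1L, ceiling(4 * sigma / step))
    kern <- stats::dnorm(seq(-half, half) * step, sd = sigma)
    kern <- kern / sum(kern)
    padded <- c(numeric(half), m, numeric(half))
    sm <- stats::filter(padded, kern, sides = 2)
    m <- as.numeric(sm[(half + 1L):(half + nb)])
  }
  attr(m, "outside") <- outside
  m
}

# all cross-cloud distances and product weights
.cloud_pair_distances <- function(ca_, cb) {
  pa <- ca_$points; pb <- cb$points
  a2 <- rowSums(pa^2); b2 <- rowSums(pb^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(pa, pb)
  d2[d2 < 0] <- 0
  list(d = sqrt(as.vector(d2)),
       w = as.vector(outer(ca_$weights, cb$weights)))
}

#' Per-conformer distance-distribution mass matrix
#'
#' For each conformer, all cross-pair point distances between the two
#' label clouds are accumulated with product point weights, smoothed by a
#' Gaussian kernel onto the grid and normalised to unit mass.  Columns of
#' the returned matrix are the per-conformer distributions; the ensemble
#' prediction for weights w is the matrix-vector product.
#'
#' @param ens a \code{ConformerEnsemble}
#' @param site_a,site_b \code{LabelSite} objects built on \code{ens}
#' @param grid uniform distance grid (Angstrom)
#' @param kernel_sigma Gaussian kernel width (Angstrom)
#' @return matrix \code{length(grid) x n_conformers}, columns summing to 1
#' @export
predict_dd_matrix <- function(ens, site_a, site_b, grid, kernel_sigma = 1.0) {
  nc <- n_conformers(ens)
  out <- matrix(0, length(grid), nc)
  for (i in seq_len(nc)) {
    pd <- .cloud_pair_distances(site_a$clouds[[i]], site_b$clouds[[i]])
    m <- .smooth_mass(pd$d, pd$w, grid, kernel_sigma)
    if (attr(m, "outside") > 0.01)
      stop(sprintf("grid %.0f-%.0f A misses %.1f%% of distance mass; widen the grid",
                   min(grid), max(grid), 100 * attr(m, "outside")))
    out[, i] <- m / sum(m)
  }
  out
}

#' Predict an ensemble distance distribution
#'
#' Weighted mixture \eqn{\sum_c w_c P_c} of the per-conformer
#' distributions, returned as a normalised \code{DistanceDistribution}.
#'
#' @inheritParams predict_dd_matrix
#' @return a \code{DistanceDistribution}
#' @export
predict_distance_distribution <- function(ens, site_a, site_b, grid,
                                          kernel_sigma = 1.0) {
  mat <- predict_dd_matrix(ens, site_a, site_b, grid, kernel_sigma)
  mass <- as.vector(mat %*% ens$weights)
  distance_distribution(grid, mass / (grid[2] - grid[1]))
}

#' Per-conformer PRE rate matrix
#'
#' For conformer c and target residue t, the effective electron-amide
#' distance is the r^-6-weighted cloud average
#' \eqn{r_{eff} = (\sum_k p_k r_k^{-6})^{-1/6}} and the conformer rate is
#' the Solomon-Bloembergen forward value at \eqn{r_{eff}}.  Rates are NOT
#' clipped here: clipping applies to ensemble averages (see
#' \code{\link{predict_pre}}).  Target positions are the amide H when
#' present, else the Calpha as proxy.
#'
#' @param ens a \code{ConformerEnsemble}
#' @param site a \code{LabelSite}
#' @param targets target residue numbers
#' @param tau_c correlation time (s)
#' @param omega_h 1H Larmor frequency (rad/s)
#' @param K PRE proportionality constant (cm^6 s^-2)
#' @return matrix \code{length(targets) x n_conformers} of Gamma2 (s^-1)
#' @export
predict_pre_matrix <- function(ens, site, targets, tau_c, omega_h,
                               K = 1.23e-32) {
  atoms <- ens$atoms
  tidx <- vapply(targets, function(rn) {
    i <- which(atoms$resno == rn & atoms$elety %in% c("H", "HN"))
    if (!length(i)) i <- which(atoms$resno == rn & atoms$elety == "CA")
    if (length(i) != 1L) stop("no amide H or CA for target residue ", rn)
    i
  }, integer(1))
  nc <- n_conformers(ens)
  out <- matrix(0, length(targets), nc)
  for (i in seq_len(nc)) {
    co <- conformer_coords(ens, i)
    cl <- site$clouds[[i]]
    tp <- co[tidx, , drop = FALSE]
    a2 <- rowSums(tp^2); b2 <- rowSums(cl$points^2)
    d2 <- outer(a2, b2, "+") - 2 * tcrossprod(tp, cl$points)
    if (any(d2 < 1e-12)) stop("label cloud point on top of a target atom")
    r6inv <- d2^(-3)                     # (r^2)^-3 = r^-6, r in Angstrom
    m6 <- as.vector(r6inv %*% cl$weights)
    r_eff <- m6^(-1 / 6)
    out[, i] <- distance_to_gamma2(r_eff, tau_c, omega_h, K)
  }
  rownames(out) <- targets
  out
}

#' Predict ensemble PRE rates
#'
#' Ensemble rate per residue is the weighted mean of the per-conformer
#' rates, clipped to the detection cap after averaging.
#'
#' @inheritParams predict_pre_matrix
#' @param cap detection-limit rate (s^-1)
#' @return data.frame with \code{residue}, \code{gamma2}
#' @export
predict_pre <- function(ens, site, targets, tau_c, omega_h, cap = 170,
                        K = 1.23e-32) {
  mat <- predict_pre_matrix(ens, site, targets, tau_c, omega_h, K)
  g <- pmin(as.vector(mat %*% ens$weights), cap)
  data.frame(residue = targets, gamma2 = g)
}
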