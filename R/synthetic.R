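# Synthetic two-domain test systems: two rigid Calpha-bead domains joined
# by a flexible fixed-bond-length linker, spin-label sites, and simulated
# noisy restraints with known ground truth.  The generator emulates the
# geometry of a tandem-RRM construct (two folded ~70-residue domains, a
# ~30-residue disordered linker) at Calpha resolution; amide positions are
# approximated by the Calpha positions.

#' Specify a toy two-domain system
#'
#' Domains are rigid Calpha clouds sampled once (seeded) from a ball of
#' radius 10 Angstrom; the linker is re-sampled per conformer as a random
#' chain with fixed virtual bond length.  Residues are numbered
#' consecutively: domain 1, linker, domain 2.
#'
#' @param domain1,domain2 residues per rigid domain
#' @param linker linker length in residues (>= 1)
#' @param bond virtual Calpha-Calpha bond length (Angstrom)
#' @param label_sites named integer vector of label-site residues;
#'   defaults to three per domain plus one linker site
#' @param motif_residues residues used as binding-motif anchors in pose
#'   checks (defaults to three central domain-2 residues)
#' @param domain_radius radius of the ball the domain beads are drawn from
#' @param mode_directions optional list of unit vectors; when given, each
#'   conformer's linker is biased towards one of them, producing distinct
#'   rigid-body arrangements of domain 2 (e.g. two for a bimodal system)
#' @param mode_bias strength of the directional bias
#' @param seed seed for the one-off domain templates
#' @return object of class \code{ToySystemSpec}
#' @export
toy_system_spec <- function(domain1 = 70L, domain2 = 70L, linker = 30L,
                            bond = 3.8, label_sites = NULL,
                            motif_residues = NULL, domain_radius = 10,
                            mode_directions = NULL, mode_bias = 2.0,
                            seed = 1L) {
  stopifnot(linker >= 1L, domain1 >= 2L, domain2 >= 2L)
  n1 <- as.integer(domain1); nl <- as.integer(linker); n2 <- as.integer(domain2)
  d1_res <- seq_len(n1)
  link_res <- n1 + seq_len(nl)
  d2_res <- n1 + nl + seq_len(n2)
  if (is.null(label_sites)) {
    label_sites <- c(
      A1 = d1_res[max(1L, round(n1 * 0.15))],
      A2 = d1_res[round(n1 * 0.5)],
      A3 = d1_res[round(n1 * 0.85)],
      L1 = link_res[max(1L, round(nl * 0.5))],
      B1 = d2_res[max(1L, round(n2 * 0.15))],
      B2 = d2_res[round(n2 * 0.5)],
      B3 = d2_res[round(n2 * 0.85)])
  }
  all_res <- c(d1_res, link_res, d2_res)
  if (!all(label_sites %in% all_res))
    stop("label site outside the generated topology")
  if (is.null(motif_residues)) motif_residues <- d2_res[round(n2 * c(0.4, 0.5, 0.6))]

  # rigid templates, sampled once per spec: uniform in a ball
  ball <- function(n, r, sd_seed) with_seed(sd_seed, {
    u <- matrix(stats::rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    u * r * stats::runif(n)^(1 / 3)
  })
  t1 <- ball(n1, domain_radius, seed)
  t2 <- ball(n2, domain_radius, seed + 1L)
  # domain 1 frame: attachment residue (last bead) at the origin
  t1 <- sweep(t1, 2L, t1[n1, ], "-")
  # domain 2 frame: attachment residue (first bead) at the origin
  t2 <- sweep(t2, 2L, t2[1L, ], "-")

  structure(list(
    n1 = n1, nl = nl, n2 = n2, bond = bond,
    d1_res = d1_res, link_res = link_res, d2_res = d2_res,
    label_sites = label_sites, motif_residues = motif_residues,
    template1 = t1, template2 = t2, domain_radius = domain_radius,
    mode_directions = mode_directions, mode_bias = mode_bias,
    seed = seed
  ), class = "ToySystemSpec")
}

#' @export
print.ToySystemSpec <- function(x, ...) {
  cat(sprintf("ToySystemSpec: %d + %d residues, %d-residue linker, %d label sites\n",
              x$n1, x$n2, x$nl, length(x$label_sites)))
  invisible(x)
}

#' Atom table of a toy system (Calpha beads)
#' @param spec a \code{ToySystemSpec}
#' @return data.frame usable as a \code{ConformerEnsemble} atom table
#' @export
toy_atoms <- function(spec) {
  n <- spec$n1 + spec$nl + spec$n2
  data.frame(elety = "CA", resno = seq_len(n), chain = "A", elesy = "C",
             stringsAsFactors = FALSE)
}

# random 3x3 rotation (uniform over SO(3), via quaternion)
.random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

# one conformer: domain1 fixed, linker grown bead by bead with the 3 A
# self-avoidance rule (clashing steps re-drawn), domain2 at the chain end
.sample_conformer <- function(spec, max_attempts = 100L) {
  b <- spec$bond
  d1 <- spec$template1
  for (attempt in seq_len(max_attempts)) {
    bias <- c(0, 0, 0)
    if (!is.null(spec$mode_directions)) {
      k <- sample.int(length(spec$mode_directions), 1L)
      bias <- spec$mode_bias * spec$mode_directions[[k]]
    }
    # grow the chain: linker beads then the domain-2 attachment bead
    n_grow <- spec$nl + 1L
    walk <- matrix(0, n_grow, 3L)
    prev <- c(0, 0, 0)                      # domain-1 attachment bead
    failed <- FALSE
    for (j in seq_len(n_grow)) {
      placed <- FALSE
      for (try in seq_len(max_attempts)) {
        st <- stats::rnorm(3) + bias
        st <- st / sqrt(sum(st^2)) * b
        pos <- prev + st
        # non-bonded clashes: earlier linker beads (excluding the bonded
        # predecessor) and all domain-1 beads except its attachment bead
        prior <- if (j > 2L) walk[seq_len(j - 2L), , drop = FALSE] else
          matrix(numeric(0), 0L, 3L)
        clash <- (nrow(prior) > 0 &&
                    min(rowSums(sweep(prior, 2L, pos, "-")^2)) < 9) ||
          (j > 1L &&
             min(rowSums(sweep(d1[-spec$n1, , drop = FALSE], 2L, pos,
                               "-")^2)) < 9)
        if (!clash) { walk[j, ] <- pos; prev <- pos; placed <- TRUE; break }
      }
      if (!placed) { failed <- TRUE; break }
    }
    if (failed) next
    link <- walk[seq_len(spec$nl), , drop = FALSE]
    att2 <- walk[n_grow, ]
    # orient domain 2 at the chain end; re-draw clashing orientations
    for (try in seq_len(max_attempts)) {
      rot <- .random_rotation()
      dom2 <- sweep(spec$template2 %*% t(rot), 2L, att2, "+")
      cross2 <- .min_cross_dist(link, dom2, exclude_a = spec$nl,
                                exclude_b = 1L)
      cross12 <- .min_cross_dist(d1, dom2)
      if (min(cross2, cross12) >= 3.0)
        return(rbind(d1, link, dom2))
    }
  }
  stop("self-avoidance failed after ", max_attempts,
       " attempts; consider a longer linker")
}

# minimum cross-set distance with one optionally excluded (bonded) pair
.min_cross_dist <- function(a, b, exclude_a = NULL, exclude_b = NULL) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  if (!is.null(exclude_a)) d2[exclude_a, exclude_b] <- Inf
  sqrt(max(0, min(d2)))
}

#' Build a conformer pool for a toy system
#'
#' Each conformer keeps both domains internally rigid (identical up to a
#' rigid-body transform) and re-samples the linker as a fixed-bond-length
#' random chain with a soft self-avoidance check (non-bonded bead pairs
#' closer than 3 Angstrom trigger a resample, at most 100 attempts).
#' Deterministic given the seed.
#'
#' @param spec a \code{ToySystemSpec}
#' @param n number of conformers (>= 1)
#' @param seed integer seed
#' @return a \code{ConformerEnsemble} with uniform weights
#' @export
build_pool <- function(spec, n, seed = 1L) {
  stopifnot(n >= 1L)
  atoms <- toy_atoms(spec)
  xyz <- with_seed(seed, {
    t(vapply(seq_len(n), function(i) as.vector(t(.sample_conformer(spec))),
             numeric(3L * nrow(atoms))))
  })
  conformer_ensemble(atoms, xyz, provenance = "pool")
}

#' Draw a ground-truth ensemble from a pool
#'
#' k conformers drawn without replacement; weights from a symmetric
#' Dirichlet with the given concentration (large concentration approaches
#' uniform weights).
#'
#' @param pool a \code{ConformerEnsemble}
#' @param k number of truth conformers (<= pool size)
#' @param concentration Dirichlet concentration parameter (> 0)
#' @param seed integer seed
#' @return a \code{ConformerEnsemble}; attribute \code{pool_indices} maps
#'   truth conformers back into the pool
#' @export
make_truth_ensemble <- function(pool, k, concentration = 1, seed = 1L) {
  if (k > n_conformers(pool)) stop("k exceeds pool size")
  res <- with_seed(seed, {
    idx <- sample.int(n_conformers(pool), k)
    g <- stats::rgamma(k, shape = concentration)
    list(idx = idx, w = g / sum(g))
  })
  ens <- subset_ensemble(pool, res$idx, res$w)
  ens$provenance <- rep("truth", k)
  attr(ens, "pool_indices") <- res$idx
  ens
}

#' Default restraint configuration for a toy system
#'
#' Eight distance-distribution site pairs (inter-domain and one
#' linker-domain pair) and two PRE label sites (one per domain, targeting
#' every fifth residue of the opposite domain), with acquisition scalars
#' typical of a ~45 kDa tandem-domain construct on a 700 MHz spectrometer
#' (tau_c 11 ns).
#'
#' @param spec a \code{ToySystemSpec}
#' @return list with \code{deer_pairs}, \code{pre_sites} (site ->
#'   target residues), \code{tau_c}, \code{omega_h}, \code{cap},
#'   \code{grid}, \code{kernel_sigma}
#' @export
toy_restraint_config <- function(spec) {
  ls <- spec$label_sites
  pairs <- list(c("A1", "B1"), c("A1", "B2"), c("A1", "B3"),
                c("A2", "B2"), c("A2", "B3"), c("A3", "B1"),
                c("A3", "B2"), c("A2", "L1"))
  targets_b <- spec$d2_res[seq(1L, spec$n2, by = 5L)]
  targets_a <- spec$d1_res[seq(1L, spec$n1, by = 5L)]
  list(deer_pairs = pairs,
       pre_sites = list(A1 = targets_b, B2 = targets_a),
       tau_c = 11e-9, omega_h = 2 * pi * 700e6, cap = 170,
       # wider than the 15-100 A DEER window: the Calpha-bead toy systems
       # reach shorter label-label distances than a labelled protein
       grid = seq(0, 160, by = 0.5), kernel_sigma = 1.0)
}

#' Build label sites for a toy system on an ensemble
#'
#' The outward direction of each site uses its own domain's beads (linker
#' sites use the linker beads).
#'
#' @param ens ensemble over the toy topology
#' @param spec a \code{ToySystemSpec}
#' @param model label model name
#' @param seed base seed
#' @return named list of \code{LabelSite} objects
#' @export
toy_label_sites <- function(ens, spec, model = "gauss_cloud", seed = 100L) {
  domain_of <- function(rn) {
    if (rn %in% spec$d1_res) spec$d1_res
    else if (rn %in% spec$d2_res) spec$d2_res
    else spec$link_res
  }
  sites <- lapply(seq_along(spec$label_sites), function(i) {
    rn <- spec$label_sites[[i]]
    label_site(ens, rn, id = names(spec$label_sites)[i], model = model,
               seed = seed + 1000L * i, domain_residues = domain_of(rn))
  })
  names(sites) <- names(spec$label_sites)
  sites
}

#' Simulate restraints from a truth ensemble
#'
#' Forward-predicts distance distributions and PRE tables on the truth
#' ensemble (noiseless), then adds zero-mean Gaussian noise: density noise
#' with sigma a fraction of the peak density (clipped at zero and
#' renormalised), PRE noise with sigma = max(floor, fraction of Gamma2).
#' Predicted rates above the cap are flagged vanished with the value set
#' to the cap.  Confidence bands are +-2 noise sigma.
#'
#' @param truth a \code{ConformerEnsemble} (the ground truth)
#' @param spec the \code{ToySystemSpec} the truth was built on
#' @param config restraint configuration (see
#'   \code{\link{toy_restraint_config}})
#' @param noise list: \code{dd_frac} (density noise as fraction of peak),
#'   \code{pre_frac}, \code{pre_floor} (s^-1); zeros give noiseless copies
#' @param seed integer seed (noise)
#' @param label_seed base seed of the label model (must match the seed
#'   used when building label sites for fitting)
#' @return object of class \code{GroundTruth}: \code{truth},
#'   \code{noiseless} and \code{noisy} lists (each with \code{deer} and
#'   \code{pre}), \code{noise}, \code{config}, \code{spec}
#' @export
simulate_restraints <- function(truth, spec, config = toy_restraint_config(spec),
                                noise = list(dd_frac = 0.05, pre_frac = 0.05,
                                             pre_floor = 2),
                                seed = 1L, label_seed = 100L) {
  # the label model is deterministic per conformer: using the same base
  # seed as the fitting side makes noiseless restraints exactly the
  # forward-model output any fit will reproduce on the same conformers
  sites <- toy_label_sites(truth, spec, seed = label_seed)
  grid <- config$grid
  noiseless <- list(deer = list(), pre = list())
  noisy <- list(deer = list(), pre = list())

  with_seed(seed, {
    for (pr in config$deer_pairs) {
      id <- paste(pr, collapse = "-")
      d <- predict_distance_distribution(truth, sites[[pr[1]]], sites[[pr[2]]],
                                         grid, config$kernel_sigma)
      noiseless$deer[[id]] <- list(pair = pr, obs = d)
      sd_n <- noise$dd_frac * max(d$p)
      # noise perturbs the fitted distribution within its support (the
      # bootstrap wiggle of a distance analysis); adding clipped noise
      # across the whole axis would manufacture spurious baseline mass
      mask <- d$p > 1e-3 * max(d$p)
      p_noisy <- d$p
      p_noisy[mask] <- pmax(d$p[mask] +
                              stats::rnorm(sum(mask), sd = sd_n), 0)
      if (sum(p_noisy) == 0) p_noisy <- d$p
      band <- sd_n * mask
      dn <- distance_distribution(grid, p_noisy,
                                  ci_lower = pmax(p_noisy - 2 * band, 0),
                                  ci_upper = p_noisy + 2 * band)
      noisy$deer[[id]] <- list(pair = pr, obs = dn)
    }
    for (sid in names(config$pre_sites)) {
      targets <- config$pre_sites[[sid]]
      tab <- predict_pre(truth, sites[[sid]], targets, config$tau_c,
                         config$omega_h, cap = config$cap)
      sig <- pmax(noise$pre_floor, noise$pre_frac * tab$gamma2)
      status <- ifelse(tab$gamma2 >= config$cap, "vanished", "observed")
      clean <- data.frame(residue = tab$residue, gamma2 = tab$gamma2,
                          gamma2_err = sig, status = status)
      class(clean) <- c("pre_table", "data.frame")
      noiseless$pre[[sid]] <- list(site = sid, obs = clean)
      g_noisy <- tab$gamma2 + stats::rnorm(length(sig), sd = sig)
      g_noisy <- pmax(g_noisy, 0)
      vn <- g_noisy >= config$cap | status == "vanished"
      g_noisy[vn] <- config$cap
      nt <- data.frame(residue = tab$residue, gamma2 = g_noisy,
                       gamma2_err = sig,
                       status = ifelse(vn, "vanished", "observed"))
      class(nt) <- c("pre_table", "data.frame")
      noisy$pre[[sid]] <- list(site = sid, obs = nt)
    }
  })
  structure(list(truth = truth, noiseless = noiseless, noisy = noisy,
                 noise = noise, config = config, spec = spec, seed = seed),
            class = "GroundTruth")
}

#' Write a complete simulated fixture directory
#'
#' Pool PDB with truth-weight sidecar, per-restraint TSV tables and a YAML
#' manifest that \code{\link{load_manifest}} can read back.
#'
#' @param gt a \code{GroundTruth}
#' @param dir output directory (created if missing)
#' @param which \code{"noisy"} or \code{"noiseless"} restraint copies
#' @return the manifest path, invisibly
#' @export
write_fixture_dir <- function(gt, dir, which = c("noisy", "noiseless")) {
  which <- match.arg(which)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_ensemble(gt$truth, file.path(dir, "truth.pdb"),
                 weights_path = file.path(dir, "truth_weights.txt"))
  rs <- gt[[which]]
  deer_entries <- list()
  for (id in names(rs$deer)) {
    f <- paste0("dd_", id, ".tsv")
    write_distance_distribution(rs$deer[[id]]$obs, file.path(dir, f))
    deer_entries[[length(deer_entries) + 1L]] <-
      list(pair = as.list(rs$deer[[id]]$pair), file = f)
  }
  pre_entries <- list()
  for (sid in names(rs$pre)) {
    f <- paste0("pre_", sid, ".tsv")
    write_pre_table(rs$pre[[sid]]$obs, file.path(dir, f))
    pre_entries[[length(pre_entries) + 1L]] <- list(site = sid, file = f)
  }
  sites <- lapply(as.list(gt$spec$label_sites), function(rn) list(residue = rn))
  manifest <- list(
    sites = sites, deer = deer_entries, pre = pre_entries,
    scalars = list(tau_c_s = gt$config$tau_c,
                   freq_1h_mhz = gt$config$omega_h / (2 * pi * 1e6),
                   gamma2_cap = gt$config$cap),
    options = list(grid_min = min(gt$config$grid),
                   grid_max = max(gt$config$grid),
                   grid_step = gt$config$grid[2] - gt$config$grid[1],
                   kernel_sigma = gt$config$kernel_sigma,
                   seed = gt$seed))
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
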