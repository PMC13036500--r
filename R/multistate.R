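# r^-6 multi-state distance modelling: effective distances over N jointly
# evaluated protein copies, quadratic restraint-violation scoring, a
# rigid-body simulated-annealing engine (fixed domain 1, per-state
# rigid-body transform of domain 2, linker-closure constraint), the
# 1..10-state selection scan, and splitting of multi-state runs into a
# conformer ensemble.

#' Effective r^-6-averaged distance over states
#'
#' \eqn{D^* = (\sum_i d_i^{-6})^{-1/6}}: the averaging used for distance
#' restraints satisfied jointly by N states.  Dominated by the shortest
#' distance: \eqn{D^* \le \min_i d_i}, with equality only for a single
#' state.
#'
#' @param distances positive distances (Angstrom), one per state
#' @return effective distance (Angstrom)
#' @export
effective_distance <- function(distances) {
  if (!length(distances)) stop("empty distance set")
  if (any(distances <= 0)) stop("distances must be positive")
  sum(distances^(-6))^(-1 / 6)
}

#' Violation score of a multi-state model against distance restraints
#'
#' Per restraint, the effective distance over states is compared to the
#' bounds: \eqn{v = \max(0, D^* - upl) + \max(0, lol - D^*)} (lower term
#' only for two-sided restraints); the score is \eqn{\sum v^2}.
#'
#' @param model a \code{MultiStateModel} (see \code{\link{anneal_states}})
#' @param restraints data.frame with \code{site}, \code{residue},
#'   \code{lol}, \code{upl}, \code{kind}
#' @return list with \code{score} (Angstrom^2) and \code{violations}
#'   (per-restraint data.frame with \code{d_eff} and \code{violation})
#' @export
violation_score <- function(model, restraints) {
  d_eff <- .model_effective_distances(model, restraints)
  v <- pmax(0, d_eff - restraints$upl) +
    ifelse(restraints$kind == "two_sided",
           pmax(0, ifelse(is.na(restraints$lol), 0, restraints$lol) - d_eff),
           0)
  list(score = sum(v^2),
       violations = data.frame(site = restraints$site,
                               residue = restraints$residue,
                               d_eff = d_eff, violation = v))
}

# effective distances for every restraint of a model
.model_effective_distances <- function(model, restraints) {
  dmat <- .restraint_state_distances(model, restraints)
  (rowSums(dmat^(-6)))^(-1 / 6)
}

# restraint x state matrix of per-state distances (site centroid ->
# target residue bead on domain 2)
.restraint_state_distances <- function(model, restraints) {
  sys <- model$system
  n_r <- nrow(restraints)
  out <- matrix(0, n_r, model$n_states)
  tgt_local <- match(restraints$residue, sys$d2_res)
  if (anyNA(tgt_local)) stop("restraint target outside domain 2")
  site_pos <- sys$site_centroids[restraints$site, , drop = FALSE]
  for (s in seq_len(model$n_states)) {
    tr <- model$states[[s]]
    pos <- sys$template2[tgt_local, , drop = FALSE] %*% t(tr$R)
    pos <- sweep(pos, 2L, tr$t, "+")
    out[, s] <- sqrt(rowSums((pos - site_pos)^2))
  }
  out
}

#' Multi-state toy system for rigid-body calculations
#'
#' Domain 1 is fixed in the laboratory frame (its template coordinates);
#' domain 2 is placed per state by a rigid-body transform.  Spin-cloud
#' centroids for the domain-1 label sites are computed once on the fixed
#' domain and then held rigid, the analogue of pinning dummy spin-cloud
#' centre atoms in the domain frame before a multi-state run.
#'
#' @param spec a \code{ToySystemSpec}
#' @param sites character vector of domain-1 label-site names to carry as
#'   restraint origins (default: all domain-1 sites)
#' @param seed seed for the one-off site clouds
#' @return list (class \code{multistate_system}) with the templates,
#'   residue maps, site centroids and the linker-closure bound
#' @export
multistate_system <- function(spec, sites = NULL, seed = 42L) {
  if (is.null(sites))
    sites <- names(spec$label_sites)[spec$label_sites %in% spec$d1_res]
  atoms1 <- data.frame(elety = "CA", resno = spec$d1_res, chain = "A",
                       elesy = "C", stringsAsFactors = FALSE)
  cents <- t(vapply(sites, function(sid) {
    rn <- spec$label_sites[[sid]]
    cl <- attach_label(atoms1, spec$template1, rn, seed = seed,
                       domain_residues = spec$d1_res)
    cloud_centroid(cl, atoms1, spec$template1,
                   anchors = spec$d1_res[seq(5L, spec$n1, length.out = 7L)])$centroid
  }, numeric(3)))
  rownames(cents) <- sites
  structure(list(
    spec = spec, template1 = spec$template1, template2 = spec$template2,
    d1_res = spec$d1_res, d2_res = spec$d2_res,
    site_centroids = cents,
    anchor1 = spec$template1[spec$n1, ],   # domain-1 attachment bead
    closure_bound = (spec$nl + 1L) * spec$bond
  ), class = "multistate_system")
}

# anchor-to-anchor linker gap of one state transform
.state_gap <- function(sys, tr) {
  att2 <- as.vector(tr$R %*% sys$template2[1L, ] + tr$t)
  sqrt(sum((att2 - sys$anchor1)^2))
}

.rotation_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3L, 3L,
              byrow = TRUE)
  diag(3) + s_ * K + (1 - c_) * (K %*% K)
}

# random initial placement satisfying closure
.random_state <- function(sys) {
  repeat {
    R <- .random_rotation()
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    t_ <- sys$anchor1 + dir * stats::runif(1, 0.2, 0.9) * sys$closure_bound -
      as.vector(R %*% sys$template2[1L, ])
    tr <- list(R = R, t = t_)
    if (.state_gap(sys, tr) <= sys$closure_bound) return(tr)
  }
}

.make_model <- function(sys, states, restraints) {
  model <- structure(list(system = sys, n_states = length(states),
                          states = states), class = "MultiStateModel")
  vs <- violation_score(model, restraints)
  gaps <- vapply(states, function(tr) .state_gap(sys, tr), numeric(1))
  model$score <- vs$score
  model$violations <- vs$violations
  model$gaps <- gaps
  model$elongated <- gaps > 0.8 * sys$closure_bound
  model$d_eff <- vs$violations$d_eff
  model
}

#' @export
print.MultiStateModel <- function(x, ...) {
  cat(sprintf("MultiStateModel: %d states, score %.4g A^2, %d elongated\n",
              x$n_states, x$score, sum(x$elongated)))
  invisible(x)
}

#' Anneal a multi-state rigid-body model against distance restraints
#'
#' Joint simulated annealing over all state transforms: each proposal
#' rotates (up to \code{max_rot} degrees) or translates (up to
#' \code{max_trans} Angstrom) domain 2 of one state; proposals breaking
#' the linker-closure bound (anchor gap above (n_linker + 1) x bond) are
#' rejected.  Geometric cooling from \code{t_start} to \code{t_end} in
#' score units, followed by a deterministic Nelder-Mead quench of the best
#' configuration.  States whose anchor gap exceeds 0.8 x the closure
#' bound are flagged elongated.  Reproducible given the seed.
#'
#' @param sys a \code{multistate_system}
#' @param n_states number of states N (>= 1)
#' @param restraints restraint data.frame (see
#'   \code{\link{violation_score}})
#' @param steps annealing steps
#' @param t_start,t_end geometric cooling schedule (score units)
#' @param max_rot,max_trans proposal sizes (degrees, Angstrom)
#' @param seed integer seed
#' @param quench run the final local refinement (default TRUE)
#' @return a \code{MultiStateModel} with \code{score}, \code{violations},
#'   \code{gaps}, \code{elongated}, and the best-score \code{trace}
#' @export
anneal_states <- function(sys, n_states, restraints, steps = 10000L,
                          t_start = 1.0, t_end = 0.01, max_rot = 15,
                          max_trans = 2.0, seed = 1L, quench = TRUE) {
  stopifnot(n_states >= 1L, nrow(restraints) >= 1L)
  run <- with_seed(seed, {
    states <- replicate(n_states, .random_state(sys), simplify = FALSE)
    cur <- .make_model(sys, states, restraints)
    best <- cur
    cool <- (t_end / t_start)^(1 / max(1L, steps - 1L))
    temp <- t_start
    trace <- numeric(0)
    for (step in seq_len(steps)) {
      s <- sample.int(n_states, 1L)
      tr <- states[[s]]
      if (stats::runif(1) < 0.5) {
        ax <- stats::rnorm(3)
        ang <- stats::runif(1, -max_rot, max_rot) * pi / 180
        Rp <- .rotation_about(ax, ang)
        # rotate about the state's domain-2 centroid to decouple from shifts
        cen <- as.vector(tr$R %*% colMeans(sys$template2) + tr$t)
        newtr <- list(R = Rp %*% tr$R,
                      t = as.vector(Rp %*% (tr$t - cen)) + cen)
      } else {
        newtr <- list(R = tr$R, t = tr$t + stats::rnorm(3) * max_trans / 2)
      }
      if (.state_gap(sys, newtr) > sys$closure_bound) next
      cand_states <- states
      cand_states[[s]] <- newtr
      cand <- .make_model(sys, cand_states, restraints)
      if (cand$score <= cur$score ||
          stats::runif(1) < exp((cur$score - cand$score) / temp)) {
        states <- cand_states
        cur <- cand
        if (cur$score < best$score) best <- cur
      }
      temp <- temp * cool
      if (step %% 100L == 0L) trace <- c(trace, best$score)
    }
    best$trace <- trace
    best
  })
  if (quench) run <- .quench_model(sys, run, restraints)
  run$seed <- seed
  run
}

# deterministic local refinement: Nelder-Mead over small rotation vectors
# and translations applied on top of the annealed transforms
.quench_model <- function(sys, model, restraints) {
  n <- model$n_states
  base <- model$states
  unpack <- function(par) {
    lapply(seq_len(n), function(s) {
      rv <- par[(s - 1L) * 6L + 1:3]
      tv <- par[(s - 1L) * 6L + 4:6]
      ang <- sqrt(sum(rv^2))
      Rp <- if (ang < 1e-12) diag(3) else .rotation_about(rv, ang)
      list(R = Rp %*% base[[s]]$R, t = base[[s]]$t + tv)
    })
  }
  fn <- function(par) {
    st <- unpack(par)
    gaps <- vapply(st, function(tr) .state_gap(sys, tr), numeric(1))
    pen <- sum(pmax(0, gaps - sys$closure_bound)^2) * 1e3
    m <- structure(list(system = sys, n_states = n, states = st),
                   class = "MultiStateModel")
    violation_score(m, restraints)$score + pen
  }
  opt <- stats::optim(rep(0, 6L * n), fn, method = "Nelder-Mead",
                      control = list(maxit = 4000L, reltol = 1e-12))
  cand <- .make_model(sys, unpack(opt$par), restraints)
  if (cand$score <= model$score &&
      max(cand$gaps) <= sys$closure_bound + 1e-9) {
    cand$trace <- c(model$trace, cand$score)
    cand
  } else model
}

#' Scan the number of states
#'
#' Repeated annealing for each N in the range, recording the best score,
#' restraint-violation count (violations above \code{viol_cut}) and
#' elongated-state count.  The selected N is the smallest whose best
#' score is within 5 percent of the overall minimum (plus a small
#' absolute slack for near-zero scores) and whose best run has no
#' elongated states.
#'
#' @param sys a \code{multistate_system}
#' @param restraints restraint data.frame
#' @param n_range candidate state counts (default 1:10)
#' @param repeats annealing repeats per N
#' @param seed base seed (run r of N uses seed + 97 N + r)
#' @param viol_cut violation magnitude counted as a violation (Angstrom)
#' @param ... passed to \code{\link{anneal_states}}
#' @return list with \code{table} (per-N statistics), \code{selected},
#'   \code{models} (best model per N)
#' @export
scan_num_states <- function(sys, restraints, n_range = 1:10, repeats = 3L,
                            seed = 1L, viol_cut = 0.1, ...) {
  if (!length(n_range)) stop("empty state range")
  models <- list()
  rows <- lapply(n_range, function(N) {
    runs <- lapply(seq_len(repeats), function(r)
      anneal_states(sys, N, restraints, seed = seed + 97L * N + r, ...))
    best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "score"))]]
    models[[as.character(N)]] <<- best
    data.frame(n_states = N, best_score = best$score,
               n_violations = sum(best$violations$violation > viol_cut),
               n_elongated = sum(best$elongated))
  })
  tab <- do.call(rbind, rows)
  floor_ <- min(tab$best_score)
  ok <- tab$best_score <= floor_ * 1.05 + 1e-6 & tab$n_elongated == 0L
  selected <- if (any(ok)) tab$n_states[which(ok)[1]] else NA_integer_
  list(table = tab, selected = selected, models = models)
}

#' Split multi-state runs into a conformer ensemble
#'
#' Keeps the best-scoring runs; each run's N states become N independent
#' conformers (domain 1 + transformed domain 2, linker omitted), all with
#' equal population.  20 kept runs of a 7-state model give a 140-conformer
#' ensemble.
#'
#' @param runs list of \code{MultiStateModel} objects sharing N and
#'   topology
#' @param keep number of best runs to keep
#' @return a \code{ConformerEnsemble} of size keep x N with uniform
#'   weights
#' @export
split_states <- function(runs, keep) {
  if (keep > length(runs)) stop("keep exceeds available runs")
  N <- unique(vapply(runs, `[[`, numeric(1), "n_states"))
  if (length(N) != 1L) stop("runs disagree on state count")
  scores <- vapply(runs, `[[`, numeric(1), "score")
  kept <- runs[order(scores)[seq_len(keep)]]
  sys <- kept[[1]]$system
  spec <- sys$spec
  resno <- c(spec$d1_res, spec$d2_res)
  atoms <- data.frame(elety = "CA", resno = resno, chain = "A", elesy = "C",
                      stringsAsFactors = FALSE)
  xyz <- do.call(rbind, lapply(kept, function(run) {
    t(vapply(run$states, function(tr) {
      dom2 <- sys$template2 %*% t(tr$R)
      dom2 <- sweep(dom2, 2L, tr$t, "+")
      as.vector(t(rbind(sys$template1, dom2)))
    }, numeric(3L * length(resno))))
  }))
  conformer_ensemble(atoms, xyz, provenance = "multistate")
}

#' Restraints from a planted multi-state arrangement
#'
#' Computes the effective r^-6 distances of a known set of state
#' transforms and wraps them as two-sided restraints with the given
#' half-width.  Used to plant a recoverable solution for annealing tests.
#'
#' @param sys a \code{multistate_system}
#' @param states list of transforms \code{list(R =, t =)}
#' @param targets domain-2 residue numbers to restrain
#' @param sites domain-1 site ids (default: all in \code{sys})
#' @param halfwidth restraint half-width (Angstrom)
#' @return restraint data.frame
#' @export
planted_restraints <- function(sys, states, targets, sites = NULL,
                               halfwidth = 0.5) {
  if (is.null(sites)) sites <- rownames(sys$site_centroids)
  grid_df <- expand.grid(site = sites, residue = targets,
                         stringsAsFactors = FALSE)
  model <- structure(list(system = sys, n_states = length(states),
                          states = states), class = "MultiStateModel")
  grid_df$lol <- grid_df$upl <- NA_real_
  d_eff <- .model_effective_distances(model, grid_df)
  data.frame(site = grid_df$site, residue = grid_df$residue,
             lol = pmax(0.5, d_eff - halfwidth), upl = d_eff + halfwidth,
             kind = "two_sided", stringsAsFactors = FALSE)
}
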