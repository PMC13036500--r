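# Conformer-weight fitting on the simplex against DEER distance
# distributions (mean earth mover's distance), PRE rates (mean
# chi-square), or both balanced through the loss of merit
#   L = 1/2 (EMD/EMD_min + chi2/chi2_min) - 1.
#
# The ensemble prediction is linear in the weights for both observable
# types, so per-conformer predictions are computed once and every fit is a
# deterministic quasi-Newton minimisation (L-BFGS-B on softmax-
# parameterised weights, uniform start) with analytic gradients.

#' Assemble precomputed restraint data for weight fitting
#'
#' Runs the forward model once per conformer for every configured
#' restraint and stores the per-conformer prediction matrices together
#' with the experimental observations.
#'
#' @param ens a \code{ConformerEnsemble} (the conformer pool)
#' @param sites named list of \code{LabelSite} objects covering every site
#'   referenced below
#' @param deer list of entries \code{list(pair = c(idA, idB), obs =
#'   DistanceDistribution)}
#' @param pre list of entries \code{list(site = id, obs = pre_table)}
#' @param tau_c correlation time (s)
#' @param omega_h 1H Larmor frequency (rad/s)
#' @param grid uniform distance grid (Angstrom)
#' @param kernel_sigma Gaussian kernel width for predicted distributions
#' @param cap PRE detection-limit rate (s^-1)
#' @param K PRE proportionality constant (cm^6 s^-2)
#' @return object of class \code{restraint_data}
#' @export
build_restraint_data <- function(ens, sites, deer, pre, tau_c = NA,
                                 omega_h = NA, grid = seq(10, 100, by = 0.5),
                                 kernel_sigma = 1.0, cap = 170,
                                 K = 1.23e-32) {
  step <- grid[2] - grid[1]
  deer_data <- lapply(deer, function(e) {
    obs <- if (inherits(e$obs, "DistanceDistribution")) e$obs else
      stop("deer entry lacks a DistanceDistribution")
    if (length(obs$r) != length(grid) || max(abs(obs$r - grid)) > 1e-6)
      obs <- regrid_distribution(obs, grid)
    om <- obs$p / sum(obs$p)
    pred <- predict_dd_matrix(ens, sites[[e$pair[1]]], sites[[e$pair[2]]],
                              grid, kernel_sigma)
    list(id = paste(e$pair, collapse = "-"), pair = e$pair,
         obs = obs, obs_mass = om, pred = pred,
         cum_pred = apply(pred, 2L, cumsum), cum_obs = cumsum(om))
  })
  pre_data <- lapply(pre, function(e) {
    tab <- e$obs
    use <- tab$status != "unreliable"
    tab <- tab[use, , drop = FALSE]
    pred <- predict_pre_matrix(ens, sites[[e$site]], tab$residue,
                               tau_c, omega_h, K)
    list(id = e$site, obs = tab, pred = pred)
  })
  structure(list(grid = grid, step = step, deer = deer_data, pre = pre_data,
                 tau_c = tau_c, omega_h = omega_h, cap = cap, K = K,
                 kernel_sigma = kernel_sigma,
                 n_conformers = n_conformers(ens)),
            class = "restraint_data")
}

#' Restrict restraint data to a conformer subset
#' @param rd a \code{restraint_data}
#' @param idx conformer indices to keep
#' @return a \code{restraint_data} over the subset
#' @export
rd_subset_conformers <- function(rd, idx) {
  rd$deer <- lapply(rd$deer, function(e) {
    e$pred <- e$pred[, idx, drop = FALSE]
    e$cum_pred <- e$cum_pred[, idx, drop = FALSE]
    e
  })
  rd$pre <- lapply(rd$pre, function(e) {
    e$pred <- e$pred[, idx, drop = FALSE]
    e
  })
  rd$n_conformers <- length(idx)
  rd
}

#' Drop one distance-distribution restraint
#' @param rd a \code{restraint_data}
#' @param i index of the deer entry to omit
#' @return a \code{restraint_data} without that restraint
#' @export
rd_drop_deer <- function(rd, i) {
  rd$deer <- rd$deer[-i]
  rd
}

# mean EMD and its gradient in w
.emd_objective <- function(rd, w, gradient = FALSE) {
  R <- length(rd$deer)
  val <- 0
  grad <- if (gradient) numeric(length(w)) else NULL
  for (e in rd$deer) {
    cdiff <- as.vector(e$cum_pred %*% w) - e$cum_obs
    val <- val + rd$step * sum(abs(cdiff)) / R
    if (gradient)
      grad <- grad + rd$step * as.vector(crossprod(e$cum_pred, sign(cdiff))) / R
  }
  list(value = val, grad = grad)
}

# pooled mean PRE chi-square and its gradient in w
.chi2_objective <- function(rd, w, gradient = FALSE) {
  cap <- rd$cap
  tot <- 0; n <- 0
  grad <- if (gradient) numeric(length(w)) else NULL
  for (e in rd$pre) {
    g <- as.vector(e$pred %*% w)
    sig <- e$obs$gamma2_err
    van <- e$obs$status == "vanished"
    res <- ifelse(van,
                  ifelse(g >= cap, 0, (cap - g) / sig),
                  (e$obs$gamma2 - pmin(g, cap)) / sig)
    tot <- tot + sum(res^2); n <- n + length(res)
    if (gradient) {
      # d(res^2)/dg: zero wherever the prediction is capped
      dg <- ifelse(van,
                   ifelse(g >= cap, 0, -2 * (cap - g) / sig^2),
                   ifelse(g >= cap, 0, -2 * (e$obs$gamma2 - g) / sig^2))
      grad <- grad + as.vector(crossprod(e$pred, dg))
    }
  }
  if (n == 0) stop("no usable PRE residues")
  list(value = tot / n, grad = if (gradient) grad / n else NULL)
}

# reported loss of merit; a figure of merit below the numerical floor is
# treated as converged (ratio 1) so near-perfect fits report L ~ 0 rather
# than an artefact of a vanishing denominator
.loss_of_merit <- function(emd_val, emd_min, chi2_val, chi2_min,
                           floor = 1e-8) {
  ratio <- function(v, m) {
    if (m < floor) { if (v <= floor) 1 else v / floor } else v / m
  }
  0.5 * (ratio(emd_val, emd_min) + ratio(chi2_val, chi2_min)) - 1
}

.softmax <- function(theta) {
  z <- exp(theta - max(theta))
  z / sum(z)
}

# minimise obj(w) over the simplex via softmax parameterisation
.simplex_minimise <- function(obj_fn, n, maxit = 5000L, pgtol = 1e-8) {
  fn <- function(theta) obj_fn(.softmax(theta), FALSE)$value
  gr <- function(theta) {
    w <- .softmax(theta)
    g <- obj_fn(w, TRUE)$grad
    w * (g - sum(w * g))
  }
  res <- stats::optim(rep(0, n), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, pgtol = pgtol,
                                     factr = 10))
  list(weights = .softmax(res$par), value = res$value,
       iterations = res$counts[["function"]],
       convergence = res$convergence,
       grad_norm = {
         w <- .softmax(res$par)
         g <- obj_fn(w, TRUE)$grad
         sqrt(sum((w * (g - sum(w * g)))^2))
       })
}

#' Fit conformer weights against restraints
#'
#' Mode \code{"deer"} minimises the mean earth mover's distance across
#' distance-distribution restraints; \code{"pre"} minimises the pooled
#' mean PRE chi-square; \code{"balanced"} first determines the two
#' single-objective minima (EMD_min, chi2_min) by separate global fits and
#' then minimises the loss of merit
#' \eqn{L = (EMD/EMD_{min} + \chi^2/\chi^2_{min})/2 - 1}.
#' All fits start from uniform weights and are deterministic.
#'
#' @param rd a \code{restraint_data}
#' @param mode one of \code{"balanced"}, \code{"deer"}, \code{"pre"}
#' @param ref_minima optional list \code{list(emd_min=, chi2_min=)} to use
#'   as fixed normalisation in balanced mode (e.g. to keep L comparable
#'   with an earlier fit over a conformer subset); computed from
#'   single-objective fits when NULL
#' @param maxit,pgtol optimizer controls
#' @return object of class \code{FitResult}: \code{weights},
#'   \code{conformers} (indices), \code{emd} (per restraint),
#'   \code{mean_emd}, \code{emd_min}, \code{chi2}, \code{chi2_min},
#'   \code{L}, \code{mode}, \code{diagnostics}
#' @export
fit_weights <- function(rd, mode = c("balanced", "deer", "pre"),
                        ref_minima = NULL, maxit = 5000L, pgtol = 1e-8) {
  mode <- match.arg(mode)
  n <- rd$n_conformers
  has_deer <- length(rd$deer) > 0
  has_pre <- length(rd$pre) > 0
  if (mode %in% c("deer", "balanced") && !has_deer)
    stop("no distance-distribution restraints for mode '", mode, "'")
  if (mode %in% c("pre", "balanced") && !has_pre)
    stop("no PRE restraints for mode '", mode, "'")

  emd_min <- chi2_min <- NA_real_
  if (mode == "deer") {
    sol <- .simplex_minimise(function(w, g) .emd_objective(rd, w, g), n,
                             maxit, pgtol)
    emd_min <- sol$value
  } else if (mode == "pre") {
    sol <- .simplex_minimise(function(w, g) .chi2_objective(rd, w, g), n,
                             maxit, pgtol)
    chi2_min <- sol$value
  } else {
    if (is.null(ref_minima)) {
      emd_min <- .simplex_minimise(function(w, g) .emd_objective(rd, w, g),
                                   n, maxit, pgtol)$value
      chi2_min <- .simplex_minimise(function(w, g) .chi2_objective(rd, w, g),
                                    n, maxit, pgtol)$value
    } else {
      emd_min <- ref_minima$emd_min
      chi2_min <- ref_minima$chi2_min
    }
    de <- max(emd_min, 1e-8)   # guard near-perfect single-objective fits
    dx <- max(chi2_min, 1e-8)
    balanced <- function(w, g) {
      a <- .emd_objective(rd, w, g)
      b <- .chi2_objective(rd, w, g)
      list(value = 0.5 * (a$value / de + b$value / dx) - 1,
           grad = if (g) 0.5 * (a$grad / de + b$grad / dx) else NULL)
    }
    sol <- .simplex_minimise(balanced, n, maxit, pgtol)
  }

  .assemble_fit(rd, sol$weights, mode, emd_min, chi2_min,
                diagnostics = list(iterations = sol$iterations,
                                   grad_norm = sol$grad_norm,
                                   convergence = sol$convergence))
}

# FitResult at given weights (no optimisation)
.assemble_fit <- function(rd, w, mode, emd_min, chi2_min,
                          diagnostics = list()) {
  has_deer <- length(rd$deer) > 0
  has_pre <- length(rd$pre) > 0
  per_emd <- if (has_deer)
    vapply(rd$deer, function(e)
      rd$step * sum(abs(as.vector(e$cum_pred %*% w) - e$cum_obs)),
      numeric(1)) else numeric(0)
  if (has_deer) names(per_emd) <- vapply(rd$deer, `[[`, "", "id")
  mean_emd <- if (has_deer) mean(per_emd) else NA_real_
  chi2 <- if (has_pre) .chi2_objective(rd, w, FALSE)$value else NA_real_
  L <- if (mode == "balanced") .loss_of_merit(mean_emd, emd_min,
                                              chi2, chi2_min) else NA_real_
  structure(list(
    weights = w, conformers = seq_len(rd$n_conformers),
    emd = per_emd, mean_emd = mean_emd, emd_min = emd_min,
    chi2 = chi2, chi2_min = chi2_min, L = L, mode = mode,
    retained = rd$n_conformers,
    diagnostics = diagnostics
  ), class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("FitResult (%s): %d conformers, mean EMD %.3f A, chi2 %s, L %s\n",
              x$mode, x$retained,
              ifelse(is.na(x$mean_emd), NaN, x$mean_emd),
              ifelse(is.na(x$chi2), "n.a.", sprintf("%.3f", x$chi2)),
              ifelse(is.na(x$L), "n.a.", sprintf("%.4f", x$L))))
  invisible(x)
}

#' Prune low-weight conformers and refit
#'
#' Conformers with weights below a fraction of the largest weight
#' (default 1 percent) are discarded, the remaining weights renormalised,
#' and one refit pass in the same mode is run on the retained set.
#'
#' @param fit a \code{FitResult}
#' @param rd the \code{restraint_data} the fit was computed on
#' @param threshold_fraction prune threshold as a fraction of max(w)
#' @return a \code{FitResult} on the retained set; \code{conformers} maps
#'   back into the original pool
#' @export
prune_weights <- function(fit, rd, threshold_fraction = 0.01) {
  if (threshold_fraction >= 1) stop("threshold must be < 1")
  keep_local <- which(fit$weights >= threshold_fraction * max(fit$weights))
  keep <- fit$conformers[keep_local]
  rd2 <- rd_subset_conformers(rd, keep)
  refit <- fit_weights(rd2, fit$mode)
  refit$conformers <- keep
  refit$retained <- length(keep)
  refit
}

#' Pool-size convergence curve
#'
#' Refits weights on nested pool prefixes (block, 2 block, ..., full pool)
#' and records the figures of merit; flags convergence when the last two
#' rows agree within a relative tolerance.  The final row is by
#' construction the full-pool fit.
#'
#' @param rd a \code{restraint_data} over the full pool
#' @param block block size (conformers added per step)
#' @param mode fit mode passed to \code{\link{fit_weights}}
#' @param tol relative tolerance for the convergence flag
#' @return list with \code{table} (data.frame: size, mean_emd, chi2) and
#'   \code{converged}
#' @export
convergence_curve <- function(rd, block = 100L, mode = "balanced",
                              tol = 0.02) {
  stopifnot(block >= 1L)
  n <- rd$n_conformers
  sizes <- unique(c(seq(block, n, by = block), n))
  rows <- lapply(sizes, function(s) {
    fit <- fit_weights(rd_subset_conformers(rd, seq_len(s)), mode)
    data.frame(size = s, mean_emd = fit$mean_emd, chi2 = fit$chi2)
  })
  tab <- do.call(rbind, rows)
  converged <- FALSE
  if (nrow(tab) >= 2L) {
    a <- tab[nrow(tab) - 1L, ]; b <- tab[nrow(tab), ]
    rel <- function(x, y) if (is.na(x) || is.na(y)) 0 else
      abs(x - y) / max(abs(y), 1e-12)
    converged <- rel(a$mean_emd, b$mean_emd) < tol && rel(a$chi2, b$chi2) < tol
  }
  list(table = tab, converged = converged)
}
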