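# Leave-one-distribution-out validation, superensemble construction and
# ensemble-of-ensembles uncertainty estimates.  Only distance-distribution
# restraints are jackknifed; the PRE set is always retained.

#' Jackknife validation over distance-distribution restraints
#'
#' For each of the R distance-distribution restraints: run a balanced fit
#' with the remaining R-1 distributions (PRE restraints always retained),
#' prune, backcalculate the omitted distribution from the validation
#' ensemble and record its EMD to experiment.  Deterministic given the
#' pool order.
#'
#' @param rd a \code{restraint_data} with >= 2 distance distributions
#' @param prune_threshold prune threshold passed to
#'   \code{\link{prune_weights}}
#' @return object of class \code{ValidationSet}: list with \code{fits}
#'   (one pruned \code{FitResult} per omission), \code{omitted}
#'   (data.frame: restraint id, EMD of the omitted restraint
#'   backcalculated from the validation ensemble)
#' @export
jackknife <- function(rd, prune_threshold = 0.01) {
  R <- length(rd$deer)
  if (R < 2L) stop("need at least 2 distance-distribution restraints")
  fits <- vector("list", R)
  omitted <- data.frame(id = character(R), emd = numeric(R))
  for (i in seq_len(R)) {
    rd_i <- rd_drop_deer(rd, i)
    fit <- fit_weights(rd_i, "balanced")
    fit <- prune_weights(fit, rd_i, prune_threshold)
    fits[[i]] <- fit
    # backcalculate the omitted distribution from the validation ensemble
    e <- rd$deer[[i]]
    pred_mass <- as.vector(e$pred[, fit$conformers, drop = FALSE] %*%
                             fit$weights)
    omitted$id[i] <- e$id
    omitted$emd[i] <- .emd_mass(pred_mass, e$obs_mass, rd$step)
  }
  structure(list(fits = fits, omitted = omitted, rd = rd),
            class = "ValidationSet")
}

#' @export
print.ValidationSet <- function(x, ...) {
  cat(sprintf("ValidationSet: %d validation ensembles, omitted-restraint EMD %.3f-%.3f A\n",
              length(x$fits), min(x$omitted$emd), max(x$omitted$emd)))
  invisible(x)
}

#' Build and refit the superensemble
#'
#' Pools the conformers of the all-restraint fit and every validation
#' ensemble (deduplicated by identity within the shared pool) and runs one
#' balanced refit with ALL restraints.  The refit reuses the all-restraint
#' fit's EMD_min and chi2_min as normalisation, so L values are comparable
#' and the superensemble objective can only improve: the all-restraint
#' solution is a feasible point of the superensemble fit.
#'
#' @param all_fit the all-restraint \code{FitResult} (pruned or not)
#' @param validation a \code{ValidationSet}
#' @param rd the full \code{restraint_data}
#' @return a \code{FitResult} over the pooled conformer set
#' @export
build_superensemble <- function(all_fit, validation, rd) {
  pool_idx <- sort(unique(c(all_fit$conformers,
                            unlist(lapply(validation$fits, `[[`, "conformers")))))
  rd_s <- rd_subset_conformers(rd, pool_idx)
  ref <- list(emd_min = all_fit$emd_min, chi2_min = all_fit$chi2_min)
  fit <- fit_weights(rd_s, "balanced", ref_minima = ref)
  # the all-restraint solution is a feasible point of the pooled problem;
  # keep it if the optimizer stopped short of the incumbent
  w0 <- numeric(length(pool_idx))
  w0[match(all_fit$conformers, pool_idx)] <- all_fit$weights
  inc <- .assemble_fit(rd_s, w0, "balanced", ref$emd_min, ref$chi2_min,
                       diagnostics = list(incumbent = TRUE))
  if (is.finite(inc$L) && inc$L < fit$L) fit <- inc
  fit$conformers <- pool_idx
  fit$retained <- length(pool_idx)
  fit
}

#' Uncertainty estimates from validation ensembles
#'
#' Evaluates a scalar ensemble descriptor on every validation ensemble
#' and reports mean plus/minus twice the standard deviation (the 95
#' percent confidence estimate of the ensemble-of-ensembles approach).
#'
#' @param validation a \code{ValidationSet}, or a plain list of
#'   \code{ConformerEnsemble} objects
#' @param descriptor_fn function mapping a \code{ConformerEnsemble} to a
#'   scalar (e.g. \code{function(e) radius_of_gyration(e)$rg})
#' @param pool the conformer pool the validation fits index into
#'   (required when \code{validation} is a \code{ValidationSet})
#' @return list with \code{values}, \code{mean}, \code{sd},
#'   \code{halfwidth} (2 sd), and \code{label} formatted as
#'   "mean +- halfwidth"
#' @export
uncertainty_estimates <- function(validation, descriptor_fn, pool = NULL) {
  ensembles <- if (inherits(validation, "ValidationSet")) {
    if (is.null(pool)) stop("pool required to materialise validation ensembles")
    lapply(validation$fits, function(f)
      subset_ensemble(pool, f$conformers, f$weights))
  } else validation
  if (length(ensembles) < 2L) stop("need at least 2 validation ensembles")
  vals <- vapply(ensembles, descriptor_fn, numeric(1))
  m <- mean(vals)
  # population SD across the ensemble of ensembles
  s <- sqrt(mean((vals - m)^2))
  list(values = vals, mean = m, sd = s, halfwidth = 2 * s,
       label = sprintf("%.3g ± %.2g", m, 2 * s))
}
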