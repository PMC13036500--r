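# Scalar figures of merit comparing predicted and experimental restraints.

# Wasserstein-1 between two mass vectors on a shared uniform grid
.emd_mass <- function(mp, mq, step) {
  mp <- mp / sum(mp); mq <- mq / sum(mq)
  step * sum(abs(cumsum(mp - mq)))
}

#' Earth mover's distance between two distance distributions
#'
#' The 1-D Wasserstein-1 distance, computed through the CDF formulation
#' \eqn{\sum_b |F_P(r_b) - F_Q(r_b)| \Delta r}.  A proper metric: zero iff
#' the distributions agree on the grid, symmetric, triangle inequality.
#' Distributions on different grids are regridded onto the first grid.
#'
#' @param p,q \code{DistanceDistribution} objects
#' @return distance in Angstrom
#' @export
emd <- function(p, q) {
  if (length(p$r) != length(q$r) || max(abs(p$r - q$r)) > 1e-6)
    q <- regrid_distribution(q, p$r)
  .emd_mass(p$p, q$p, p$step)
}

#' Overlap deficiency between two distance distributions
#'
#' \eqn{1 - \int \min(P, Q) dr} on a shared grid; 0 for identical
#' distributions, 1 for disjoint supports.
#'
#' @param p,q \code{DistanceDistribution} objects on identical grids
#' @return fraction in [0, 1]
#' @export
overlap_deficiency <- function(p, q) {
  if (length(p$r) != length(q$r) || max(abs(p$r - q$r)) > 1e-6)
    stop("overlap_deficiency requires identical grids")
  ov <- trapz(p$r, pmin(p$p, q$p))
  min(max(1 - ov, 0), 1)
}

#' Mean PRE chi-square
#'
#' Mean over usable residues of \eqn{((\Gamma_{2,obs} -
#' \Gamma_{2,pred})/\sigma_{obs})^2}.  Vanished residues (bleached beyond
#' detection) contribute zero when the prediction also reaches the cap,
#' else \eqn{((cap - \Gamma_{2,pred})/\sigma)^2}.  Unreliable residues are
#' excluded.  Predictions for observed residues are clipped to the cap
#' before comparison.
#'
#' @param observed PRE table (\code{residue}, \code{gamma2},
#'   \code{gamma2_err}, \code{status})
#' @param predicted data.frame (\code{residue}, \code{gamma2}) or numeric
#'   vector matched to \code{observed}
#' @param cap detection-limit rate (s^-1)
#' @return dimensionless mean chi-square
#' @export
chi2_pre <- function(observed, predicted, cap = 170) {
  if (is.data.frame(predicted)) {
    m <- match(observed$residue, predicted$residue)
    pred <- predicted$gamma2[m]
  } else pred <- predicted
  use <- observed$status != "unreliable"
  if (!any(use)) stop("no usable residues for chi-square")
  obs <- observed$gamma2[use]; sig <- observed$gamma2_err[use]
  pr <- pred[use]; st <- observed$status[use]
  if (any(sig <= 0)) stop("observed errors must be > 0")
  res <- ifelse(st == "vanished",
                ifelse(pr >= cap, 0, (cap - pr) / sig),
                (obs - pmin(pr, cap)) / sig)
  mean(res^2)
}

#' Fit a Gaussian overlay to a distance distribution
#'
#' Least-squares fit of \eqn{P(r) = A \exp[-(r - \langle r \rangle)^2 /
#' (2\sigma^2)]} to a non-parametric density, initialised from the
#' distribution's moments, with a handful of perturbed restarts if the
#' first fit fails.
#'
#' @param d a \code{DistanceDistribution}
#' @param restarts number of perturbed restarts before giving up
#' @return list with \code{A}, \code{mean}, \code{sd}, \code{rss}
#' @export
fit_gaussian <- function(d, restarts = 5L) {
  m0 <- distribution_mean(d); s0 <- distribution_sd(d)
  if (!is.finite(s0) || s0 <= 0) stop("degenerate distribution")
  dat <- data.frame(r = d$r, p = d$p)
  starts <- c(0, 0.3, -0.3, 0.6, -0.6, 1.0)[seq_len(restarts + 1L)]
  for (sh in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        p ~ A * exp(-(r - mu)^2 / (2 * sg^2)), data = dat,
        start = list(A = max(d$p), mu = m0 + sh * s0, sg = s0),
        lower = c(0, min(d$r), 1e-3 * s0),
        upper = c(Inf, max(d$r), diff(range(d$r))),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      return(list(A = unname(cf["A"]), mean = unname(cf["mu"]),
                  sd = unname(cf["sg"]),
                  rss = sum(stats::residuals(fit)^2)))
    }
  }
  stop("Gaussian overlay did not converge after ", restarts + 1L,
       " starts (mean ", signif(m0, 4), ", sd ", signif(s0, 4), ")")
}
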