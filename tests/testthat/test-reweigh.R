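# small hand-built restraint data: K point-label conformers on a grid
# lets every objective be checked against direct computation
toy_rd <- function(positions, obs_from = NULL, obs_weights = NULL,
                   with_pre = TRUE) {
  ens <- two_point_ensemble(lapply(positions, function(x)
    rbind(c(0, 0, 0), c(x, 0, 0))))
  sites <- point_sites(ens)
  grid <- seq(0, 120, by = 0.5)
  tau <- 11e-9; omega <- 2 * pi * 700e6
  if (is.null(obs_weights)) obs_weights <- rep(1, length(obs_from))
  obs_ens <- set_weights(subset_ensemble(ens, obs_from), obs_weights)
  obs_sites <- point_sites(obs_ens)
  dd <- predict_distance_distribution(obs_ens, obs_sites$a, obs_sites$b,
                                      grid, 1)
  pre_tab <- NULL
  if (with_pre) {
    g <- predict_pre(obs_ens, obs_sites$a, targets = 2L, tau, omega)
    pre_tab <- data.frame(residue = 2L, gamma2 = g$gamma2,
                          gamma2_err = pmax(2, 0.05 * g$gamma2),
                          status = "observed")
  }
  build_restraint_data(
    ens, sites,
    deer = list(list(pair = c("a", "b"), obs = dd)),
    pre = if (with_pre) list(list(site = "a", obs = pre_tab)) else list(),
    tau_c = tau, omega_h = omega, grid = grid, kernel_sigma = 1)
}

test_that("single-conformer truth is recovered from a two-conformer pool", {
  rd <- toy_rd(positions = c(25, 45), obs_from = 1L)
  fit <- fit_weights(rd, "deer")
  expect_gte(fit$weights[1], 0.99)
  expect_lt(fit$mean_emd, 0.01)
})

test_that("symmetric observations give symmetric weights", {
  rd <- toy_rd(positions = c(25, 45), obs_from = c(1L, 2L),
               obs_weights = c(0.5, 0.5), with_pre = FALSE)
  fit <- fit_weights(rd, "deer")
  expect_equal(fit$weights, c(0.5, 0.5), tolerance = 1e-3)
})

test_that("analytic gradients match finite differences", {
  rd <- mini_rd("noisy")
  rd5 <- rd_subset_conformers(rd, 1:5)
  set.seed(3)
  for (i in 1:3) {
    w <- as.vector(rmultinom(1, 50, rep(1, 5))) / 50 + 0.01
    w <- w / sum(w)
    ge <- tandemens:::.emd_objective(rd5, w, TRUE)$grad
    gn <- numeric_gradient(function(x)
      tandemens:::.emd_objective(rd5, x, FALSE)$value, w)
    # project both onto the simplex tangent (objective used on the simplex)
    expect_equal(ge - mean(ge), gn - mean(gn), tolerance = 1e-4)
    gx <- tandemens:::.chi2_objective(rd5, w, TRUE)$grad
    gxn <- numeric_gradient(function(x)
      tandemens:::.chi2_objective(rd5, x, FALSE)$value, w)
    expect_equal(gx - mean(gx), gxn - mean(gxn), tolerance = 1e-4)
  }
})

test_that("the optimizer finds the dense-search optimum on small pools", {
  rd <- mini_rd("noisy")
  rd4 <- rd_subset_conformers(rd, c(2L, 9L, 17L, 25L))
  fit <- fit_weights(rd4, "deer")
  # dense random search over the 4-simplex
  set.seed(5)
  best <- Inf
  for (i in 1:4000) {
    w <- -log(runif(4)); w <- w / sum(w)
    best <- min(best, tandemens:::.emd_objective(rd4, w, FALSE)$value)
  }
  expect_lte(fit$emd_min, best + 1e-6)
})

test_that("balanced mode balances both figures of merit", {
  rd <- mini_rd("noisy")
  fit <- fit_weights(rd, "balanced")
  # ratios are >= 1 by definition of the single-objective minima
  expect_gte(fit$mean_emd, fit$emd_min - 1e-6)
  expect_gte(fit$chi2, fit$chi2_min - 1e-6)
  expect_gte(fit$L, -1e-6)
  expect_true(all(fit$weights >= 0))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  # balanced objective improves on uniform weights
  n <- rd$n_conformers
  u <- rep(1 / n, n)
  L_u <- 0.5 * (tandemens:::.emd_objective(rd, u, FALSE)$value / fit$emd_min +
                  tandemens:::.chi2_objective(rd, u, FALSE)$value /
                  fit$chi2_min) - 1
  expect_lte(fit$L, L_u + 1e-9)
  expect_error(fit_weights(rd_drop_deer(rd, 1:8), "deer"), "restraints")
})

test_that("adding conformers never worsens the optimum", {
  rd <- mini_rd("noisy")
  f10 <- fit_weights(rd_subset_conformers(rd, 1:10), "deer")
  f20 <- fit_weights(rd_subset_conformers(rd, 1:20), "deer")
  f30 <- fit_weights(rd, "deer")
  expect_lte(f20$emd_min, f10$emd_min + 1e-6)
  expect_lte(f30$emd_min, f20$emd_min + 1e-6)
})

test_that("pruning drops sub-threshold weights and refits", {
  # rule check on a synthetic FitResult
  fit <- structure(list(weights = c(0.98, 0.015, 0.005), conformers = 1:3,
                        mode = "deer"), class = "FitResult")
  rd <- mini_rd("noisy")
  rd3 <- rd_subset_conformers(rd, 1:3)
  pruned <- prune_weights(fit, rd3, threshold_fraction = 0.01)
  expect_equal(pruned$conformers, c(1L, 2L))   # 0.005 < 0.0098 dropped

  # all-equal weights: the max-relative rule drops nothing
  fit_eq <- structure(list(weights = rep(1 / 3, 3), conformers = 1:3,
                           mode = "deer"), class = "FitResult")
  expect_equal(prune_weights(fit_eq, rd3)$conformers, 1:3)

  # pruning a converged fit keeps the objective within 5 percent
  full <- fit_weights(rd, "balanced")
  pr <- prune_weights(full, rd)
  expect_lte(pr$mean_emd, full$mean_emd * 1.05 + 1e-6)
})

test_that("the convergence curve ends at the full-pool fit", {
  rd <- mini_rd("noisy")
  cc <- convergence_curve(rd, block = 10L, mode = "deer")
  expect_equal(cc$table$size, c(10L, 20L, 30L))
  full <- fit_weights(rd, "deer")
  expect_equal(cc$table$mean_emd[3], full$mean_emd, tolerance = 1e-9)

  # pool whose first block contains the truth: flat near-zero curve
  # (noiseless restraints, so no block can improve on the first)
  rd0 <- mini_rd("noiseless")
  truth_idx <- sort(attr(mini_truth(), "pool_indices"))
  rest <- setdiff(seq_len(rd0$n_conformers), truth_idx)
  rd_sorted <- rd_subset_conformers(rd0, c(truth_idx, rest))
  cc2 <- convergence_curve(rd_sorted, block = 10L, mode = "deer")
  expect_true(all(cc2$table$mean_emd < 0.05))
  expect_lte(cc2$table$mean_emd[3], cc2$table$mean_emd[1] + 1e-6)
})
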