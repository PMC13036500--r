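# Shared fixtures (built in code, memoised per test run) and independent
# oracles used across the suite.

.fix_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fix_cache)) assign(key, builder(), envir = .fix_cache)
  get(key, envir = .fix_cache)
}

# small two-domain system: quick enough for per-operation tests
mini_spec <- function() memo("mini_spec", function()
  toy_system_spec(domain1 = 30L, domain2 = 30L, linker = 20L, seed = 3L))

mini_pool <- function() memo("mini_pool", function()
  build_pool(mini_spec(), 30L, seed = 7L))

mini_truth <- function() memo("mini_truth", function()
  make_truth_ensemble(mini_pool(), 5L, concentration = 2, seed = 9L))

mini_gt <- function() memo("mini_gt", function()
  simulate_restraints(mini_truth(), mini_spec(), seed = 11L))

mini_sites <- function() memo("mini_sites", function()
  toy_label_sites(mini_pool(), mini_spec(), seed = 100L))

# restraint data over the mini pool; which = "noiseless" or "noisy"
mini_rd <- function(which = "noiseless") memo(paste0("mini_rd_", which), function() {
  gt <- mini_gt()
  cfg <- gt$config
  build_restraint_data(
    mini_pool(), mini_sites(),
    deer = lapply(gt[[which]]$deer, function(e) list(pair = e$pair, obs = e$obs)),
    pre = lapply(gt[[which]]$pre, function(e) list(site = e$site, obs = e$obs)),
    tau_c = cfg$tau_c, omega_h = cfg$omega_h, grid = cfg$grid,
    kernel_sigma = cfg$kernel_sigma, cap = cfg$cap)
})

# standard-size broad-linker pool (the generator's default geometry),
# used for the disorder-parameter calibration checks
std_pool <- function() memo("std_pool", function()
  build_pool(toy_system_spec(seed = 3L), 25L, seed = 61L))

# full-scale recovery fixture: 200-conformer pool containing a
# 20-conformer truth ensemble, noiseless restraints (8 distance
# distributions, 2 PRE sites)
full_fixture <- function() memo("full_fixture", function() {
  spec <- toy_system_spec(seed = 3L)
  pool <- build_pool(spec, 200L, seed = 7L)
  truth <- make_truth_ensemble(pool, 20L, concentration = 2, seed = 9L)
  gt <- simulate_restraints(truth, spec, seed = 11L)
  sites <- toy_label_sites(pool, spec, seed = 100L)
  cfg <- gt$config
  rd <- build_restraint_data(
    pool, sites,
    deer = lapply(gt$noiseless$deer, function(e)
      list(pair = e$pair, obs = e$obs)),
    pre = lapply(gt$noiseless$pre, function(e)
      list(site = e$site, obs = e$obs)),
    tau_c = cfg$tau_c, omega_h = cfg$omega_h, grid = cfg$grid,
    kernel_sigma = cfg$kernel_sigma, cap = cfg$cap)
  list(spec = spec, pool = pool, truth = truth, gt = gt, rd = rd)
})

# exact 1-D optimal transport by greedy monotone coupling: the linear
# programming optimum for cost |x - y| on the line, computed by an
# algorithm independent of the CDF formula under test
emd_transport_oracle <- function(mass_p, mass_q, grid) {
  p <- mass_p / sum(mass_p); q <- mass_q / sum(mass_q)
  i <- 1L; j <- 1L; cost <- 0
  while (i <= length(p) && j <= length(q)) {
    m <- min(p[i], q[j])
    cost <- cost + m * abs(grid[i] - grid[j])
    p[i] <- p[i] - m; q[j] <- q[j] - m
    if (p[i] <= 1e-15) i <- i + 1L
    if (j <= length(q) && q[j] <= 1e-15) j <- j + 1L
  }
  cost
}

# central finite-difference gradient
numeric_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# ensemble of a single point-atom "conformer" at given pair positions
two_point_ensemble <- function(pos_list) {
  atoms <- data.frame(elety = "CA", resno = c(1L, 2L), chain = "A",
                      elesy = "C", stringsAsFactors = FALSE)
  xyz <- t(vapply(pos_list, function(pp) as.vector(t(pp)), numeric(6)))
  conformer_ensemble(atoms, xyz)
}

# point-model label sites on a two-bead ensemble (offset 0: cloud on CA)
point_sites <- function(ens) {
  list(a = label_site(ens, 1L, id = "a", model = "point", offset = 0),
       b = label_site(ens, 2L, id = "b", model = "point", offset = 0))
}

# planted 2-state multistate fixture
planted_multistate <- function() memo("planted_multistate", function() {
  spec <- toy_system_spec(seed = 3L)
  sys <- multistate_system(spec, sites = c("A1", "A3"))
  rot1 <- tandemens:::.rotation_about(c(0, 0, 1), 0.4)
  rot2 <- tandemens:::.rotation_about(c(0, 1, 0), -0.7)
  states <- list(
    list(R = rot1, t = sys$site_centroids["A1", ] + c(14, 0, 0) -
           as.vector(rot1 %*% colMeans(sys$template2))),
    list(R = rot2, t = sys$site_centroids["A3", ] + c(0, 14, 0) -
           as.vector(rot2 %*% colMeans(sys$template2))))
  targets <- spec$d2_res[seq(5L, spec$n2, by = 10L)]
  list(spec = spec, sys = sys, states = states, targets = targets,
       restraints = planted_restraints(sys, states, targets))
})
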