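test_that("label clouds are seeded, offset and model-pluggable", {
  spec <- mini_spec()
  pool <- build_pool(spec, 1L, seed = 51L)
  co <- conformer_coords(pool, 1L)
  rn <- spec$label_sites[["A2"]]
  cl1 <- attach_label(pool$atoms, co, rn, seed = 5L,
                      domain_residues = spec$d1_res)
  cl2 <- attach_label(pool$atoms, co, rn, seed = 5L,
                      domain_residues = spec$d1_res)
  expect_identical(cl1$points, cl2$points)
  expect_equal(sum(cl1$weights), 1, tolerance = 1e-9)

  # cloud mean sits near the 7 A offset point (3 sigma / sqrt(64) bound)
  ca <- co[which(pool$atoms$resno == rn), ]
  expect_lt(abs(sqrt(sum((colMeans(cl1$points) - ca)^2)) - 7.0),
            3 * 2.5 / sqrt(64) * sqrt(3))

  # degenerate point model lands exactly at the offset position
  pt <- attach_label(pool$atoms, co, rn, model = "point", seed = 1L,
                     domain_residues = spec$d1_res)
  expect_equal(sqrt(sum((pt$points[1, ] - ca)^2)), 7.0, tolerance = 1e-9)

  expect_error(attach_label(pool$atoms, co, rn, model = "nope"),
               "gauss_cloud")
})

test_that("cloud centroids and anchor distances match brute force", {
  spec <- mini_spec()
  pool <- build_pool(spec, 1L, seed = 52L)
  co <- conformer_coords(pool, 1L)
  atoms <- pool$atoms

  # symmetric two-point cloud: centroid at the midpoint
  cl <- list(points = rbind(c(0, 0, 0), c(2, 0, 0)), weights = c(0.5, 0.5))
  cc <- cloud_centroid(cl, atoms, co, anchors = c(5L, 10L))
  expect_equal(cc$centroid, c(1, 0, 0))

  # single-point cloud: plain distances
  cl1 <- list(points = matrix(c(3, 4, 0), 1), weights = 1)
  cc1 <- cloud_centroid(cl1, atoms, co, anchors = 5L)
  expect_equal(unname(cc1$anchor_distances[1]),
               sqrt(sum((co[5, ] - c(3, 4, 0))^2)), tolerance = 1e-12)

  # random 64-point cloud against an independent weighted-mean computation
  cl64 <- attach_label(atoms, co, spec$label_sites[["A1"]], seed = 3L,
                       domain_residues = spec$d1_res)
  anchors <- c(2L, 8L, 14L, 20L, 24L, 27L, 29L)
  cc64 <- cloud_centroid(cl64, atoms, co, anchors = anchors)
  brute <- colSums(cl64$points * cl64$weights)
  for (k in seq_along(anchors))
    expect_equal(unname(cc64$anchor_distances[k]),
                 sqrt(sum((co[anchors[k], ] - brute)^2)), tolerance = 1e-9)

  expect_error(cloud_centroid(cl, atoms, co, anchors = integer(0)), "anchor")

  # placement verification against the recorded distances
  expect_true(verify_centroid_placement(cc64$centroid, atoms, co,
                                        cc64$anchor_distances))
  expect_error(verify_centroid_placement(cc64$centroid + c(1, 0, 0), atoms,
                                         co, cc64$anchor_distances), "anchor")
})

test_that("predicted distributions reduce to known limits", {
  grid <- seq(0, 120, by = 0.5)
  # single conformer, point clouds 30 A apart -> Gaussian(30, kernel sigma)
  ens <- two_point_ensemble(list(rbind(c(0, 0, 0), c(30, 0, 0))))
  ps <- point_sites(ens)
  d <- predict_distance_distribution(ens, ps$a, ps$b, grid, kernel_sigma = 1)
  expect_equal(distribution_mean(d), 30, tolerance = 1e-3)
  expect_equal(distribution_sd(d), 1, tolerance = 1e-2)
  expect_equal(tandemens:::trapz(d$r, d$p), 1, tolerance = 1e-6)

  # two equal-weight conformers at 25 and 45 A -> bimodal, equal masses
  ens2 <- two_point_ensemble(list(rbind(c(0, 0, 0), c(25, 0, 0)),
                                  rbind(c(0, 0, 0), c(45, 0, 0))))
  ps2 <- point_sites(ens2)
  d2 <- predict_distance_distribution(ens2, ps2$a, ps2$b, grid, 1)
  lower <- tandemens:::trapz(grid[grid <= 35], d2$p[grid <= 35])
  expect_equal(lower, 0.5, tolerance = 1e-3)

  # grid that misses the support errors out
  expect_error(
    predict_distance_distribution(ens2, ps2$a, ps2$b, seq(50, 100, 0.5), 1),
    "widen")
})

test_that("distribution mean matches brute-force pair enumeration", {
  spec <- mini_spec()
  pool <- build_pool(spec, 3L, seed = 53L)
  sa <- label_site(pool, spec$label_sites[["A1"]],
                   domain_residues = spec$d1_res)
  sb <- label_site(pool, spec$label_sites[["B3"]],
                   domain_residues = spec$d2_res)
  grid <- seq(0, 160, by = 0.5)
  d <- predict_distance_distribution(pool, sa, sb, grid, kernel_sigma = 1)
  # brute force: weighted mean over conformers and all cloud point pairs
  brute <- sum(vapply(1:3, function(i) {
    pa <- sa$clouds[[i]]$points; pb <- sb$clouds[[i]]$points
    dd <- sqrt(outer(rowSums(pa^2), rowSums(pb^2), "+") -
                 2 * tcrossprod(pa, pb))
    pool$weights[i] * mean(dd)
  }, numeric(1)))
  expect_equal(distribution_mean(d), brute, tolerance = 1e-3)
})

test_that("rigid-body moves leave forward predictions unchanged", {
  spec <- mini_spec()
  pool1 <- build_pool(spec, 1L, seed = 54L)
  R <- tandemens:::.rotation_about(c(1, 2, 3), 0.7)
  shift <- c(5, -3, 11)
  co <- conformer_coords(pool1, 1L)
  co2 <- sweep(co %*% t(R), 2L, shift, "+")
  pool2 <- conformer_ensemble(pool1$atoms, as.vector(t(co2)))

  mk <- function(ens, transform = FALSE) {
    sa <- label_site(pool1, spec$label_sites[["A1"]],
                     domain_residues = spec$d1_res)
    sb <- label_site(pool1, spec$label_sites[["B2"]],
                     domain_residues = spec$d2_res)
    if (transform) {
      tr <- function(site) {
        site$clouds <- lapply(site$clouds, function(cl) {
          cl$points <- sweep(cl$points %*% t(R), 2L, shift, "+")
          cl
        })
        site
      }
      sa <- tr(sa); sb <- tr(sb)
    }
    list(a = sa, b = sb)
  }
  s1 <- mk(pool1)
  s2 <- mk(pool1, transform = TRUE)   # clouds co-transformed with the model
  grid <- seq(0, 160, by = 0.5)
  d1 <- predict_distance_distribution(pool1, s1$a, s1$b, grid, 1)
  d2 <- predict_distance_distribution(pool2, s2$a, s2$b, grid, 1)
  expect_equal(d1$p, d2$p, tolerance = 1e-9)

  g1 <- predict_pre(pool1, s1$a, spec$d2_res[1:5], 11e-9, 2 * pi * 700e6)
  g2 <- predict_pre(pool2, s2$a, spec$d2_res[1:5], 11e-9, 2 * pi * 700e6)
  expect_equal(g1$gamma2, g2$gamma2, tolerance = 1e-9)
})

test_that("PRE prediction inverts the rate-distance relation and averages", {
  omega <- 2 * pi * 700e6; tau <- 11e-9
  r100 <- gamma2_to_distance(100, tau, omega)

  # one-point cloud at that distance returns 100 s^-1 exactly
  ens <- two_point_ensemble(list(rbind(c(0, 0, 0), c(r100, 0, 0))))
  site <- label_site(ens, 1L, model = "point", offset = 0)
  out <- predict_pre(ens, site, targets = 2L, tau, omega)
  expect_equal(out$gamma2, 100, tolerance = 1e-6)

  # ensemble averaging: rates 40 and 80 with weights 0.25/0.75 -> 70
  r40 <- gamma2_to_distance(40, tau, omega)
  r80 <- gamma2_to_distance(80, tau, omega)
  ens2 <- two_point_ensemble(list(rbind(c(0, 0, 0), c(r40, 0, 0)),
                                  rbind(c(0, 0, 0), c(r80, 0, 0))))
  ens2 <- set_weights(ens2, c(0.25, 0.75))
  site2 <- label_site(ens2, 1L, model = "point", offset = 0)
  out2 <- predict_pre(ens2, site2, targets = 2L, tau, omega)
  expect_equal(out2$gamma2, 70, tolerance = 1e-6)

  # clipping applies after ensemble averaging
  r500 <- gamma2_to_distance(500, tau, omega)
  ens3 <- two_point_ensemble(list(rbind(c(0, 0, 0), c(r500, 0, 0))))
  site3 <- label_site(ens3, 1L, model = "point", offset = 0)
  out3 <- predict_pre(ens3, site3, targets = 2L, tau, omega, cap = 170)
  expect_equal(out3$gamma2, 170)
})
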