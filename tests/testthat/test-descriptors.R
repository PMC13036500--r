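test_that("ensemble radius of gyration is the weighted RMS", {
  # two equal-weight conformers with per-conformer radii 3 and 4
  mk_ring <- function(r) {
    ang <- seq(0, 2 * pi, length.out = 9L)[-9]
    cbind(r * cos(ang), r * sin(ang), 0)
  }
  atoms <- data.frame(elety = "CA", resno = 1:8, chain = "A", elesy = "C")
  ens <- conformer_ensemble(atoms, rbind(as.vector(t(mk_ring(3))),
                                         as.vector(t(mk_ring(4)))))
  out <- radius_of_gyration(ens)
  expect_equal(out$per_conformer, c(3, 4), tolerance = 1e-12)
  expect_equal(out$rg, sqrt(12.5), tolerance = 1e-12)

  # single point per conformer: degenerate zero
  a1 <- data.frame(elety = "CA", resno = 1L, chain = "A", elesy = "C")
  expect_equal(radius_of_gyration(
    conformer_ensemble(a1, matrix(c(1, 2, 3), 1)))$rg, 0)

  # invariance under rigid-body motion of any conformer
  R <- tandemens:::.rotation_about(c(1, 1, 0), 1.1)
  moved <- sweep(mk_ring(4) %*% t(R), 2L, c(9, -2, 4), "+")
  ens2 <- conformer_ensemble(atoms, rbind(as.vector(t(mk_ring(3))),
                                          as.vector(t(moved))))
  expect_equal(radius_of_gyration(ens2)$rg, out$rg, tolerance = 1e-9)
})

test_that("dRMSD matrices vanish for rigid moves and match hand values", {
  atoms <- data.frame(elety = "CA", resno = 1:3, chain = "A", elesy = "C")
  tri1 <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))
  R <- tandemens:::.rotation_about(c(0, 1, 1), 0.8)
  tri1_moved <- sweep(tri1 %*% t(R), 2L, c(5, 5, 5), "+")
  tri2 <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 6, 0))
  ens <- conformer_ensemble(atoms, rbind(as.vector(t(tri1)),
                                         as.vector(t(tri1_moved)),
                                         as.vector(t(tri2))))
  d <- drmsd_matrix(ens)
  expect_equal(diag(d), rep(0, 3))
  expect_equal(d, t(d))
  expect_lt(d[1, 2], 1e-9)               # internal distances unchanged
  # hand computation over the three pair distances:
  # conformer 1: (3, 4, 5); conformer 3: (4, 6, sqrt(52))
  oracle <- sqrt(mean(c(3 - 4, 4 - 6, 5 - sqrt(52))^2))
  expect_equal(d[1, 3], oracle, tolerance = 1e-9)
})

test_that("disorder parameter embeds the shape-difference matrix", {
  # identical conformers: no spread, delta = 0 without error
  atoms <- data.frame(elety = "CA", resno = 1:3, chain = "A", elesy = "C")
  tri <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))
  same <- conformer_ensemble(atoms, rbind(as.vector(t(tri)),
                                          as.vector(t(tri))))
  expect_equal(disorder_parameter(same)$delta, 0)

  # equilateral D_kl triple: R_g,ACS is the circumradius a / sqrt(3)
  a <- 6
  three <- conformer_ensemble(atoms, rbind(as.vector(t(tri)),
                                           as.vector(t(tri + 1)),
                                           as.vector(t(tri + 2))))
  pts <- rbind(c(0, 0), c(a, 0), c(a / 2, a * sqrt(3) / 2))
  d_equi <- as.matrix(dist(pts))      # all off-diagonals equal a
  rg_acs <- disorder_parameter(three, d_kl = d_equi)$rg_acs
  expect_equal(rg_acs, a / sqrt(3), tolerance = 1e-9)

  # embedded pairwise distances reproduce D_kl when the Gram matrix is PSD
  pool <- mini_pool()
  sub <- subset_ensemble(pool, 1:8)
  dkl <- drmsd_matrix(sub)
  mds <- stats::cmdscale(dkl, k = 7, eig = TRUE)
  keep <- which(mds$eig > 1e-9 * max(mds$eig))
  if (all(mds$eig > -1e-9 * max(mds$eig))) {
    emb <- unname(as.matrix(dist(mds$points[, keep])))
    expect_equal(emb, unname(dkl), tolerance = 1e-6)
  }

  # rotation/translation of one conformer leaves delta unchanged
  d0 <- disorder_parameter(sub)$delta
  co <- conformer_coords(sub, 3L)
  R <- tandemens:::.rotation_about(c(1, 0, 2), 2.2)
  moved <- sweep(co %*% t(R), 2L, c(-4, 8, 1), "+")
  xyz2 <- sub$xyz; xyz2[3, ] <- as.vector(t(moved))
  sub2 <- conformer_ensemble(sub$atoms, xyz2, sub$weights)
  expect_equal(disorder_parameter(sub2)$delta, d0, tolerance = 1e-9)
})

test_that("delta separates rigid from disordered ensembles", {
  broad <- std_pool()
  expect_gt(disorder_parameter(broad)$delta, 0.35)

  # rigid ensemble: one arrangement plus tiny coordinate jitter
  base <- conformer_coords(broad, 1L)
  xyz <- with_seed(71L, t(vapply(1:25, function(i)
    as.vector(t(base + matrix(rnorm(length(base), sd = 0.3),
                              ncol = 3))), numeric(length(base) * 1))))
  rigid <- conformer_ensemble(broad$atoms, xyz)
  expect_lt(disorder_parameter(rigid)$delta, 0.15)
})

test_that("contact fractions are weighted conformer counts", {
  # 4 contacting conformers out of 140 equally weighted -> 2.9 %
  atoms <- data.frame(elety = "CA", resno = 1:2, chain = "A", elesy = "C")
  xyz <- t(vapply(1:140, function(i) {
    gap <- if (i <= 4) 2.5 else 20
    as.vector(t(rbind(c(0, 0, 0), c(gap, 0, 0))))
  }, numeric(6)))
  ens <- conformer_ensemble(atoms, xyz)
  cm <- contact_map(ens, group_a = 1L, group_b = 2L, cutoff = 3.0)
  expect_equal(cm$pairs$fraction, 4 / 140, tolerance = 1e-12)
  expect_equal(format_contact_fraction(cm$pairs$fraction), "2.9 %")

  # cutoff zero yields no contacts
  expect_equal(nrow(contact_map(ens, 1L, 2L, cutoff = 0)$pairs), 0L)

  # doubling all coordinates removes contacts found at the original cutoff
  ens2 <- conformer_ensemble(atoms, 2 * ens$xyz)
  expect_equal(nrow(contact_map(ens2, 1L, 2L, cutoff = 3.0)$pairs), 0L)

  expect_error(contact_map(ens, integer(0), 2L), "empty")
})

test_that("binding pose checks use the shortest cross-set distance", {
  m <- rbind(c(0, 0, 0), c(1, 0, 0))
  d74 <- rbind(c(7.4, 0, 0) + c(1, 0, 0), c(50, 0, 0))
  d76 <- rbind(c(7.6, 0, 0) + c(1, 0, 0), c(50, 0, 0))
  expect_true(binding_pose_check(m, d74)$pass)
  expect_false(binding_pose_check(m, d76)$pass)

  # brute-force all-pairs minimum on random sets
  set.seed(9)
  for (i in 1:10) {
    a <- matrix(rnorm(15, sd = 8), ncol = 3)
    b <- matrix(rnorm(21, sd = 8), ncol = 3)
    brute <- min(as.matrix(stats::dist(rbind(a, b)))[1:5, 6:12])
    expect_equal(binding_pose_check(a, b)$min_distance, brute,
                 tolerance = 1e-9)
  }
  expect_error(binding_pose_check(m[0, , drop = FALSE], d74), "empty")
})

test_that("merged-pool clustering classifies by provenance", {
  pool <- mini_pool()
  a <- subset_ensemble(pool, 1:12)
  # identical ensembles: every cluster is mixed
  out <- merged_cluster_analysis(a, a, mean_cluster_size = 4L)
  expect_equal(unname(out$fractions["mixed"]), 1, tolerance = 1e-12)

  # well-separated islands: inflate one source so its internal distances
  # are far from anything in the other -> no mixed clusters
  b <- subset_ensemble(pool, 13:24)
  bxyz <- t(vapply(1:12, function(i)
    as.vector(t(conformer_coords(b, i) * 3)), numeric(ncol(b$xyz))))
  b_far <- conformer_ensemble(b$atoms, bxyz, b$weights)
  out2 <- merged_cluster_analysis(a, b_far, mean_cluster_size = 4L)
  expect_equal(unname(out2$fractions["mixed"]), 0, tolerance = 1e-12)
  expect_equal(sum(out2$fractions), 1, tolerance = 1e-12)

  # default mean cluster size is 12
  expect_equal(formals(merged_cluster_analysis)$mean_cluster_size, 12L)
})
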