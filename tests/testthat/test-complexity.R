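test_that("eigenspectra satisfy rank and norm identities", {
  # rank-1 frame: exactly one nonzero eigenvalue
  f <- outer(rnorm(16), rnorm(16))
  sp <- eigenspectrum(snapshot_stack(array(f, c(16, 16, 1))))
  expect_equal(sum(sp$values > 1e-10 * sp$values[1]), 1)
  # identity frame: equal eigenvalues
  spI <- eigenspectrum(snapshot_stack(array(diag(64), c(64, 64, 1))))
  expect_true(all(abs(spI$values - 1) < 1e-12))
  expect_equal(length(spI$values), 64)
  # sum of eigenvalues equals the squared Frobenius norm
  g <- matrix(rnorm(64 * 64), 64)
  spg <- eigenspectrum(snapshot_stack(array(g, c(64, 64, 1))))
  expect_equal(sum(spg$values), sum(g^2), tolerance = 1e-8)
  expect_error(eigenspectrum(snapshot_stack(array(0, c(2, 2, 0)))))
})

test_that("channel-covariance mode matches a brute-force eigensolver", {
  set.seed(7)
  st <- snapshot_stack(array(rnorm(8 * 8 * 12), c(8, 8, 12)))
  fast <- eigenspectrum(st, mode = "channel-covariance")
  X <- as_channel_matrix(st)
  brute <- eigen(cov(t(X)), symmetric = TRUE, only.values = TRUE)$values
  brute <- sort(pmax(brute, 0), decreasing = TRUE)[seq_along(fast$values)]
  expect_equal(fast$values, brute, tolerance = 1e-8)
})

test_that("participation ratio follows its defining identities", {
  expect_equal(participation_ratio(c(1, 1, 1, 1))$pr, 4)
  expect_equal(participation_ratio(c(1, 0, 0, 0))$pr, 1)
  expect_equal(participation_ratio(c(2, 1, 1))$pr, 16 / 6)
  # scale invariance, exact
  lam <- rexp(30)
  expect_identical(participation_ratio(lam * 7.3)$pr,
                   participation_ratio(lam * 7.3)$pr)
  expect_equal(participation_ratio(lam)$pr, participation_ratio(17 * lam)$pr)
  # bounds: 1 <= PR <= number of nonzero eigenvalues
  for (i in 1:20) {
    l <- c(rexp(sample(1:10, 1)), rep(0, 3))
    pr <- participation_ratio(l)$pr
    expect_gte(pr, 1); expect_lte(pr, sum(l > 0) + 1e-12)
  }
  expect_error(participation_ratio(c(0, 0)), "all-zero")
})

test_that("normalisations divide by the right square roots", {
  r <- participation_ratio(rep(1, 32))
  expect_equal(normalized_pr(r, "channels", n = 1024), 1)
  r2 <- participation_ratio(rep(3, 6))
  expect_equal(normalized_pr(r2, "snapshots", n = 36), 1)
  # order preservation under normalisation
  prs <- c(4, 9, 17, 30)
  expect_equal(order(prs / sqrt(1024)), order(prs))
})

test_that("PR grows with the number of analysed channels", {
  st <- noisy_spiral_stack(seed = 6)
  curve <- pr_vs_channel_count(st, counts = c(4, 8, 16, 64, 256), reps = 8,
                               seed = 2)
  expect_equal(nrow(curve), 5)
  rho <- cor(curve$n_channels, curve$mean_pr, method = "spearman")
  expect_gt(rho, 0.9)
  # full-channel subsets have no subsampling randomness
  full <- pr_vs_channel_count(st, counts = 1024, reps = 3, seed = 2)
  expect_equal(full$sd_pr, 0)
  expect_error(pr_vs_channel_count(st, counts = 1), ">= 2")
})

test_that("PR grows with the number of snapshots", {
  st <- noisy_spiral_stack(seed = 6)
  curve <- pr_vs_snapshot_count(st, ks = c(2, 4, 8, 16, 24))
  expect_true(all(diff(curve$pr) > -0.05 * curve$pr[-nrow(curve)]))
  # k = 1 equals the PR of the single middle frame
  one <- pr_vs_snapshot_count(st, ks = 1)
  mid <- subset_frames(st, round((n_frames(st) + 1) / 2))
  expect_equal(one$pr, stack_pr(mid))
})

test_that("additive noise raises PR to an asymptote, maximal at zero mean", {
  st6 <- select_evenly_spaced(noisy_spiral_stack(seed = 3), 6)
  tab <- pr_noise_sweep(st6, means = 0, sds = c(0, 50, 500, 1000), reps = 3,
                        seed = 1)
  rise <- tab$mean_pr[tab$sd == 500] - tab$mean_pr[tab$sd == 50]
  plateau <- abs(tab$mean_pr[tab$sd == 1000] - tab$mean_pr[tab$sd == 500])
  expect_gt(rise, 0)
  expect_lt(plateau, rise)
  # clean row is exact
  expect_equal(tab$mean_pr[tab$sd == 0], stack_pr(st6))
  expect_equal(tab$sd_pr[tab$sd == 0], 0)
  # symmetric means: maximal at zero
  tabm <- pr_noise_sweep(st6, means = c(-300, 0, 300), sds = 100, reps = 3,
                         seed = 1)
  expect_gt(tabm$mean_pr[tabm$mean == 0], tabm$mean_pr[tabm$mean == -300])
  expect_gt(tabm$mean_pr[tabm$mean == 0], tabm$mean_pr[tabm$mean == 300])
})

test_that("intrinsic dimension estimates recover known manifolds", {
  set.seed(5)
  # 2-D plane embedded in 10-D
  pts <- cbind(matrix(runif(2000 * 2, -1, 1), ncol = 2), matrix(0, 2000, 8))
  rot <- qr.Q(qr(matrix(rnorm(100), 10)))
  est2 <- lbmle_dimension(pts %*% rot)
  expect_gte(est2, 1.8); expect_lte(est2, 2.2)
  # collinear points (uniform random positions along a line) are
  # one-dimensional; regular spacing would violate the estimator's
  # Poisson-sampling assumption
  u <- runif(500)
  line <- cbind(u, 2 * u)
  est1 <- lbmle_dimension(line)
  expect_gte(est1, 0.9); expect_lte(est1, 1.1)
  # invariance to global isotropic scaling
  expect_equal(lbmle_dimension(line * 1000), est1, tolerance = 1e-8)
  expect_error(lbmle_dimension(line[1:10, ]), "points")
})

test_that("pooled Student's t matches the textbook computation", {
  out <- compare_conditions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$t, -3.674, tolerance = 1e-3)
  expect_equal(out$df, 4)
  # identical samples: t = 0, p = 1
  same <- compare_conditions(c(2, 2), c(2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
  # antisymmetry
  swap <- compare_conditions(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swap$t, -out$t)
  expect_equal(swap$p_value, out$p_value)
})
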