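test_that("fat_fraction computes percentages and flags dead voxels", {
  d <- c(4L, 4L, 4L)
  eq <- fat_fraction(fat_water_volume(array(3, d), array(3, d)))
  expect_equal(eq$ff, array(50, d))
  w <- fat_fraction(fat_water_volume(array(0, d), array(5, d)))
  expect_equal(w$ff, array(0, d))
  set.seed(0)
  f <- array(runif(prod(d), 0, 10), d); g <- array(runif(prod(d), 0, 10), d)
  expect_equal(fat_fraction(fat_water_volume(f, g))$ff, 100 * f / (f + g))
  dead <- fat_water_volume(array(0, d), array(0, d))
  expect_true(all(is.na(fat_fraction(dead)$ff)))
})

test_that("magdensity is the complement of mean fat fraction in the mask", {
  d <- c(6L, 6L, 6L)
  # uniform 30% fat fraction: fat = 30, water = 70
  fw <- fat_water_volume(array(30, d), array(70, d))
  mask <- segmentation_mask(array(1, d), spacing = c(2, 2, 2))
  res <- magdensity(fat_fraction(fw), mask)
  expect_equal(res$magdensity, 70)
  expect_equal(res$n_voxels, prod(d))
  expect_equal(res$mask_volume, prod(d) * 8)
  # pure fat -> MagDensity 0
  pure <- fat_water_volume(array(5, d), array(0, d))
  expect_equal(magdensity(fat_fraction(pure), mask)$magdensity, 0)
  # exact complement invariant
  set.seed(1)
  f <- array(runif(prod(d), 1, 9), d); w <- array(runif(prod(d), 1, 9), d)
  ffm <- fat_fraction(fat_water_volume(f, w))
  sel <- array(as.numeric(runif(prod(d)) > 0.5), d)
  m2 <- segmentation_mask(sel)
  expect_equal(magdensity(ffm, m2)$magdensity +
                 mean(ffm$ff[sel == 1]), 100)
  expect_error(magdensity(ffm, segmentation_mask(array(0, d))), "empty mask")
  # undefined voxels inside the mask are excluded and counted
  f2 <- f; f2[1, 1, 1] <- 0; w2 <- w; w2[1, 1, 1] <- 0
  res2 <- magdensity(fat_fraction(fat_water_volume(f2, w2)),
                     segmentation_mask(array(1, d)))
  expect_equal(res2$n_undefined, 1L)
  expect_equal(res2$n_voxels, prod(d) - 1L)
})

test_that("magdensity recovers the phantom's constructed density", {
  ph <- make_phantom(phantom_spec(seed = 8, density_fraction = 0.25,
                                  noise_sigma = 0))
  mask <- segmentation_mask(combined_truth(ph$truth), spacing = c(2, 2, 2))
  md <- magdensity(fat_fraction(ph$volume), mask)$magdensity
  expect_lt(abs(md - 25), 1)
})

test_that("delta statistics and paired MSE match hand arithmetic and oracles", {
  same <- paired_measures(1:3, c(10, 20, 30), c(10, 20, 30))
  expect_equal(delta_stats(same), list(mean_delta = 0, mean_abs_delta = 0,
                                       max_abs_delta = 0))
  expect_equal(mse_paired(same), 0)
  p <- paired_measures(1:2, c(1, 3), c(2, 5))
  expect_equal(delta_stats(p), list(mean_delta = 1.5, mean_abs_delta = 1.5,
                                    max_abs_delta = 2))
  expect_equal(mse_paired(p), 2.5)
  set.seed(0)
  t1 <- rnorm(25); t2 <- rnorm(25)
  pr <- paired_measures(1:25, t1, t2)
  dd <- t2 - t1
  expect_equal(delta_stats(pr),
               list(mean_delta = mean(dd), mean_abs_delta = mean(abs(dd)),
                    max_abs_delta = max(abs(dd))))
  expect_equal(mse_paired(pr), mean(dd^2))
  # mse >= (mean delta)^2, equality iff all deltas equal
  expect_gte(mse_paired(pr), delta_stats(pr)$mean_delta^2)
  shift <- paired_measures(1:4, c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(mse_paired(shift), delta_stats(shift)$mean_delta^2)
})

test_that("icc_a1 matches the sums-of-squares oracle and its edge cases", {
  set.seed(0)
  for (rep in 1:10) {
    x1 <- rnorm(10, 20, 5); x2 <- x1 + rnorm(10, 0, 2)
    p <- paired_measures(1:10, x1, x2)
    expect_equal(icc_a1(p)$icc, icc_oracle(x1, x2), tolerance = 1e-10)
  }
  # perfect agreement with inter-subject spread
  perf <- icc_a1(paired_measures(1:5, c(1, 5, 9, 13, 17), c(1, 5, 9, 13, 17)))
  expect_identical(perf$icc, 1)
  expect_identical(c(perf$ci_low, perf$ci_high), c(1, 1))
  # independent columns: ICC ~ 0
  set.seed(0)
  big <- paired_measures(1:2000, rnorm(2000), rnorm(2000))
  expect_lt(abs(icc_a1(big)$icc), 0.05)
  # invariances: common constant shift, subject relabeling
  x1 <- rnorm(12); x2 <- x1 + rnorm(12, 0, 0.5)
  r0 <- icc_a1(paired_measures(1:12, x1, x2))
  r_shift <- icc_a1(paired_measures(1:12, x1 + 100, x2 + 100))
  expect_equal(r_shift$icc, r0$icc, tolerance = 1e-12)
  ord <- sample(12)
  r_perm <- icc_a1(paired_measures(1:12, x1[ord], x2[ord]))
  expect_equal(r_perm$icc, r0$icc, tolerance = 1e-12)
  # CI brackets the estimate
  expect_lte(r0$ci_low, r0$icc)
  expect_gte(r0$ci_high, r0$icc)
  expect_error(icc_a1(paired_measures(1:2, c(1, 2), c(1, 2))), "3 subjects")
  expect_error(icc_a1(paired_measures(1:5, rep(3, 5), rep(3, 5))),
               "zero total variance")
})

test_that("power_simulation reproduces the published p at SD 1.42 and limits", {
  res <- power_simulation(n_per_group = 10, true_change = 1, sd = 1.42,
                          reps = 200, seed = 1)
  expect_equal(round(res$p_analytic, 2), 0.13)
  tiny <- power_simulation(n_per_group = 10, true_change = 1, sd = 1e-9,
                           reps = 50, seed = 1)
  expect_lt(tiny$p_analytic, 1e-10)
  expect_equal(tiny$power_mc, 1)
  # doubling n strictly decreases the analytic p
  p1 <- power_simulation(10, 1, 1.42, reps = 1, seed = 1)$p_analytic
  p2 <- power_simulation(20, 1, 1.42, reps = 1, seed = 1)$p_analytic
  expect_lt(p2, p1)
  # analytic branch agrees with stats::t.test on a constructed dataset
  g1 <- c(1.2, 0.8, 1.5, 0.5); g2 <- c(0.1, -0.2, 0.3, -0.1)
  tt <- t.test(g1, g2, var.equal = TRUE)
  d <- mean(g1) - mean(g2)
  sp <- sqrt((var(g1) + var(g2)) / 2)
  res2 <- power_simulation(n_per_group = 4, true_change = d, sd = sp,
                           reps = 1, seed = 1)
  expect_equal(res2$p_analytic, tt$p.value, tolerance = 1e-10)
})
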