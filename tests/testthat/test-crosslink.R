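simple_lane <- function(het1, het2, mono1 = 0, mono2 = 0, homo1 = 0,
                        homo2 = 0) {
  lane_table(species = rep(c("monomer", "homodimer", "heterodimer"), 2),
             channel = rep(c("ch1", "ch2"), each = 3),
             intensity = c(mono1, homo1, het1, mono2, homo2, het2))
}

test_that("channel normalization equalizes the heterodimer band", {
  lane <- simple_lane(het1 = 200, het2 = 100, mono1 = 60, mono2 = 80)
  norm <- normalize_channels(lane)
  expect_equal(attr(norm, "scale"), 0.5)
  expect_equal(norm$intensity[norm$species == "heterodimer" &
                              norm$channel == "ch1"], 100)
  expect_equal(norm$intensity[norm$species == "monomer" &
                              norm$channel == "ch1"], 30)
  # already-equal channels are untouched
  lane2 <- simple_lane(het1 = 100, het2 = 100, mono1 = 60)
  norm2 <- normalize_channels(lane2)
  expect_equal(attr(norm2, "scale"), 1)
  expect_equal(norm2$intensity, lane2$intensity)
  # zero heterodimer signal cannot be normalized
  expect_error(normalize_channels(simple_lane(het1 = 0, het2 = 100)),
               "not normalizable")
})

test_that("random assembly yields M*H/(M+H) expected heterodimers", {
  expect_equal(expected_heterodimer(100, 100), 50)
  expect_equal(expected_heterodimer(300, 100), 75)
  expect_equal(expected_heterodimer(100, 0), 0)
  expect_error(expected_heterodimer(0, 0), "m \\+ h")
})

test_that("the closed form matches Monte-Carlo random pairing within 3 SE", {
  set.seed(5)
  for (i in 1:6) {
    n1 <- sample(2000:20000, 1)
    n2 <- sample(2000:20000, 1)
    if ((n1 + n2) %% 2 == 1) n2 <- n2 + 1
    het <- oracle_pairing(n1, n2, seed = i)
    exp_het <- expected_heterodimer(n1, n2)
    # variance of the pairing count is bounded by binomial variance at
    # the heterodimer fraction
    p <- exp_het / ((n1 + n2) / 2)
    se <- sqrt((n1 + n2) / 2 * p * (1 - p))
    expect_lt(abs(het - exp_het), 3 * se + 3)
  }
})

test_that("expected heterodimers are symmetric, maximal at parity, homogeneous", {
  set.seed(6)
  m <- runif(20, 1, 500)
  h <- runif(20, 1, 500)
  expect_equal(expected_heterodimer(m, h), expected_heterodimer(h, m))
  tot <- m + h
  expect_true(all(expected_heterodimer(m, h) <=
                  expected_heterodimer(tot / 2, tot / 2) + 1e-12))
  expect_equal(expected_heterodimer(3.7 * m, 3.7 * h),
               3.7 * expected_heterodimer(m, h))
})

test_that("complete crosslinking at a balanced pool gives efficiency 1", {
  # all dimers crosslinked: random assembly of equal pools puts half the
  # dimers in the heterodimer band and a quarter in each homodimer band
  lane <- simple_lane(het1 = 50, het2 = 50, homo1 = 25, homo2 = 25)
  res <- crosslink_efficiency(lane)
  expect_equal(res$efficiency, 1.0)
  expect_false(res$model_violation)
  expect_equal(res$subunits_ch1, 100)

  # nothing crosslinked except a trace heterodimer band used for scaling
  lane0 <- simple_lane(het1 = 1e-6, het2 = 1e-6, mono1 = 100, mono2 = 100)
  expect_lt(crosslink_efficiency(lane0)$efficiency, 1e-7)
})

test_that("efficiencies above 1 are flagged, never clipped", {
  # heterodimers far beyond the random-assembly expectation
  lane <- simple_lane(het1 = 90, het2 = 90, mono1 = 10, mono2 = 10)
  res <- crosslink_efficiency(lane)
  expect_gt(res$efficiency, 1)
  expect_true(res$model_violation)
})

test_that("efficiency is invariant to rescaling one channel", {
  lane <- simple_lane(het1 = 80, het2 = 120, mono1 = 140, mono2 = 260,
                      homo1 = 30, homo2 = 10)
  eff <- crosslink_efficiency(lane)$efficiency
  lane_scaled <- lane
  ch1 <- lane_scaled$channel == "ch1"
  lane_scaled$intensity[ch1] <- lane_scaled$intensity[ch1] * 7.3
  expect_equal(crosslink_efficiency(lane_scaled)$efficiency, eff,
               tolerance = 1e-12)
})

test_that("simulated lanes conserve subunits and recover the true efficiency", {
  # subunit accounting on a noiseless lane is exact
  lane <- simulate_crosslink_lane(5000, frac_ch1 = 0.6, efficiency = 0.3,
                                  noise_cv = 0, seed = 3)
  res <- crosslink_efficiency(lane)
  expect_equal(res$subunits_ch1 + res$subunits_ch2, 10000, tolerance = 1e-9)

  # with densitometry noise and a channel gain mismatch, 20 independent
  # lanes recover the generating 30% efficiency
  effs <- vapply(1:20, function(s)
    crosslink_efficiency(simulate_crosslink_lane(
      10000, frac_ch1 = 0.6, efficiency = 0.3, noise_cv = 0.02,
      gain_ch1 = 1.8, seed = s))$efficiency, numeric(1))
  expect_lt(abs(mean(effs) - 0.3), 0.02)
  expect_lt(max(abs(effs - 0.3)), 0.06)
})

test_that("bootstrap intervals behave over replicates", {
  lanes <- lapply(1:4, function(i)
    simple_lane(het1 = 30, het2 = 30, mono1 = 70, mono2 = 70))
  b <- bootstrap_efficiency(lanes, n_boot = 200, seed = 2)
  expect_equal(b$lower, b$upper)  # identical replicates: zero width
  expect_true(b$interval_available)

  # two replicates with efficiencies 0.2 and 0.4 average to 0.3
  # with subunit totals fixed at 100 per channel, expected heterodimers
  # are 50, so a band of 10 dimer units is 20% efficiency
  l1 <- simple_lane(het1 = 10, het2 = 10, mono1 = 90, mono2 = 90)
  l2 <- simple_lane(het1 = 20, het2 = 20, mono1 = 80, mono2 = 80)
  expect_equal(crosslink_efficiency(l1)$efficiency, 0.2, tolerance = 1e-9)
  b2 <- bootstrap_efficiency(list(l1, l2), n_boot = 100, seed = 3)
  expect_equal(b2$mean, 0.3, tolerance = 1e-9)

  # single replicate: point estimate, interval flagged unavailable
  b1 <- bootstrap_efficiency(list(l1))
  expect_false(b1$interval_available)
  expect_true(is.na(b1$lower))

  # determinism under a fixed seed
  lanes_v <- lapply(1:5, function(i)
    simulate_crosslink_lane(3000, efficiency = 0.3, noise_cv = 0.05,
                            seed = i))
  expect_identical(bootstrap_efficiency(lanes_v, 300, seed = 7),
                   bootstrap_efficiency(lanes_v, 300, seed = 7))
})

test_that("bootstrap percentile intervals cover the truth in most trials", {
  covered <- vapply(1:120, function(trial) {
    lanes <- lapply(1:8, function(i)
      simulate_crosslink_lane(1500, frac_ch1 = 0.55, efficiency = 0.3,
                              noise_cv = 0.05, seed = trial * 100 + i))
    b <- bootstrap_efficiency(lanes, n_boot = 200, seed = trial)
    b$lower <= 0.3 && b$upper >= 0.3
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})
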