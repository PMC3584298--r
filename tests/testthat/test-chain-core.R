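test_that("store intensities follow the cascade closed forms", {
  expect_equal(store_intensity(chain_params(mu = 2, a = 0.3), 1, 0), 2)

  cho <- cho_chain()
  # hippocampal decline after 3.5 days
  expect_equal(store_intensity(cho, 1, 3.5), 1.5 * exp(-0.103 * 3.5),
               tolerance = 1e-12)
  # neocortical asymptote mu1 mu2 / a1 (a2 = 0)
  expect_equal(store_intensity(cho, 2, 1e7), 1.5 * 0.00325 / 0.103,
               tolerance = 1e-9)
  # store-2 build-up closed form at finite t
  t <- c(3.5, 14, 56)
  expect_equal(store_intensity(cho, 2, t),
               (1.5 * 0.00325 / 0.103) * (1 - exp(-0.103 * t)),
               tolerance = 1e-12)
})

test_that("total intensity sums stores and applies cue quality once", {
  cp <- demo_chain()
  expect_equal(total_intensity(cp, 0), 2)            # r2(0) = 0, q = 1
  expect_equal(total_intensity(cp, 5), 0.9641735, tolerance = 1e-7)
  cp_half <- chain_params(mu = c(2, 0.1), a = c(0.3, 0), q = 0.5)
  tt <- c(0, 1, 5, 30)
  expect_equal(total_intensity(cp_half, tt), 0.5 * total_intensity(cp, tt),
               tolerance = 1e-14)
})

test_that("recall probability is the exponential link with guessing floor", {
  cp <- demo_chain()
  expect_equal(recall_probability(cp, 0), 1 - exp(-2), tolerance = 1e-12)
  # zero intensity recalls at the floor
  empty <- chain_params(mu = c(0, 0), a = c(0.3, 0))
  expect_equal(recall_probability(empty, 5), 0)
  empty_g <- chain_params(mu = c(0, 0), a = c(0.3, 0), g = 0.5)
  expect_equal(recall_probability(empty_g, 5), 0.5)
  # huge intensity saturates at 1 regardless of the floor
  big <- chain_params(mu = c(500, 0), a = c(0, 0), g = 0.5)
  expect_equal(recall_probability(big, 0), 1, tolerance = 1e-12)
})

test_that("intensity/probability link is a bijection at g = 0", {
  expect_equal(intensity_from_probability(0), 0)
  # p = 0.90 is more than 150% stronger than p = 0.60, not 50%
  r <- intensity_from_probability(c(0.90, 0.60))
  expect_equal(r, c(2.302585, 0.9162907), tolerance = 1e-6)
  expect_gt(r[1] / r[2], 2.5)
  # round trip
  set.seed(11)
  x <- stats::rexp(50, 0.5)
  expect_equal(intensity_from_probability(1 - exp(-x)), x,
               tolerance = 1e-12)
  expect_error(intensity_from_probability(-0.1))
  expect_error(intensity_from_probability(1, strict = TRUE))
  expect_warning(r1 <- intensity_from_probability(1), "clipped")
  expect_true(is.finite(r1))
})

test_that("closed forms agree with the numeric oracle on random chains", {
  set.seed(42)
  for (rep in 1:25) {
    for (ns in 2:3) {
      cp <- random_chain(ns)
      tt <- sort(stats::runif(6, 0, 20))
      cf <- intensity_curve(cp, tt)
      oc <- ode_oracle(cp, times = tt)
      # error relative to the solution scale (tiny components cannot be
      # certified beyond the integrator's absolute tolerance)
      expect_lt(max(abs(cf$per_store - oc$per_store)) / max(oc$total), 1e-8)
      expect_equal(cf$total, rowSums(cf$per_store), tolerance = 1e-14)
      expect_true(all(cf$per_store >= 0))
    }
  }
})

test_that("confluent decline rates fall back to the exact limit form", {
  cp <- chain_params(mu = c(1.3, 0.25), a = c(0.4, 0.4))
  tt <- c(0, 0.5, 2, 8)
  expect_equal(store_intensity(cp, 2, tt), 1.3 * 0.25 * tt * exp(-0.4 * tt),
               tolerance = 1e-8)
  # a1 = a2 = 0: undamped consolidation grows linearly, no division by zero
  cp0 <- chain_params(mu = c(2, 0.1), a = c(0, 0))
  expect_equal(store_intensity(cp0, 2, c(1, 5)), 2 * 0.1 * c(1, 5),
               tolerance = 1e-8)
})

test_that("total intensity is monotone decreasing iff mu2 < a1 (a2 = 0)", {
  tt <- seq(0, 10, by = 0.1)
  forgetting <- chain_params(mu = c(2, 0.1), a = c(0.3, 0))   # mu2 < a1
  expect_true(all(diff(total_intensity(forgetting, tt)) < 0))
  reminiscence <- chain_params(mu = c(2, 0.5), a = c(0.3, 0)) # mu2 > a1
  expect_true(all(diff(total_intensity(reminiscence, tt)) > 0))
})

test_that("recall probability approaches the consolidation asymptote", {
  cp <- chain_params(mu = c(2, 0.1), a = c(0.3, 0), q = 0.8)
  expect_equal(recall_probability(cp, 1e8),
               1 - exp(-0.8 * 2 * 0.1 / 0.3), tolerance = 1e-9)
})

test_that("power decline gives the stated store-1 form and a consistent cascade", {
  cp <- chain_params(mu = c(2, 0.1), a = c(0.6, 0.02), decline = "power")
  tt <- c(0, 1, 5, 20)
  expect_equal(store_intensity(cp, 1, tt), 2 * (1 + tt)^(-0.6),
               tolerance = 1e-12)
  oc <- ode_oracle(cp, times = tt)
  cf <- intensity_curve(cp, tt)
  expect_equal(cf$per_store, oc$per_store, tolerance = 1e-8)
})

test_that("invalid inputs are rejected with clear errors", {
  cp <- demo_chain()
  expect_error(store_intensity(cp, 3, 1), "store index")
  expect_error(store_intensity(cp, 1, -1), "nonnegative")
  expect_error(chain_params(mu = c(-1, 0), a = c(1, 0)))
  expect_error(chain_params(mu = 1, a = 1, q = 0))
  expect_error(chain_params(mu = 1, a = 1, g = 1))
})
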