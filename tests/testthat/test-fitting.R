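les2 <- function() list(control = NULL, lesion = full_lesion())

noiseless_data <- function(cp, times = c(3.5, 7, 14, 28, 56), trials = 500) {
  les <- les2()
  retention_data(data.frame(
    group = rep(c("control", "lesion"), each = length(times)),
    time = rep(times, 2),
    proportion = c(recall_probability(cp, times),
                   recall_probability(cp, times, les$lesion)),
    trials = trials))
}

test_that("noiseless curves are recovered to high precision", {
  cp <- cho_chain()
  fit <- fit_memory_chain(noiseless_data(cp), lesions = les2(),
                          multistart = 16, seed = 3)
  truth <- c(mu1 = 1.5, a1 = 0.103, mu2 = 0.00325)
  expect_lt(max(abs(coef(fit) - truth) / truth), 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_lt(fit$sse, 1e-12)
  expect_identical(fit$convergence, 0L)
})

test_that("fits are bit-identical under a fixed seed", {
  cp <- cho_chain()
  dat <- simulate_retention(cp, c(3.5, 7, 14, 28), n = 50,
                            lesions = les2(), seed = 9)
  f1 <- fit_memory_chain(dat, lesions = les2(), multistart = 8, seed = 4)
  f2 <- fit_memory_chain(dat, lesions = les2(), multistart = 8, seed = 4)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$sse, f2$sse)
})

test_that("binomial likelihood loss fits the same generative model", {
  cp <- cho_chain()
  dat <- simulate_retention(cp, c(3.5, 7, 14, 28, 56), n = 200,
                            lesions = les2(), seed = 21)
  fit <- fit_memory_chain(dat, lesions = les2(), loss = "binomial",
                          multistart = 8, seed = 5)
  truth <- c(mu1 = 1.5, a1 = 0.103, mu2 = 0.00325)
  expect_lt(max(abs(coef(fit) - truth) / truth), 0.5)
})

test_that("a free lesion fraction is estimated, shared or per group", {
  cp <- demo_chain()
  les_true <- lesion_profile(lambda = c(0.7, 0))
  times <- c(1, 2, 4, 8, 16)
  dat <- retention_data(data.frame(
    group = rep(c("control", "patient"), each = 5),
    time = rep(times, 2),
    proportion = c(recall_probability(cp, times),
                   recall_probability(cp, times, les_true)),
    trials = 100))
  fit <- fit_memory_chain(
    dat, lesions = list(control = NULL,
                        patient = lesion_profile(lambda = c(NA, 0))),
    multistart = 16, seed = 6)
  est <- coef(fit)
  expect_equal(unname(est[["lambda1:patient"]]), 0.7, tolerance = 1e-3)
  expect_equal(unname(est[["a1"]]), 0.3, tolerance = 1e-3)
})

test_that("flat data produce a flagged degenerate fit", {
  # a temporally flat dataset carries no signal about the decline rates:
  # the optimum is a ridge (any mu1 mu2 / a1 matching the flat intensity),
  # so the contract is a degeneracy flag, with some parameter at a bound
  flat <- retention_data(data.frame(
    group = rep(c("control", "lesion"), each = 4),
    time = rep(c(1, 2, 4, 8), 2),
    proportion = 0.5, trials = 20))
  expect_warning(
    fit <- fit_memory_chain(flat, lesions = les2(), multistart = 8,
                            seed = 7),
    "at bound")
  expect_true(any(fit$par_table$at_bound))
  expect_lt(diff(range(fitted(fit))), 1e-3)   # flat solution found
})

test_that("under-identified specifications fail before optimisation", {
  tiny <- retention_data(data.frame(group = "g", time = c(1, 2),
                                    proportion = c(0.7, 0.5), trials = 10))
  expect_error(fit_memory_chain(tiny), "under-identified")
})

test_that("freeing a parameter never increases the minimised SSE", {
  cp <- demo_chain()
  dat <- simulate_retention(cp, c(1, 2, 4, 8, 16), n = 40,
                            lesions = list(control = NULL,
                                           patient = lesion_profile(
                                             lambda = c(0.7, 0))),
                            seed = 31)
  restricted <- fit_memory_chain(
    dat, lesions = list(control = NULL,
                        patient = lesion_profile(lambda = c(1, 0))),
    multistart = 16, seed = 8)
  extended <- fit_memory_chain(
    dat, lesions = list(control = NULL,
                        patient = lesion_profile(lambda = c(NA, 0))),
    multistart = 16, seed = 8)
  expect_lte(extended$sse, restricted$sse + 1e-9)
})

test_that("estimator bias shrinks as trial counts grow", {
  cp <- cho_chain()
  times <- c(3.5, 8, 20, 56)
  errs <- sapply(c(20, 100, 1000), function(n) {
    est <- sapply(1:12, function(i) {
      dat <- simulate_retention(cp, times, n = n, lesions = les2(),
                                seed = 7000 + 13 * n + i)
      coef(fit_memory_chain(dat, lesions = les2(), multistart = 6,
                            seed = 1))
    })
    max(abs(apply(est, 1, median) - c(1.5, 0.103, 0.00325)) /
          c(1.5, 0.103, 0.00325))
  })
  expect_lt(errs[3], 0.10)          # near-unbiased at n = 1000
  expect_lt(errs[3], errs[1] + 0.05) # no blow-up as n grows
})

test_that("fit methods expose predictions, residuals and simulations", {
  cp <- cho_chain()
  dat <- simulate_retention(cp, c(3.5, 7, 14, 28), n = 60,
                            lesions = les2(), seed = 12)
  fit <- fit_memory_chain(dat, lesions = les2(), multistart = 8, seed = 2)
  expect_equal(predict(fit), fitted(fit), tolerance = 1e-12)
  pr <- predict(fit, data.frame(group = "lesion", time = c(0, 5, 10)))
  expect_true(all(pr >= 0 & pr < 1))
  expect_true(all(diff(pr) > 0))    # Ribot ordering in predictions
  ri <- predict(fit, data.frame(group = "control", time = c(1, 5)),
                type = "intensity")
  expect_equal(1 - exp(-ri),
               predict(fit, data.frame(group = "control", time = c(1, 5))),
               tolerance = 1e-12)
  expect_equal(residuals(fit), dat$proportion - fitted(fit),
               tolerance = 1e-12)
  sims <- simulate(fit, nsim = 2, seed = 99)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "retention_data")
  expect_identical(sims[[1]]$trials, dat$trials)
  s <- summary(fit)
  expect_s3_class(s, "summary.memory_chain_fit")
  expect_equal(s$lifetime, 1 / coef(fit)[["a1"]], tolerance = 1e-12)
})

test_that("goodness-of-fit statistics match hand computation", {
  g <- goodness(c(0.6, 0.4), c(0.5, 0.5), trials = c(10, 10))
  expect_equal(g$sse, 0.02, tolerance = 1e-12)
  expect_equal(g$chisq, 0.8, tolerance = 1e-12)
  gp <- goodness(c(0.6, 0.4), c(0.6, 0.4), trials = c(10, 10), n_free = 1)
  expect_equal(gp$sse, 0)
  expect_equal(gp$r_squared, 1)
  expect_equal(gp$chisq, 0)
  # the mean-only predictor has R^2 = 0 by definition
  obs <- c(0.2, 0.5, 0.8)
  g0 <- goodness(obs, rep(mean(obs), 3))
  expect_equal(g0$r_squared, 0, tolerance = 1e-12)
  expect_warning(goodness(c(0.5), c(1), trials = 10), "undefined")
})

test_that("MTL lifetime is the inverse decline rate", {
  expect_equal(round(mtl_lifetime(0.103), 1), 9.7)
  expect_equal(round(mtl_lifetime(0.286), 1), 3.5)
  expect_equal(mtl_lifetime(1), 1)
  expect_error(mtl_lifetime(0), "positive")
})
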