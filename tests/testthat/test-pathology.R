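test_that("identity profile leaves the chain untouched", {
  cp <- demo_chain()
  tt <- c(0, 1, 5, 20)
  expect_equal(lesioned_intensity(cp, lesion_profile(), tt),
               total_intensity(cp, tt), tolerance = 1e-14)
  expect_equal(ribot_gradient(cp, lesion_profile(lambda = c(0, 0)), tt),
               recall_probability(cp, tt), tolerance = 1e-14)
})

test_that("lesioned intensity weights stores by 1 - lambda", {
  cp <- demo_chain()
  # full hippocampal lesion leaves only the consolidated neocortical trace
  tt <- c(1, 5, 20)
  expect_equal(lesioned_intensity(cp, full_lesion(), tt),
               (2 * 0.1 / 0.3) * (1 - exp(-0.3 * tt)), tolerance = 1e-12)
  # partial lesion, frozen oracle value
  expect_equal(lesioned_intensity(cp, lesion_profile(lambda = c(0.5, 0)), 2),
               0.8496039, tolerance = 1e-7)
  # cross-check against the numeric oracle with the lesion applied
  les <- lesion_profile(lambda = c(0.5, 0))
  oc <- ode_oracle(cp, les, times = tt)
  expect_equal(lesioned_intensity(cp, les, tt), oc$total, tolerance = 1e-9)
})

test_that("Ribot gradient rises with memory age under a full lesion", {
  cp <- demo_chain()
  tt <- seq(0, 40, by = 0.5)
  pr <- ribot_gradient(cp, full_lesion(), tt)
  expect_equal(pr[1], 0)                      # nothing consolidated at t = 0
  expect_true(all(diff(pr) >= 0))             # Ribot's Law
  expect_equal(ribot_gradient(cp, full_lesion(), 1e8),
               1 - exp(-2 * 0.1 / 0.3), tolerance = 1e-9)
})

test_that("lesioned recall never exceeds control recall", {
  set.seed(7)
  for (rep in 1:10) {
    cp <- random_chain(2)
    lam <- stats::runif(1, 0.1, 1)
    tt <- sort(stats::runif(8, 0, 15))
    p_les <- ribot_gradient(cp, lesion_profile(lambda = c(lam, 0)), tt)
    p_ctl <- recall_probability(cp, tt)
    expect_true(all(p_les <= p_ctl + 1e-12))
  }
})

test_that("post-lesion intensity decays at the final store's rate", {
  cp <- demo_chain()
  les <- lesion_profile(lambda = c(0.5, 0))
  expect_equal(post_lesion_decay(cp, les, t_l = 3, tau = 0),
               lesioned_intensity(cp, les, 3), tolerance = 1e-14)
  # a2 = 0: post-lesion forgetting negligible, flat in tau
  expect_equal(post_lesion_decay(cp, les, 3, c(0, 5, 50)),
               rep(lesioned_intensity(cp, les, 3), 3), tolerance = 1e-14)
  cp2 <- chain_params(mu = c(2, 0.1), a = c(0.3, 0.1))
  expect_equal(post_lesion_decay(cp2, les, 3, 10),
               post_lesion_decay(cp2, les, 3, 0) * exp(-1),
               tolerance = 1e-12)
})

test_that("named pathology profiles encode the clinical mechanisms", {
  cp <- demo_chain()
  tt <- c(1, 5, 20)
  # Korsakoff with full lesion reduces to the Ribot gradient
  kor <- pathology_profile("korsakoff", lambda = 1)
  expect_equal(ribot_gradient(cp, kor, tt),
               ribot_gradient(cp, full_lesion(), tt), tolerance = 1e-14)
  # Alzheimer with lambda2 = 0 is Korsakoff
  alz0 <- pathology_profile("alzheimer", lambda = 0.6, lambda2 = 0)
  kor6 <- pathology_profile("korsakoff", lambda = 0.6)
  expect_equal(ribot_gradient(cp, alz0, tt), ribot_gradient(cp, kor6, tt),
               tolerance = 1e-14)
  # extra neocortical damage only hurts
  alz <- pathology_profile("alzheimer", lambda = 0.6, lambda2 = 0.3)
  expect_true(all(ribot_gradient(cp, alz, tt) <
                    ribot_gradient(cp, kor6, tt)))
  # Huntington: flat rr at q_H, and the curve-shape identity
  hun <- pathology_profile("huntington", q_H = 0.6)
  expect_equal(rr_model(cp, hun, tt)$rr, rep(0.6, 3), tolerance = 1e-12)
  p_ctl <- recall_probability(cp, tt)
  expect_equal(recall_probability(cp, tt, hun),
               1 - (1 - p_ctl)^0.6, tolerance = 1e-12)
  expect_error(pathology_profile("korsakoff"), "lambda")
  expect_error(pathology_profile("huntington", q_H = 1.5))
})

test_that("anterograde lesions scale induction rates", {
  cp <- chain_params(mu = c(5.61, 0.0599), a = c(0.185, 0))
  les <- lesion_profile(induction = c(1, 0.3))
  scaled <- chain_params(mu = c(5.61, 0.0599 * 0.3), a = c(0.185, 0))
  tt <- c(8, 15, 60, 600)
  expect_equal(lesioned_intensity(cp, les, tt), total_intensity(scaled, tt),
               tolerance = 1e-12)
})
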