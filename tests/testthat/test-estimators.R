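test_that("every variant recovers CBT exactly from error-free readings", {
  t_ambs <- c(-15, 0, 20, 30, 45)
  cbts <- c(35, 36.5, 38, 40, 42)
  ratios <- c(1.5, 2, 8)  # h_s1/h_s2 via channel-2 thickness
  for (r in ratios) {
    p <- dhf_probe(d_s2_mm = 15 * r)
    co <- derive_channel_coefficients(p)
    for (cbt in cbts) for (ta in t_ambs) {
      truth <- simulate_true_readings(co, dhf_env(cbt, ta))
      for (v in dhf_variants()) {
        e <- estimate_cbt(v, true_measured_set(v, truth, co))
        expect_true(e$finite)
        expect_equal(e$value, cbt, tolerance = 1e-9,
                     label = sprintf("%s r=%g cbt=%g ta=%g", v, r, cbt, ta))
      }
    }
  }
})

test_that("skin coefficient estimate returns h_t and rejects equal surface temps", {
  r <- dhf_forward()
  expect_equal(skin_coefficient_estimate(r$q_1, r$q_2, r$T_ss1, r$T_ss2), 148)
  expect_equal(
    skin_coefficient_estimate(44.331, 32.372, 36.7005, 36.7813), 148,
    tolerance = 1e-3)
  expect_error(skin_coefficient_estimate(10, 5, 36, 36), "undefined")
})

test_that("a +0.05 degC error on T_ss1 biases the HT estimate as direct substitution predicts", {
  r <- dhf_forward()
  m <- measured_set("HT", list(T_ss1 = r$T_ss1 + 0.05, T_ss2 = r$T_ss2,
                               q_1 = r$q_1, q_2 = r$q_2))
  # frozen by hand: T1' + q1 (T1' - T2)/(q2 - q1) with the default readings
  expect_equal(estimate_cbt("HT", m)$value, 36.864654, tolerance = 1e-6)
})

test_that("an exactly-zero denominator flags the estimate non-finite without error", {
  m <- measured_set("HT", list(T_ss1 = 36.7, T_ss2 = 36.8, q_1 = 40, q_2 = 40))
  e <- estimate_cbt("HT", m)
  expect_false(e$finite)
  expect_false(is.finite(e$value))
  m2 <- measured_set("TTp", list(T_ss1 = 36.7, dT_ss = -0.08,
                                 dT_s1 = 4.4, dT_s2 = 8.8), k_meas = 0.5)
  expect_false(estimate_cbt("TTp", m2)$finite)
})

test_that("swapping channel labels (k -> 1/k) leaves error-free estimates unchanged", {
  p <- dhf_probe()
  swapped <- dhf_probe(k_s1 = p$k_s2, k_s2 = p$k_s1,
                       d_s1_mm = 1000 * p$d_s2, d_s2_mm = 1000 * p$d_s1)
  co <- derive_channel_coefficients(swapped)
  expect_equal(co$k, 2)  # 1/0.5
  truth <- simulate_true_readings(co, dhf_env(37, 25))
  for (v in dhf_variants())
    expect_equal(estimate_cbt(v, true_measured_set(v, truth, co))$value, 37,
                 tolerance = 1e-9, label = v)
})

test_that("TT equals TTp when differentials come from the same absolute temperatures", {
  set.seed(17)
  for (i in 1:10) {
    T_ss1 <- 36.7 + rnorm(1, 0, 0.1); T_ss2 <- 36.78 + rnorm(1, 0, 0.1)
    T_sa1 <- 32.3 + rnorm(1, 0, 0.5); T_sa2 <- 30.3 + rnorm(1, 0, 0.5)
    k <- runif(1, 0.2, 0.9)
    tt <- estimate_cbt("TT", measured_set(
      "TT", list(T_ss1 = T_ss1, T_ss2 = T_ss2, T_sa1 = T_sa1, T_sa2 = T_sa2),
      k_meas = k))
    ttp <- estimate_cbt("TTp", measured_set(
      "TTp", list(T_ss1 = T_ss1, dT_ss = T_ss1 - T_ss2,
                  dT_s1 = T_ss1 - T_sa1, dT_s2 = T_ss2 - T_sa2),
      k_meas = k))
    expect_equal(tt$value, ttp$value, tolerance = 1e-12)
  }
})

test_that("averaging variants equal the mean of their per-equation estimates", {
  set.seed(23)
  for (i in 1:10) {
    # arbitrary (noisy-looking) measured values, not an error-free point
    T1 <- 36.7 + rnorm(1, 0, 0.1); T2 <- 36.78 + rnorm(1, 0, 0.1)
    Ta1 <- 32.3 + rnorm(1, 0, 0.1); Ta2 <- 30.3 + rnorm(1, 0, 0.1)
    dss <- -0.08 + rnorm(1, 0, 0.01)
    ds1 <- 4.43 + rnorm(1, 0, 0.05); ds2 <- 6.47 + rnorm(1, 0, 0.05)
    q1 <- 44.3 + rnorm(1); q2 <- 32.4 + rnorm(1)
    k <- 0.5
    htpm <- estimate_cbt("HTpm", measured_set(
      "HTpm", list(T_ss1 = T1, T_ss2 = T2, dT_ss = dss, q_1 = q1, q_2 = q2)))
    eq8 <- T1 + q1 * dss / (q2 - q1)
    eq13 <- T2 + q2 * dss / (q2 - q1)
    expect_equal(htpm$value, (eq8 + eq13) / 2, tolerance = 1e-12)
    ttpm <- estimate_cbt("TTpm", measured_set(
      "TTpm", list(T_ss1 = T1, T_ss2 = T2, T_sa1 = Ta1, T_sa2 = Ta2,
                   dT_ss = dss, dT_s1 = ds1, dT_s2 = ds2), k_meas = k))
    f <- ds1 * dss / (k * ds2 - ds1)
    four <- c(T1 + f, T2 + dss + f, Ta1 + ds1 + f, Ta2 + dss + ds2 + f)
    expect_equal(ttpm$value, mean(four), tolerance = 1e-12)
  }
})

test_that("measured sets are validated against their variant's component list", {
  expect_error(measured_set("HT", list(T_ss1 = 36.7, q_1 = 44, q_2 = 32)),
               "missing: T_ss2")
  expect_error(
    measured_set("HTp", list(T_ss1 = 36.7, T_ss2 = 36.8, dT_ss = -0.08,
                             q_1 = 44, q_2 = 32)),
    "unexpected: T_ss2")
  expect_error(
    measured_set("TT", list(T_ss1 = 36.7, T_ss2 = 36.8,
                            T_sa1 = 32, T_sa2 = 30)),
    "k_meas")
  expect_error(
    measured_set("TTp", list(T_ss1 = 36.7, dT_ss = -0.08,
                             dT_s1 = 4.4, dT_s2 = 6.5), k_meas = -0.5),
    "k_meas")
  expect_error(
    measured_set("HT", list(T_ss1 = 36.7, T_ss2 = 36.8, q_1 = 44, q_2 = 32),
                 k_meas = 0.5),
    "TT-family")
  m <- measured_set("HT", list(T_ss1 = 36.7, T_ss2 = 36.8, q_1 = 44, q_2 = 32))
  expect_error(estimate_cbt("TT", m), "built for variant")
})
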