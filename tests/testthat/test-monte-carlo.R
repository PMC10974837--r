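test_that("zero noise gives an exactly zero uncertainty estimate", {
  for (v in c("HT", "TTpm")) {
    mc <- estimate_uncertainty(v, noise = zero_noise(), n_reps = 50,
                               n_trials = 3, seed = 1)
    expect_equal(mc$mu_cbt, 0)
    expect_equal(mc$su_cbt, 0)
    expect_equal(mc$nonfinite_count, 0L)
  }
})

test_that("a singular point with zero noise propagates as counted non-finites", {
  s <- run_mc_trial("HT", dhf_probe(), dhf_env(37, 37), zero_noise(),
                    n_reps = 20)
  expect_false(is.finite(as.numeric(s)))
  expect_equal(attr(s, "nonfinite"), 20L)
})

test_that("the same master seed reproduces the full Monte Carlo result", {
  a <- estimate_uncertainty("TTp", n_reps = 200, n_trials = 5, seed = 99)
  b <- estimate_uncertainty("TTp", n_reps = 200, n_trials = 5, seed = 99)
  expect_identical(a, b)
  c <- estimate_uncertainty("TTp", n_reps = 200, n_trials = 5, seed = 100)
  expect_false(identical(a$trial_sds, c$trial_sds))
})

test_that("Monte Carlo dispersion matches the first-order budget in the stable region", {
  # TT-family variants are nearly linear at the default operating point,
  # so mean trial SD falls within the trial-to-trial repeatability band
  for (v in c("TT", "TTp", "TTpm")) {
    mc <- estimate_uncertainty(v, n_reps = 2000, n_trials = 20, seed = 314)
    u <- combined_uncertainty(v)$u_combined
    expect_lt(abs(mc$mu_cbt - u), 3 * mc$su_cbt, label = v)
  }
  # flux-based variants carry a small positive second-order excess from the
  # noisy flux-difference denominator; the budget still agrees to within 8%
  for (v in c("HT", "HTp", "HTpm")) {
    mc <- estimate_uncertainty(v, n_reps = 2000, n_trials = 20, seed = 314)
    u <- combined_uncertainty(v)$u_combined
    expect_lt(abs(mc$mu_cbt - u) / u, 0.08, label = v)
    expect_gt(mc$mu_cbt, u)  # the excess is one-sided
  }
})

test_that("HT with flux noise off reproduces the closed-form amplification", {
  mc <- estimate_uncertainty("HT", noise = dhf_noise(u_q = 0),
                             n_reps = 2000, n_trials = 15, seed = 271)
  expect_lt(abs(mc$mu_cbt - 0.2432727), 3 * mc$su_cbt)
})

test_that("repeatability shrinks roughly as 1/sqrt(n_reps)", {
  m1 <- estimate_uncertainty("TTp", n_reps = 1000, n_trials = 30, seed = 31)
  m4 <- estimate_uncertainty("TTp", n_reps = 4000, n_trials = 30, seed = 32)
  expect_lt(abs(m1$su_cbt / m4$su_cbt - 2) / 2, 0.3)
})

test_that("temperature-noise-only uncertainty is ambient-invariant in the stable region", {
  tn <- dhf_noise(u_q = 0, u_h = 0)
  for (v in c("HT", "TTp")) {
    a <- estimate_uncertainty(v, env = dhf_env(37, 25), noise = tn,
                              n_reps = 2000, n_trials = 15, seed = 61)
    b <- estimate_uncertainty(v, env = dhf_env(37, -15), noise = tn,
                              n_reps = 2000, n_trials = 15, seed = 62)
    expect_lt(abs(a$mu_cbt - b$mu_cbt), 3 * max(a$su_cbt, b$su_cbt), label = v)
  }
})

test_that("pairing reduces uncertainty; averaging does not increase it", {
  mcs <- lapply(dhf_variants(), estimate_uncertainty,
                n_reps = 2000, n_trials = 15, seed = 1234)
  names(mcs) <- dhf_variants()
  expect_lt(mcs$HTp$mu_cbt, mcs$HT$mu_cbt)
  expect_lt(mcs$TTp$mu_cbt, mcs$TT$mu_cbt)
  expect_lt(mcs$HTpm$mu_cbt,
            mcs$HTp$mu_cbt + 2 * max(mcs$HTpm$su_cbt, mcs$HTp$su_cbt))
  expect_lt(mcs$TTpm$mu_cbt,
            mcs$TTp$mu_cbt + 2 * max(mcs$TTpm$su_cbt, mcs$TTp$su_cbt))
})

test_that("sweep grids implement the documented parameter linkages", {
  e1 <- dhf_experiment("e1")
  expect_length(e1$grid, 121)
  expect_equal(range(e1$grid), c(-15, 45))
  expect_equal(range(dhf_experiment("e1_narrow")$grid), c(36.95, 37.05))
  expect_equal(range(dhf_experiment("e5")$grid), c(6, 104))
  # common-conductivity sweep: k = 0.01 W/(m K) gives h_s1 = 0.01/0.015
  g <- build_sweep_grid(sweep_spec("hs_pair", c(0.01, 1, 100)))
  co <- derive_channel_coefficients(g[[1]]$probe)
  expect_equal(co$h_s1, 2 / 3, tolerance = 1e-9)
  expect_equal(co$h_s1 / co$h_s2, 2)  # ratio preserved along the sweep
  # ratio sweep: r = 2 reproduces the default 30 mm channel
  g <- build_sweep_grid(sweep_spec("hs_ratio", c(1.25, 2, 10)))
  expect_equal(g[[2]]$probe$d_s2, 0.030)
  expect_equal(derive_channel_coefficients(g[[3]]$probe)$k, 0.1)
  # environment sweeps touch only the environment
  g <- build_sweep_grid(sweep_spec("tamb", c(-15, 45)))
  expect_equal(g[[2]]$env$t_amb, 45)
  expect_identical(g[[1]]$probe, dhf_probe())
  expect_error(sweep_spec("banana", 1:3), "arg")
  expect_error(sweep_spec("tamb", c(1, 1, 2)), "monotone")
})

test_that("a sweep yields one row per variant and grid point, deterministically", {
  sp <- sweep_spec("tamb", c(0, 10, 20))
  tab <- run_sweep(sp, variants = c("HT", "TTp"), n_reps = 100, n_trials = 3,
                   seed = 5)
  expect_s3_class(tab, "dhf_sweep")
  expect_equal(nrow(tab), 6)
  expect_identical(names(tab),
                   c("variant", "parameter", "value", "mu_cbt", "su_cbt",
                     "n_reps", "n_trials", "seed", "nonfinite_count"))
  expect_equal(sort(unique(tab$value)), c(0, 10, 20))
  tab2 <- run_sweep(sp, variants = c("HT", "TTp"), n_reps = 100, n_trials = 3,
                    seed = 5)
  expect_identical(tab, tab2)
})
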