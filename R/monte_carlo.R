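#' One Monte Carlo trial: the sample SD of estimation errors
#'
#' Simulates the error-free readings once, draws `n_reps` noisy measured
#' sets, applies the variant's estimator to each, and returns the sample
#' standard deviation (n - 1 denominator) of the estimation errors
#' (estimate minus the true CBT). Non-finite estimates (zero denominators)
#' are never dropped: they make the returned SD non-finite and are counted
#' in attribute `"nonfinite"`, because the explosive behaviour near singular
#' operating points is part of what the analysis measures.
#'
#' @param variant one of [dhf_variants()].
#' @param probe a [dhf_probe()].
#' @param env a [dhf_env()].
#' @param noise a [dhf_noise()].
#' @param n_reps number of noisy repetitions (>= 2).
#' @return Per-trial uncertainty estimate, deg C, with attributes
#'   `"nonfinite"` and `"redraws"`.
#' @export
run_mc_trial <- function(variant, probe, env, noise, n_reps = 10000) {
  stopifnot(n_reps >= 2)
  co <- derive_channel_coefficients(probe)
  truth <- simulate_true_readings(co, env)
  m <- sample_measured_set(variant, truth, co, noise, n = n_reps)
  est <- estimate_cbt(variant, m)
  err <- est$value - env$cbt
  out <- stats::sd(err)
  attr(out, "nonfinite") <- sum(!est$finite)
  attr(out, "redraws") <- attr(m, "redraws")
  out
}

#' Monte Carlo uncertainty of a CBT estimator, with repeatability
#'
#' Runs [run_mc_trial()] `n_trials` times and summarises the per-trial
#' uncertainty estimates: `mu_cbt` is their mean (the predicted standard
#' uncertainty of the variant at this operating point) and `su_cbt` their
#' sample SD (the repeatability of the Monte Carlo estimate itself, usable
#' as a confidence measure on `mu_cbt`).
#'
#' Reproducibility: the master `seed` seeds a draw of one 31-bit child seed
#' per trial (`sample.int(2^31 - 1, n_trials)`); each trial then reseeds the
#' generator with its child seed, so trials are mutually independent and the
#' whole result is reproducible bit-for-bit.
#'
#' @inheritParams run_mc_trial
#' @param n_trials number of repeated trials (>= 2).
#' @param seed master seed (integer); `NULL` leaves the RNG state alone.
#' @return An object of class `dhf_mc`: list with `mu_cbt`, `su_cbt`,
#'   `trial_sds`, `n_reps`, `n_trials`, `seed`, `nonfinite_count`, `redraws`,
#'   `variant`.
#' @export
estimate_uncertainty <- function(variant, probe = dhf_probe(), env = dhf_env(),
                                 noise = dhf_noise(), n_reps = 10000,
                                 n_trials = 100, seed = NULL) {
  stopifnot(n_trials >= 2)
  variant <- match.arg(variant, dhf_variants())
  if (!is.null(seed)) set.seed(seed)
  child <- sample.int(2147483647L, n_trials)
  sds <- numeric(n_trials)
  nonfinite <- 0L
  redraws <- 0L
  for (i in seq_len(n_trials)) {
    set.seed(child[i])
    s <- run_mc_trial(variant, probe, env, noise, n_reps = n_reps)
    sds[i] <- as.numeric(s)
    nonfinite <- nonfinite + attr(s, "nonfinite")
    redraws <- redraws + attr(s, "redraws")
  }
  structure(list(mu_cbt = mean(sds), su_cbt = stats::sd(sds), trial_sds = sds,
                 n_reps = n_reps, n_trials = n_trials,
                 seed = if (is.null(seed)) NA_integer_ else seed,
                 nonfinite_count = nonfinite, redraws = redraws,
                 variant = variant),
            class = "dhf_mc")
}

#' @export
print.dhf_mc <- function(x, ...) {
  cat(sprintf("Monte Carlo CBT uncertainty (%s): mu_cbt = %.5g, su_cbt = %.3g deg C\n",
              x$variant, x$mu_cbt, x$su_cbt))
  cat(sprintf("  %d reps x %d trials; %d non-finite estimates\n",
              x$n_reps, x$n_trials, x$nonfinite_count))
  invisible(x)
}

#' Define a parameter sweep
#'
#' A sweep varies one setup parameter over a grid while everything else stays
#' at its default. Supported parameters and their linkage to the probe or
#' environment:
#' \describe{
#'   \item{tamb}{grid value is the ambient temperature, deg C.}
#'   \item{cbt}{grid value is the core temperature, deg C.}
#'   \item{hs_pair}{grid value is the common channel conductivity
#'     k_s1 = k_s2, W/(m K); thicknesses fixed, so the h_s1/h_s2 ratio stays
#'     at its default 2 while both coefficients scale.}
#'   \item{hs_ratio}{grid value is r = h_s1/h_s2; channel 1 is untouched and
#'     channel 2's thickness grows as d_s2 = r k_s2/h_s1.}
#'   \item{hsa}{grid value is the convection coefficient h_sa, W/(m^2 K).}
#' }
#'
#' @param parameter one of `"tamb"`, `"cbt"`, `"hs_pair"`, `"hs_ratio"`, `"hsa"`.
#' @param grid strictly monotone numeric grid of parameter values.
#' @return An object of class `dhf_sweep_spec`.
#' @export
sweep_spec <- function(parameter, grid) {
  parameter <- match.arg(parameter, c("tamb", "cbt", "hs_pair", "hs_ratio", "hsa"))
  grid <- as.numeric(grid)
  if (length(grid) < 2 || any(!is.finite(grid)) ||
      !(all(diff(grid) > 0) || all(diff(grid) < 0)))
    stop("grid must be a strictly monotone numeric sequence", call. = FALSE)
  structure(list(parameter = parameter, grid = grid), class = "dhf_sweep_spec")
}

#' Pre-defined sweep experiments
#'
#' The five standard design-space sweeps, plus the narrow ambient sweep used
#' to resolve the very thin unstable band of the paired temperature-only
#' variants:
#' \describe{
#'   \item{e1}{ambient temperature -15 to +45 deg C, step 0.5.}
#'   \item{e1_narrow}{ambient temperature 36.95 to 37.05, step 0.001.}
#'   \item{e2}{core temperature 35 to 45 deg C, step 0.25.}
#'   \item{e3}{channel conductivities 0.01 to 100 W/(m K), 60 log-spaced
#'     points (h_s1 roughly 0.7 to 6667 W/(m^2 K), ratio 2 preserved).}
#'   \item{e4}{coefficient ratio h_s1/h_s2 from 1.25 to 10000, 60 log-spaced
#'     points.}
#'   \item{e5}{convection h_sa 6 to 104 W/(m^2 K) (still air to roughly
#'     14 m/s airflow), step 2.}
#' }
#'
#' @param id experiment identifier.
#' @return A [sweep_spec()].
#' @export
dhf_experiment <- function(id = c("e1", "e1_narrow", "e2", "e3", "e4", "e5")) {
  switch(match.arg(id),
    e1 = sweep_spec("tamb", seq(-15, 45, by = 0.5)),
    e1_narrow = sweep_spec("tamb", seq(36.95, 37.05, by = 0.001)),
    e2 = sweep_spec("cbt", seq(35, 45, by = 0.25)),
    e3 = sweep_spec("hs_pair", exp(seq(log(0.01), log(100), length.out = 60))),
    e4 = sweep_spec("hs_ratio", exp(seq(log(1.25), log(10000), length.out = 60))),
    e5 = sweep_spec("hsa", seq(6, 104, by = 2)))
}

#' Materialise a sweep as probe/environment pairs
#'
#' @param spec a [sweep_spec()].
#' @param base_probe,base_env the configuration every grid point starts from.
#' @return A list with one element per grid point, each a list
#'   `(value, probe, env)`.
#' @export
build_sweep_grid <- function(spec, base_probe = dhf_probe(),
                             base_env = dhf_env()) {
  stopifnot(inherits(spec, "dhf_sweep_spec"))
  h_s1 <- base_probe$k_s1 / base_probe$d_s1
  lapply(spec$grid, function(v) {
    probe <- base_probe
    env <- base_env
    switch(spec$parameter,
      tamb = { env$t_amb <- v },
      cbt = { env$cbt <- v },
      hs_pair = { probe$k_s1 <- v; probe$k_s2 <- v },
      hs_ratio = { probe$d_s2 <- v * probe$k_s2 / h_s1 },
      hsa = { probe$h_sa <- v })
    list(value = v, probe = probe, env = env)
  })
}

#' Run a sweep experiment for a set of variants
#'
#' Evaluates [estimate_uncertainty()] for every variant at every grid point.
#' Each (variant, grid point) cell gets its own deterministic child seed
#' drawn from the master seed, so the full table is reproducible and cells
#' are mutually independent.
#'
#' @param spec a [sweep_spec()] or [dhf_experiment()] result.
#' @param variants character vector of variant ids (default all six).
#' @param probe,env base configuration.
#' @param noise a [dhf_noise()].
#' @param n_reps,n_trials Monte Carlo sizes per cell.
#' @param seed master seed.
#' @return A data.frame of class `dhf_sweep` with one row per (variant, grid
#'   point): columns `variant`, `parameter`, `value`, `mu_cbt`, `su_cbt`,
#'   `n_reps`, `n_trials`, `seed`, `nonfinite_count`.
#' @export
run_sweep <- function(spec, variants = dhf_variants(), probe = dhf_probe(),
                      env = dhf_env(), noise = dhf_noise(),
                      n_reps = 10000, n_trials = 100, seed = 1L) {
  stopifnot(inherits(spec, "dhf_sweep_spec"))
  variants <- match.arg(variants, dhf_variants(), several.ok = TRUE)
  pts <- build_sweep_grid(spec, probe, env)
  set.seed(seed)
  cells <- expand.grid(point = seq_along(pts), variant = variants,
                       stringsAsFactors = FALSE)
  cells$child <- sample.int(2147483647L, nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    p <- pts[[cells$point[i]]]
    mc <- estimate_uncertainty(cells$variant[i], p$probe, p$env, noise,
                               n_reps = n_reps, n_trials = n_trials,
                               seed = cells$child[i])
    data.frame(variant = cells$variant[i], parameter = spec$parameter,
               value = p$value, mu_cbt = mc$mu_cbt, su_cbt = mc$su_cbt,
               n_reps = n_reps, n_trials = n_trials, seed = seed,
               nonfinite_count = mc$nonfinite_count,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dhf_sweep", "data.frame")
  out
}
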