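# component lists for the sensitivity analysis: measured quantities plus,
# for TT-family variants, the channel coefficients entering k = h_s2/h_s1
budget_components <- function(variant) {
  comp <- variant_components(variant)
  if (is_tt_family(variant)) comp <- c(comp, "h_s1", "h_s2")
  comp
}

# evaluate a variant's estimator at explicit component values (scalar use)
eval_variant_at <- function(variant, x) {
  comp <- variant_components(variant)
  k <- if (is_tt_family(variant)) x[["h_s2"]] / x[["h_s1"]] else NULL
  estimate_cbt(variant, measured_set(variant, x[comp], k_meas = k))$value
}

# error-free component values as a named list
truth_components <- function(variant, truth, coeffs) {
  x <- unclass(truth)[variant_components(variant)]
  if (is_tt_family(variant)) {
    x$h_s1 <- coeffs$h_s1
    x$h_s2 <- coeffs$h_s2
  }
  x
}

#' Closed-form sensitivity coefficients of a CBT estimator
#'
#' Partial derivatives of the variant's estimate with respect to each of its
#' independent measured components, evaluated at the error-free operating
#' point. For TT-family variants the h_s1/h_s2 sensitivities are obtained by
#' the chain rule through k = h_s2/h_s1, which gives the exact ratio
#' d/dh_s2 : d/dh_s1 = -1/k.
#'
#' @param variant one of [dhf_variants()].
#' @param truth a `dhf_readings` object (the operating point).
#' @param coeffs the matching `dhf_coefficients` (carries k, h_s1, h_s2).
#' @return Named numeric vector of sensitivities, deg C per unit of each
#'   component.
#' @export
analytic_partials <- function(variant, truth, coeffs) {
  variant <- match.arg(variant, dhf_variants())
  stopifnot(inherits(truth, "dhf_readings"), inherits(coeffs, "dhf_coefficients"))
  t <- unclass(truth)
  k <- coeffs$k
  if (is_tt_family(variant)) {
    A <- t$dT_s1; B <- t$dT_s2; M <- k * B - A
    if (M == 0) stop("singular operating point: k*dT_s2 - dT_s1 is zero",
                     call. = FALSE)
  } else {
    D <- t$q_2 - t$q_1
    if (D == 0) stop("singular operating point: q_2 - q_1 is zero",
                     call. = FALSE)
  }
  g <- switch(variant,
    HT = {
      dT <- t$T_ss1 - t$T_ss2
      c(T_ss1 = 1 + t$q_1 / D, T_ss2 = -t$q_1 / D,
        q_1 = dT * t$q_2 / D^2, q_2 = -dT * t$q_1 / D^2)
    },
    HTp = c(T_ss1 = 1, dT_ss = t$q_1 / D,
            q_1 = t$dT_ss * t$q_2 / D^2, q_2 = -t$dT_ss * t$q_1 / D^2),
    HTpm = c(T_ss1 = 0.5, T_ss2 = 0.5,
             dT_ss = (t$q_1 + t$q_2) / (2 * D),
             q_1 = t$dT_ss * t$q_2 / D^2, q_2 = -t$dT_ss * t$q_1 / D^2),
    TT = {
      dT <- t$T_ss1 - t$T_ss2
      c(T_ss1 = 1 + ((dT + A) * M + A * dT) / M^2,
        T_ss2 = -A * (M + k * dT) / M^2,
        T_sa1 = -dT * k * B / M^2,
        T_sa2 = k * A * dT / M^2,
        k = -A * B * dT / M^2)
    },
    TTp = c(T_ss1 = 1, dT_ss = A / M,
            dT_s1 = t$dT_ss * k * B / M^2,
            dT_s2 = -k * A * t$dT_ss / M^2,
            k = -A * B * t$dT_ss / M^2),
    TTpm = c(T_ss1 = 0.25, T_ss2 = 0.25, T_sa1 = 0.25, T_sa2 = 0.25,
             dT_ss = 0.5 + A / M,
             dT_s1 = 0.25 + t$dT_ss * k * B / M^2,
             dT_s2 = 0.25 - k * A * t$dT_ss / M^2,
             k = -A * B * t$dT_ss / M^2))
  if (is_tt_family(variant)) {
    dk <- g[["k"]]
    g <- g[setdiff(names(g), "k")]
    g[["h_s1"]] <- dk * (-k / coeffs$h_s1)
    g[["h_s2"]] <- dk * (1 / coeffs$h_s1)
  }
  g[budget_components(variant)]
}

#' Finite-difference sensitivity coefficients (oracle)
#'
#' Central finite differences of the estimator with respect to each
#' independent component, at the error-free operating point. Serves as an
#' implementation-independent check on [analytic_partials()].
#'
#' @inheritParams analytic_partials
#' @param step relative perturbation; the absolute step for a component is
#'   `step * max(|value|, 1)`.
#' @return Named numeric vector of sensitivities.
#' @export
numeric_partials <- function(variant, truth, coeffs, step = 1e-6) {
  variant <- match.arg(variant, dhf_variants())
  x0 <- truth_components(variant, truth, coeffs)
  base <- eval_variant_at(variant, x0)
  if (!is.finite(base))
    stop("singular operating point: estimator denominator is zero",
         call. = FALSE)
  comp <- budget_components(variant)
  g <- vapply(comp, function(nm) {
    h <- step * max(abs(x0[[nm]]), 1)
    xp <- x0; xp[[nm]] <- x0[[nm]] + h
    xm <- x0; xm[[nm]] <- x0[[nm]] - h
    (eval_variant_at(variant, xp) - eval_variant_at(variant, xm)) / (2 * h)
  }, numeric(1))
  names(g) <- comp
  g
}

#' First-order Taylor uncertainty budget of a CBT estimator
#'
#' Combines the sensitivity coefficients c_x with the per-component standard
#' uncertainties u_x into the combined standard uncertainty
#' u = sqrt(sum (c_x u_x)^2), and decomposes it into relative shares
#' ru(x) = (c_x u_x)^2 / u^2. Component uncertainties follow the noise spec:
#' `u_t` for absolute temperatures, `u_dt` for paired differentials, `u_q`
#' for fluxes and `u_h` for h_s1/h_s2 (the latter only when the spec's
#' `h_noise` is on).
#'
#' @param variant one of [dhf_variants()].
#' @param probe a [dhf_probe()].
#' @param env a [dhf_env()].
#' @param noise a [dhf_noise()].
#' @return An object of class `dhf_budget`: `u_combined` (deg C), `ru`
#'   (named shares summing to 1, or all `NA` when `u_combined` is 0),
#'   `sensitivity` and `u_x` (named vectors), `variant`.
#' @export
combined_uncertainty <- function(variant, probe = dhf_probe(), env = dhf_env(),
                                 noise = dhf_noise()) {
  variant <- match.arg(variant, dhf_variants())
  co <- derive_channel_coefficients(probe)
  truth <- simulate_true_readings(co, env)
  g <- analytic_partials(variant, truth, co)
  sds <- effective_sds(noise)
  u_x <- sds[component_sd_kind[names(g)]]
  names(u_x) <- names(g)
  if (is_tt_family(variant) && !noise$h_noise)
    u_x[c("h_s1", "h_s2")] <- 0
  contrib <- (g * u_x)^2
  u <- sqrt(sum(contrib))
  ru <- if (u > 0) contrib / u^2 else rep(NA_real_, length(contrib))
  names(ru) <- names(g)
  structure(list(u_combined = u, ru = ru, sensitivity = g, u_x = u_x,
                 variant = variant),
            class = "dhf_budget")
}

#' @export
print.dhf_budget <- function(x, digits = 4, ...) {
  cat(sprintf("Taylor uncertainty budget (%s): u_combined = %.4g deg C\n",
              x$variant, x$u_combined))
  df <- data.frame(component = names(x$sensitivity),
                   sensitivity = signif(x$sensitivity, digits),
                   u_x = x$u_x,
                   share = if (all(is.na(x$ru))) NA else signif(x$ru, digits))
  print(df, row.names = FALSE)
  if (all(is.na(x$ru)))
    cat("  (all component uncertainties are zero; shares undefined)\n")
  invisible(x)
}
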