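#' The six dual-heat-flux estimator variants
#'
#' `HT`-family variants read the two heat fluxes directly; `TT`-family
#' variants use only the four surface temperatures plus the characteristic
#' probe parameter k = h_s2/h_s1. A trailing `p` marks paired (bias-calibrated)
#' temperature sensors, whose differential readings carry a much smaller
#' uncertainty than absolute readings; a trailing `m` marks multi-equation
#' averaging of the algebraically equivalent re-expressions of the same
#' measurement.
#'
#' @return Character vector of the variant identifiers.
#' @export
dhf_variants <- function() c("HT", "HTp", "HTpm", "TT", "TTp", "TTpm")

# measured components (excluding k, held separately) required by each variant
variant_components <- function(variant) {
  switch(match.arg(variant, dhf_variants()),
    HT   = c("T_ss1", "T_ss2", "q_1", "q_2"),
    HTp  = c("T_ss1", "dT_ss", "q_1", "q_2"),
    HTpm = c("T_ss1", "T_ss2", "dT_ss", "q_1", "q_2"),
    TT   = c("T_ss1", "T_ss2", "T_sa1", "T_sa2"),
    TTp  = c("T_ss1", "dT_ss", "dT_s1", "dT_s2"),
    TTpm = c("T_ss1", "T_ss2", "T_sa1", "T_sa2", "dT_ss", "dT_s1", "dT_s2"))
}

is_tt_family <- function(variant) substr(variant, 1, 2) == "TT"

#' Assemble a measured-quantity set for one estimator variant
#'
#' @param variant one of [dhf_variants()].
#' @param values named list or vector of the measured quantities the variant
#'   requires (see Details); all numeric, equal lengths.
#' @param k_meas measured characteristic parameter k = h_s2/h_s1
#'   (TT-family only; must be positive).
#' @details Required components: `HT` needs `T_ss1, T_ss2, q_1, q_2`; `HTp`
#'   needs `T_ss1, dT_ss, q_1, q_2`; `HTpm` additionally `T_ss2`; `TT` needs
#'   the four surface temperatures; `TTp` needs `T_ss1, dT_ss, dT_s1, dT_s2`;
#'   `TTpm` additionally `T_ss2, T_sa1, T_sa2`. TT-family sets carry `k_meas`.
#' @return An object of class `dhf_measured`.
#' @export
measured_set <- function(variant, values, k_meas = NULL) {
  variant <- match.arg(variant, dhf_variants())
  need <- variant_components(variant)
  values <- as.list(values)
  if (anyDuplicated(names(values)))
    stop("duplicated measured quantity: ",
         paste(unique(names(values)[duplicated(names(values))]), collapse = ", "),
         call. = FALSE)
  missing_q <- setdiff(need, names(values))
  extra_q <- setdiff(names(values), need)
  if (length(missing_q) || length(extra_q))
    stop("variant ", variant, " requires exactly {",
         paste(need, collapse = ", "), "}",
         if (length(missing_q)) paste0("; missing: ", paste(missing_q, collapse = ", ")),
         if (length(extra_q)) paste0("; unexpected: ", paste(extra_q, collapse = ", ")),
         call. = FALSE)
  if (is_tt_family(variant)) {
    if (is.null(k_meas) || !all(k_meas > 0))
      stop("TT-family variants require k_meas > 0", call. = FALSE)
  } else if (!is.null(k_meas)) {
    stop("k_meas is only meaningful for TT-family variants", call. = FALSE)
  }
  structure(list(variant = variant, values = values[need], k_meas = k_meas),
            class = "dhf_measured")
}

#' Error-free measured set for a variant
#'
#' Maps the forward model's readings onto the quantities a given variant
#' measures, with no noise added (k taken exactly as h_s2/h_s1).
#'
#' @param variant one of [dhf_variants()].
#' @param truth a `dhf_readings` object.
#' @param coeffs the matching `dhf_coefficients`.
#' @return A `dhf_measured` set equal to the truth.
#' @export
true_measured_set <- function(variant, truth, coeffs) {
  variant <- match.arg(variant, dhf_variants())
  vals <- unclass(truth)[variant_components(variant)]
  measured_set(variant, vals,
               k_meas = if (is_tt_family(variant)) coeffs$k else NULL)
}

#' Skin heat-transfer coefficient from the two channels
#'
#' Eliminating the core temperature between the two single-flux equations
#' gives h_t = (q_1 - q_2)/(T_ss2 - T_ss1): the flux contrast divided by the
#' skin-side temperature contrast.
#'
#' @param q_1,q_2 channel heat fluxes, W/m^2.
#' @param T_ss1,T_ss2 skin-side surface temperatures, deg C.
#' @return Estimated h_t, W/(m^2 K).
#' @export
skin_coefficient_estimate <- function(q_1, q_2, T_ss1, T_ss2) {
  if (any(T_ss2 - T_ss1 == 0))
    stop("skin coefficient is undefined when T_ss1 equals T_ss2", call. = FALSE)
  (q_1 - q_2) / (T_ss2 - T_ss1)
}

#' Estimate core body temperature from a measured set
#'
#' Applies the variant's estimator. With D = q_2 - q_1 and
#' M = k dT_s2 - dT_s1:
#' \describe{
#'   \item{HT}{T_ss1 + q_1 (T_ss1 - T_ss2)/D}
#'   \item{HTp}{T_ss1 + q_1 dT_ss/D (paired differential)}
#'   \item{HTpm}{mean of the channel-1 and channel-2 based forms, sharing the
#'     measured fluxes and dT_ss}
#'   \item{TT}{T_ss1 + (T_ss1 - T_sa1)(T_ss1 - T_ss2)/(k (T_ss2 - T_sa2) - (T_ss1 - T_sa1))}
#'   \item{TTp}{T_ss1 + dT_s1 dT_ss/M}
#'   \item{TTpm}{mean of the four re-expressions based at T_ss1, T_ss2, T_sa1
#'     and T_sa2, sharing the differentials and k}
#' }
#' A denominator that is exactly zero yields a non-finite estimate (flagged,
#' not an error); no epsilon clipping is applied, so the amplification near
#' singular operating points is preserved.
#'
#' @param variant one of [dhf_variants()]; must match `m`.
#' @param m a [measured_set()] (vectorised: components may be vectors).
#' @return An object of class `dhf_estimate`: list with `value` (deg C),
#'   `variant` and logical `finite`.
#' @export
estimate_cbt <- function(variant, m) {
  variant <- match.arg(variant, dhf_variants())
  if (!inherits(m, "dhf_measured"))
    stop("m must be a dhf_measured set", call. = FALSE)
  if (!identical(m$variant, variant))
    stop("measured set was built for variant ", m$variant,
         ", not ", variant, call. = FALSE)
  v <- m$values
  value <- switch(variant,
    HT = v$T_ss1 + v$q_1 * (v$T_ss1 - v$T_ss2) / (v$q_2 - v$q_1),
    HTp = v$T_ss1 + v$q_1 * v$dT_ss / (v$q_2 - v$q_1),
    HTpm = {
      D <- v$q_2 - v$q_1
      (v$T_ss1 + v$q_1 * v$dT_ss / D + v$T_ss2 + v$q_2 * v$dT_ss / D) / 2
    },
    TT = {
      A <- v$T_ss1 - v$T_sa1
      v$T_ss1 + A * (v$T_ss1 - v$T_ss2) /
        (m$k_meas * (v$T_ss2 - v$T_sa2) - A)
    },
    TTp = v$T_ss1 + v$dT_s1 * v$dT_ss / (m$k_meas * v$dT_s2 - v$dT_s1),
    TTpm = {
      f <- v$dT_s1 * v$dT_ss / (m$k_meas * v$dT_s2 - v$dT_s1)
      ((v$T_ss1 + f) + (v$T_ss2 + v$dT_ss + f) +
         (v$T_sa1 + v$dT_s1 + f) + (v$T_sa2 + v$dT_ss + v$dT_s2 + f)) / 4
    })
  structure(list(value = value, variant = variant, finite = is.finite(value)),
            class = "dhf_estimate")
}

#' @export
print.dhf_estimate <- function(x, ...) {
  n <- length(x$value)
  if (n == 1L) {
    cat(sprintf("CBT estimate (%s): %s deg C\n", x$variant,
                if (x$finite) format(x$value) else "undefined (zero denominator)"))
  } else {
    cat(sprintf("CBT estimates (%s): n = %d, %d non-finite\n",
                x$variant, n, sum(!x$finite)))
    print(summary(x$value))
  }
  invisible(x)
}
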