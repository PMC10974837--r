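#' Describe a dual-heat-flux probe and the skin layer beneath it
#'
#' A dual-heat-flux (DHF) probe has two adjacent channels of thermally
#' resistive material with different overall resistances; comparing the two
#' channels' readings eliminates the unknown skin heat-transfer coefficient
#' from the core-temperature estimate. The probe is described by the thermal
#' conductivity and thickness of each channel, the conductivity and thickness
#' of the skin layer, and a single sensor-to-air convection coefficient
#' applied to both channels.
#'
#' Defaults correspond to a PDMS probe (15 mm and 30 mm channels) over 2.5 mm
#' of skin under natural convection, i.e. channel coefficients
#' h_s1 = 10 and h_s2 = 5 W/(m^2 K).
#'
#' @param k_s1,k_s2 thermal conductivity of the channel-1 and channel-2
#'   material, W/(m K).
#' @param d_s1_mm,d_s2_mm channel thicknesses, mm (converted to m internally).
#' @param k_t skin thermal conductivity, W/(m K).
#' @param d_t_mm skin thickness, mm.
#' @param h_sa sensor-air convection coefficient, W/(m^2 K), applied
#'   identically to both channels.
#' @return An object of class `dhf_probe`: a list with the conductivities and
#'   the thicknesses in metres (`d_s1`, `d_s2`, `d_t`).
#' @examples
#' p <- dhf_probe()
#' derive_channel_coefficients(p)
#' @export
dhf_probe <- function(k_s1 = 0.15, k_s2 = 0.15, d_s1_mm = 15, d_s2_mm = 30,
                      k_t = 0.37, d_t_mm = 2.5, h_sa = 6.1) {
  p <- list(k_s1 = k_s1, k_s2 = k_s2,
            d_s1 = d_s1_mm / 1000, d_s2 = d_s2_mm / 1000,
            k_t = k_t, d_t = d_t_mm / 1000, h_sa = h_sa)
  for (f in names(p)) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      # report the user-facing (mm) name for thicknesses
      shown <- switch(f, d_s1 = "d_s1_mm", d_s2 = "d_s2_mm", d_t = "d_t_mm", f)
      stop("probe parameter '", shown, "' must be a single positive number",
           call. = FALSE)
    }
  }
  structure(p, class = "dhf_probe")
}

#' Derive the layer and overall heat-transfer coefficients of a probe
#'
#' Each layer's coefficient is conductivity over thickness, h = k/d; the
#' overall coefficient of channel i is the series combination
#' 1/h_i = 1/h_t + 1/h_si + 1/h_sa. The characteristic probe parameter
#' k = h_s2/h_s1 is the only probe property entering the temperature-only
#' estimators.
#'
#' @param probe a [dhf_probe()].
#' @return An object of class `dhf_coefficients` with fields `h_t`, `h_s1`,
#'   `h_s2`, `h_sa`, `h_1`, `h_2` (all W/(m^2 K)) and the dimensionless `k`.
#' @export
derive_channel_coefficients <- function(probe) {
  stopifnot(inherits(probe, "dhf_probe"))
  h_t <- probe$k_t / probe$d_t
  h_s1 <- probe$k_s1 / probe$d_s1
  h_s2 <- probe$k_s2 / probe$d_s2
  h_1 <- 1 / (1 / h_t + 1 / h_s1 + 1 / probe$h_sa)
  h_2 <- 1 / (1 / h_t + 1 / h_s2 + 1 / probe$h_sa)
  structure(list(h_t = h_t, h_s1 = h_s1, h_s2 = h_s2, h_sa = probe$h_sa,
                 h_1 = h_1, h_2 = h_2, k = h_s2 / h_s1),
            class = "dhf_coefficients")
}

#' Environment state seen by the probe
#'
#' @param cbt core body temperature (blood temperature under the skin), deg C.
#' @param t_amb ambient air temperature, deg C. May exceed `cbt`.
#' @return An object of class `dhf_env`.
#' @export
dhf_env <- function(cbt = 37, t_amb = 25) {
  stopifnot(is.numeric(cbt), length(cbt) == 1L, is.finite(cbt),
            is.numeric(t_amb), length(t_amb) == 1L, is.finite(t_amb))
  structure(list(cbt = cbt, t_amb = t_amb), class = "dhf_env")
}

#' @export
print.dhf_probe <- function(x, ...) {
  cat("Dual-heat-flux probe\n")
  cat(sprintf("  channel 1: k = %g W/(m K), d = %g mm\n", x$k_s1, 1000 * x$d_s1))
  cat(sprintf("  channel 2: k = %g W/(m K), d = %g mm\n", x$k_s2, 1000 * x$d_s2))
  cat(sprintf("  skin:      k = %g W/(m K), d = %g mm\n", x$k_t, 1000 * x$d_t))
  cat(sprintf("  convection h_sa = %g W/(m^2 K)\n", x$h_sa))
  invisible(x)
}

#' @export
print.dhf_coefficients <- function(x, ...) {
  cat("Derived heat-transfer coefficients [W/(m^2 K)]\n")
  cat(sprintf("  h_t = %g  h_s1 = %g  h_s2 = %g  h_sa = %g\n",
              x$h_t, x$h_s1, x$h_s2, x$h_sa))
  cat(sprintf("  overall h_1 = %.4f  h_2 = %.4f   k = h_s2/h_s1 = %g\n",
              x$h_1, x$h_2, x$k))
  invisible(x)
}
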