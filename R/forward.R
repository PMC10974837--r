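#' Error-free steady-state readings of a dual-heat-flux probe
#'
#' Evaluates the lumped thermal model of the blood-skin-sensor-air stack.
#' With overall channel coefficient h_i, the flux through channel i is
#' q_i = h_i (CBT - T_amb); the skin-side surface temperature is
#' T_ssi = CBT - q_i/h_t and the air-side surface temperature
#' T_sai = T_ssi - q_i/h_si. The three differentials used by the
#' paired-sensor estimators are dT_ss = T_ss1 - T_ss2, dT_s1 = T_ss1 - T_sa1,
#' dT_s2 = T_ss2 - T_sa2.
#'
#' The model is algebraic (steady state, no thermal capacitance) and affine
#' in the driving gradient CBT - T_amb, so all fluxes and temperature
#' differences scale linearly with it and vanish when T_amb = CBT.
#'
#' @param coeffs a [derive_channel_coefficients()] result.
#' @param env a [dhf_env()].
#' @return An object of class `dhf_readings`: fluxes `q_1`, `q_2` (W/m^2),
#'   temperatures `T_ss1`, `T_ss2`, `T_sa1`, `T_sa2` (deg C), differentials
#'   `dT_ss`, `dT_s1`, `dT_s2` (deg C), plus the `cbt`/`t_amb` used.
#' @export
simulate_true_readings <- function(coeffs, env) {
  stopifnot(inherits(coeffs, "dhf_coefficients"), inherits(env, "dhf_env"))
  grad <- env$cbt - env$t_amb
  q_1 <- coeffs$h_1 * grad
  q_2 <- coeffs$h_2 * grad
  T_ss1 <- env$cbt - q_1 / coeffs$h_t
  T_ss2 <- env$cbt - q_2 / coeffs$h_t
  T_sa1 <- T_ss1 - q_1 / coeffs$h_s1
  T_sa2 <- T_ss2 - q_2 / coeffs$h_s2
  structure(list(q_1 = q_1, q_2 = q_2,
                 T_ss1 = T_ss1, T_ss2 = T_ss2, T_sa1 = T_sa1, T_sa2 = T_sa2,
                 dT_ss = T_ss1 - T_ss2, dT_s1 = T_ss1 - T_sa1,
                 dT_s2 = T_ss2 - T_sa2,
                 cbt = env$cbt, t_amb = env$t_amb),
            class = "dhf_readings")
}

#' One-call forward model from a probe description
#'
#' Convenience wrapper: derives the coefficients and simulates the error-free
#' readings in one step.
#'
#' @param probe a [dhf_probe()].
#' @param cbt,t_amb core body and ambient temperature, deg C.
#' @return A `dhf_readings` object (see [simulate_true_readings()]); the
#'   derived coefficients are attached as attribute `"coefficients"`.
#' @examples
#' dhf_forward(dhf_probe(), cbt = 37, t_amb = 25)
#' @export
dhf_forward <- function(probe = dhf_probe(), cbt = 37, t_amb = 25) {
  co <- derive_channel_coefficients(probe)
  r <- simulate_true_readings(co, dhf_env(cbt, t_amb))
  attr(r, "coefficients") <- co
  r
}

#' Single-flux core temperature estimate
#'
#' The classic single-channel reconstruction CBT_e = T_ss + q/h_t. It needs
#' the skin coefficient h_t, which is what the dual-flux estimators avoid.
#'
#' @param T_ss skin-side surface temperature, deg C.
#' @param q heat flux through the channel, W/m^2.
#' @param h_t skin heat-transfer coefficient, W/(m^2 K); must be positive.
#' @return Core temperature estimate, deg C.
#' @export
single_flux_estimate <- function(T_ss, q, h_t) {
  if (!is.numeric(h_t) || any(h_t <= 0))
    stop("h_t must be positive", call. = FALSE)
  T_ss + q / h_t
}

#' @export
print.dhf_readings <- function(x, digits = 4, ...) {
  cat(sprintf("Error-free DHF readings (CBT = %g, T_amb = %g deg C)\n",
              x$cbt, x$t_amb))
  df <- as.data.frame(x)
  df$value <- signif(df$value, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.dhf_readings <- function(x, ...) {
  data.frame(
    quantity = c("q", "q", "T_ss", "T_ss", "T_sa", "T_sa",
                 "dT_ss", "dT_s1", "dT_s2"),
    channel = c(1, 2, 1, 2, 1, 2, NA, 1, 2),
    value = c(x$q_1, x$q_2, x$T_ss1, x$T_ss2, x$T_sa1, x$T_sa2,
              x$dT_ss, x$dT_s1, x$dT_s2),
    unit = c("W/m^2", "W/m^2", rep("degC", 7)),
    stringsAsFactors = FALSE
  )
}
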