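# Frozen reference values for the default probe (PDMS 15/30 mm, skin 2.5 mm,
# h_sa 6.1), computed by hand through the series-resistance chain:
#   h_t = 0.37/0.0025, h_s1 = 0.15/0.015, h_s2 = 0.15/0.030,
#   1/h_i = 1/h_t + 1/h_si + 1/h_sa, q_i = h_i (CBT - T_amb),
#   T_ssi = CBT - q_i/h_t, T_sai = T_ssi - q_i/h_si.
ref_default <- list(
  h_t = 148, h_s1 = 10, h_s2 = 5, k = 0.5,
  h_1 = 3.694246665, h_2 = 2.6976633,
  # CBT = 37, T_amb = 25
  q_1 = 44.33095998, q_2 = 32.37195960,
  T_ss1 = 36.70046649, T_ss2 = 36.78127054,
  T_sa1 = 32.26737049, T_sa2 = 30.30687862
)

# a pool of valid non-degenerate probe configurations for property tests
random_probe <- function() {
  dhf_probe(k_s1 = runif(1, 0.05, 2), k_s2 = runif(1, 0.05, 2),
            d_s1_mm = runif(1, 2, 40), d_s2_mm = runif(1, 45, 120),
            k_t = runif(1, 0.2, 0.6), d_t_mm = runif(1, 1, 5),
            h_sa = runif(1, 4, 100))
}

zero_noise <- function() dhf_noise(u_t = 0, u_dt = 0, u_q = 0, u_h = 0)
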