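# Independent, literal transcription of the hydraulic-property regressions.
# Deliberately written as bare formulas with no shared code with R/ptf.R, so
# it can serve as the oracle the implementation is checked against. S and C
# are decimal fractions, OM is mass %.

oracle_theta1500 <- function(S, C, OM) {
  t <- -0.024 * S + 0.487 * C + 0.006 * OM +
    0.005 * (S * OM) - 0.013 * (C * OM) + 0.068 * (S * C) + 0.031
  t + (0.14 * t - 0.02)
}

oracle_theta33 <- function(S, C, OM) {
  t <- -0.251 * S + 0.195 * C + 0.011 * OM +
    0.006 * (S * OM) - 0.027 * (C * OM) + 0.452 * (S * C) + 0.299
  t + (1.283 * t^2 - 0.374 * t - 0.015)
}

oracle_thetaS <- function(S, C, OM) {
  t <- 0.278 * S + 0.034 * C + 0.022 * OM -
    0.018 * (S * OM) - 0.027 * (C * OM) - 0.584 * (S * C) + 0.078
  ts33 <- t + (0.636 * t - 0.107)
  oracle_theta33(S, C, OM) + ts33 - 0.097 * S + 0.043
}

oracle_ks <- function(t1500, t33, tS) {
  B <- (log(1500) - log(33)) / (log(t33) - log(t1500))
  1930 * (tS - t33)^(3 - 1 / B)
}

# Full sweep of the texture simplex (1 % steps) crossed with OM 0..8 %.
oracle_sweep_grid <- function(step = 0.01, om = 0:8) {
  g <- expand.grid(S = seq(0, 1, by = step), C = seq(0, 1, by = step),
    OM = om)
  g[g$S + g$C <= 1, ]
}
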