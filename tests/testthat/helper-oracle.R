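# Continuous-time closed-form oracle for the decay model, kept independent of
# the package's discrete sampling path.

oracle_period_mean <- function(v0 = 100) v0 * (1 - exp(-2 * pi)) / (2 * pi)

oracle_k <- function(rr_ms, species = "mouse", v0 = 100) {
  x <- 1000 / rr_ms
  term <- if (species == "mouse") 2 * pi / x^2 else -6 * pi / x^2
  abs(oracle_period_mean(v0) / x + term)
}

# midpoint of the band-crossing times: the curve enters the band where
# R(t) = k + 1 and leaves where R(t) = k - 0.5
oracle_t_end <- function(rr_ms, species = "mouse", v0 = 100) {
  k <- oracle_k(rr_ms, species, v0)
  t1 <- (rr_ms / (2 * pi)) * log(v0 / (k + 1))
  t2 <- (rr_ms / (2 * pi)) * log(v0 / (k - 0.5))
  (t1 + t2) / 2
}
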