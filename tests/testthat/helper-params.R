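# Shared fixtures built in code.

ref_params <- function() interval_params(p = 0.5, a = 1, b = 0.1)

# printed steady-state gating midpoints (mV) for the two genotypes
WT_ACT_V50 <- -37.14
MUT_ACT_V50 <- -44.69
WT_INACT_V50 <- -58.18
MUT_INACT_V50 <- -63.11

act_grid <- seq(-80, 10, by = 10)
inact_grid <- seq(-100, -30, by = 5)

# draw random valid interval parameters with a sampleable mixture (a >= b)
random_valid_params <- function() {
  p <- runif(1, 0.1, 0.9)
  b <- runif(1, 0.02, 0.5)
  a <- b * runif(1, 2, 30)
  interval_params(p, a, b)
}
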