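# Independent enumeration oracle for the exact two-sided rank-sum p-value:
# walks all labelings via the sum of ranks rather than the U-statistic path
# used inside the package.
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  labelings <- combn(length(pooled), n1)
  w_obs <- sum(r[seq_len(n1)])
  w_all <- apply(labelings, 2, function(i) sum(r[i]))
  mu <- n1 * mean(r)  # n1 (N+1)/2 with midranks
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
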