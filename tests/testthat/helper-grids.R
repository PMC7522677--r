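# Shared fixtures: integer ratio grids and a brute-force chi-square oracle.

# all ordered integer triples a >= b >= c >= 1 with a <= amax
ordered_triples <- function(amax) {
  g <- expand.grid(c = seq_len(amax), b = seq_len(amax), a = seq_len(amax))
  g[g$a >= g$b & g$b >= g$c, c("a", "b", "c")]
}

# strictly ordered triples a > b > c >= 1
strict_triples <- function(amax) {
  g <- ordered_triples(amax)
  g[g$a > g$b & g$b > g$c, ]
}

# Independent chi-square oracle: expected counts from margins, then
# sum (O - E)^2 / E over the four cells. No stats::chisq.test involved.
chi2_oracle <- function(s1, f1, s2, f2) {
  obs <- matrix(c(s1, f1, s2, f2), nrow = 2, byrow = TRUE)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  stat <- sum((obs - expd)^2 / expd)
  list(statistic = stat, p.value = pchisq(stat, df = 1, lower.tail = FALSE))
}
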