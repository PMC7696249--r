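## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths for the quantities they check.

## ANOM decisions via per-group p-values against a Bonferroni-corrected
## level (same math as decision limits, different computational route).
anom_oracle_decisions <- function(df, alpha = 0.05) {
  grp <- factor(df$group, levels = unique(df$group))
  k <- nlevels(grp)
  n_i <- as.integer(table(grp))
  N <- sum(n_i)
  gm <- mean(df$value)
  sp2 <- sum(unlist(tapply(df$value, grp, function(v) (v - mean(v))^2))) /
    (N - k)
  means <- tapply(df$value, grp, mean)
  se <- sqrt(sp2 * (N - n_i) / (N * n_i))
  tstat <- (means - gm) / se
  pval <- 2 * pt(-abs(tstat), df = N - k)
  as.vector(ifelse(pval < alpha / k & tstat > 0, "above",
                   ifelse(pval < alpha / k & tstat < 0, "below", "within")))
}

## Permutation p-value for the two-group log-rank statistic, fully
## vectorized over permutations.
perm_logrank_p <- function(time, event, z, B = 10000, seed = 1) {
  set.seed(seed)
  n <- length(time)
  et <- sort(unique(time[event == 1]))
  R <- outer(time, et, ">=") * 1
  E <- outer(time, et, "==") * event
  n_j <- colSums(R)
  d_j <- colSums(E)
  stat_of <- function(Z) {
    N1 <- Z %*% R               # B x d, at risk in group 2
    O1 <- Z %*% E
    E1 <- sweep(N1, 2, d_j / n_j, "*")
    frac <- sweep(N1, 2, n_j, "/")
    V <- sweep(frac * (1 - frac), 2,
               d_j * (n_j - d_j) / pmax(n_j - 1, 1), "*")
    V[, n_j <= 1] <- 0
    num <- rowSums(O1 - E1)^2
    den <- rowSums(V)
    ifelse(den > 0, num / den, 0)
  }
  obs <- stat_of(matrix(as.numeric(z), 1))[1]
  Z <- t(vapply(seq_len(B), function(i) as.numeric(sample(z)), numeric(n)))
  mean(stat_of(Z) >= obs - 1e-12)
}

## Small helper: a hand-built killing matrix.
toy_killing_matrix <- function(values, species) {
  killing_matrix(values, species)
}
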