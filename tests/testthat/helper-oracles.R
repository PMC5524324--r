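# Independent oracles, deliberately written with none of the package's
# vectorised machinery: plain loops and base R only.

# Benjamini-Hochberg step-up by direct definition
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[o[i]] <= i * q / m) k <- i
  rej <- rep(FALSE, m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

# pooled-variance two-sample t, scalar
oracle_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# exhaustive two-sided permutation p for one vector by full enumeration
oracle_perm_p <- function(x, n_a) {
  n <- length(x)
  combs <- combn(n, n_a)
  t_obs <- abs(oracle_t(x[seq_len(n_a)], x[-seq_len(n_a)]))
  hits <- 0
  for (j in seq_len(ncol(combs))) {
    sel <- combs[, j]
    tj <- abs(oracle_t(x[sel], x[-sel]))
    if (tj >= t_obs - 1e-10) hits <- hits + 1
  }
  hits / ncol(combs)
}

# balanced two-way ANOVA by explicit sums of squares
oracle_anova2 <- function(y, f1, f2) {
  f1 <- factor(f1); f2 <- factor(f2)
  gm <- mean(y)
  n <- length(y)
  a <- nlevels(f1); b <- nlevels(f2)
  m1 <- tapply(y, f1, mean); m2 <- tapply(y, f2, mean)
  m12 <- tapply(y, interaction(f1, f2), mean)
  nrep <- n / (a * b)
  ss1 <- nrep * b * sum((m1 - gm)^2)
  ss2 <- nrep * a * sum((m2 - gm)^2)
  cellm <- m12[interaction(f1, f2)]
  sse <- sum((y - cellm)^2)
  ss12 <- sum((y - gm)^2) - ss1 - ss2 - sse
  dfe <- n - a * b
  list(F1 = (ss1 / (a - 1)) / (sse / dfe),
       F2 = (ss2 / (b - 1)) / (sse / dfe),
       F12 = (ss12 / ((a - 1) * (b - 1))) / (sse / dfe))
}
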