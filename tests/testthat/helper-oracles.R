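# Independent brute-force oracles; deliberately naive code paths that share
# nothing with the package implementations they check.

# freezing labels by scanning every length-min_run window
oracle_freezing_labels <- function(values, threshold, min_run) {
  n <- length(values)
  sub <- values < threshold
  labels <- rep(FALSE, n)
  if (n < min_run) return(labels)
  for (start in 1:(n - min_run + 1)) {
    if (all(sub[start:(start + min_run - 1)])) {
      labels[start:(start + min_run - 1)] <- TRUE
    }
  }
  labels
}

# dense-matrix Gaussian convolution with edge replication
oracle_gaussian_smooth <- function(x, sigma) {
  half <- ceiling(4 * sigma)
  kern <- dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  n <- length(x)
  M <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in seq_along(kern)) {
      src <- min(n, max(1, i + j - half - 1))
      M[i, src] <- M[i, src] + kern[j]
    }
  }
  as.vector(M %*% x)
}

# exact Mann-Whitney p by enumerating every assignment of the pooled values
oracle_mwu_enum <- function(x, y, alternative = "two.sided") {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, u_of)
  p_less <- mean(us <= u_obs)
  p_greater <- mean(us >= u_obs)
  switch(alternative,
         two.sided = min(1, 2 * min(p_less, p_greater)),
         less = p_less,
         greater = p_greater)
}

# Fisher two-sided p by explicit factorial enumeration over fixed margins
oracle_fisher_enum <- function(a, b, c, d) {
  logfac <- function(k) lgamma(k + 1)
  tab_p <- function(a2) {
    b2 <- a + b - a2; c2 <- a + c - a2; d2 <- d - a + a2
    if (min(b2, c2, d2) < 0) return(0)
    n <- a + b + c + d
    exp(logfac(a + b) + logfac(c + d) + logfac(a + c) + logfac(b + d) -
          logfac(n) - logfac(a2) - logfac(b2) - logfac(c2) - logfac(d2))
  }
  all_a <- 0:(a + b + c + d)
  probs <- vapply(all_a, tab_p, numeric(1))
  probs <- probs[probs > 0]
  sum(probs[probs <= tab_p(a) * (1 + 1e-7)])
}

# Scheirer-Ray-Hare H values through aov() sums of squares on ranks
oracle_srh <- function(values, a, b) {
  r <- rank(values)
  a <- as.factor(a); b <- as.factor(b)
  tab <- anova(aov(r ~ a * b))
  ms_tot <- sum((r - mean(r))^2) / (length(r) - 1)
  list(A = tab["a", "Sum Sq"] / ms_tot,
       B = tab["b", "Sum Sq"] / ms_tot,
       AB = tab["a:b", "Sum Sq"] / ms_tot)
}

# literal sequential Holm step-down
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# per-point Welch-weighted quadratic regression via lm()
oracle_sg_welch <- function(x, width = 11, order = 2) {
  half <- (width - 1) / 2
  n <- length(x)
  out <- numeric(n)
  for (i in 1:n) {
    k <- (-half):half
    k <- k[i + k >= 1 & i + k <= n]
    w <- 1 - (k / ((width + 1) / 2))^2
    fit <- lm(x[i + k] ~ poly(k, order, raw = TRUE), weights = w)
    out[i] <- unname(predict(fit, newdata = data.frame(k = 0)))
  }
  out
}

# expected relative rate profile of the thinned-process generator
oracle_rate_ratio <- function(s) 1 - s
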