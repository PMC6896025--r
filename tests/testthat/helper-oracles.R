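# Independent oracles used to check the package's statistical primitives.
# Each is a deliberately naive, brute-force implementation that shares no
# code path with the package.

# Benjamini-Hochberg by explicit step-down enumeration on the sorted scale:
# q_(i) = min over j >= i of m * p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * ps[j] / j, numeric(1))
    q[i] <- min(1, min(cand))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Two-sided Fisher exact p by brute-force enumeration of all tables with
# the observed margins, with probabilities from the multinomial formula
# computed via lgamma (no dhyper).
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; N <- r1 + r2
  lp <- function(x) {
    bb <- r1 - x; cc <- c1 - x; dd <- r2 - cc
    if (bb < 0 || cc < 0 || dd < 0) return(-Inf)
    (lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) + lgamma(c2 + 1)) -
      (lgamma(N + 1) + lgamma(x + 1) + lgamma(bb + 1) + lgamma(cc + 1) +
       lgamma(dd + 1))
  }
  probs <- vapply(0:min(r1, c1), lp, numeric(1))
  probs <- exp(probs[is.finite(probs)])
  p_obs <- exp(lp(a))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Two-sample KS statistic as the supremum of |ECDF1 - ECDF2| evaluated at
# every pooled data point.
ks_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  e1 <- vapply(pts, function(t) mean(x <= t), numeric(1))
  e2 <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(e1 - e2))
}

# Single-probe OLS slope and its standard error, closed form.
ols_oracle <- function(y, x) {
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc^2)
  resid <- y - mean(y) - slope * xc
  se <- sqrt(sum(resid^2) / (length(y) - 2) / sum(xc^2))
  list(slope = slope, se = se)
}
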