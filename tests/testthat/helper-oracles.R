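# Independent brute-force oracles.  These deliberately avoid the package's
# own code paths (and the library calls behind them): direct formulas,
# exhaustive enumeration, hand-rolled rank sums.

# Pearson correlation by the direct formula.
pearson_brute <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# P(X >= k) for X ~ Hypergeom(N population, m successes, n draws),
# by exhaustive combinatorial summation.
hyper_tail_brute <- function(k, N, m, n) {
  hi <- min(m, n)
  if (k > hi) return(0)
  i <- max(k, 0):hi
  sum(choose(m, i) * choose(N - m, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up by hand: sort ascending, p_(i) * m / i,
# enforce monotonicity from the largest rank down, restore input order.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  if (m == 1) adj <- pmin(p, 1)
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Harrell's C by exhaustive pair enumeration.  A pair is usable iff the
# shorter observed time carries an event and the times differ, or the times
# tie with discordant event status (the censored sample is the survivor).
# Risk ties score 0.5.
concordance_brute <- function(time, event, risk) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) {
      if (event[i] == event[j]) next           # both events or both censored
      short <- which.max(c(event[i], event[j])) # the event is "shorter"
    } else {
      short <- which.min(c(time[i], time[j]))
      if (c(event[i], event[j])[short] == 0) next
    }
    long <- 3 - short
    r <- c(risk[i], risk[j])
    den <- den + 1
    if (r[short] > r[long]) num <- num + 1
    else if (r[short] == r[long]) num <- num + 0.5
  }
  list(C = num / den, usable = den)
}

# Product-limit estimator by hand over unique event times.
km_brute <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ut, survival = surv)
}

# Two-group log-rank chi-square from first principles.
logrank_brute <- function(time, event, group) {
  g <- unique(group)
  stopifnot(length(g) == 2)
  ut <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ut) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Small deterministic expression fixture: 4 genes x 3 samples.
tiny_matrix <- function() {
  matrix(c(1, 2, 3,
           4, 5, 6,
           0, 4, 0,
           7, 7, 7),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("gA", "gB", "gC", "gD"),
                         c("s1", "s2", "s3")))
}
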