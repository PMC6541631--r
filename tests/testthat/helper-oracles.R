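# Independent brute-force oracles. These deliberately re-derive each
# quantity by explicit loops over risk sets, never by calling the package's
# vectorized code paths.

# Product-limit estimate by explicit risk-set bookkeeping.
oracle_km <- function(times, events) {
  out_t <- numeric(0)
  out_s <- numeric(0)
  s <- 1
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- 0
    d <- 0
    for (i in seq_along(times)) {
      if (times[i] >= t) at_risk <- at_risk + 1
      if (times[i] == t && events[i] == 1) d <- d + 1
    }
    s <- s * (1 - d / at_risk)
    out_t <- c(out_t, t)
    out_s <- c(out_s, s)
  }
  list(time = out_t, surv = out_s)
}

# Two-group logrank statistic by direct evaluation of the O/E/V sums.
oracle_logrank_chisq <- function(times, events, x) {
  o1 <- 0; e1 <- 0; v <- 0
  for (t in sort(unique(times[events == 1]))) {
    n <- sum(times >= t)
    n1 <- sum(times >= t & x == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & x == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1)
      v <- v + d * (n - d) / (n - 1) * (n1 / n) * (1 - n1 / n)
  }
  if (v == 0) return(0)
  (o1 - e1)^2 / v
}

# Naive Cox partial log-likelihood for a binary covariate, explicit loops.
oracle_cox_loglik <- function(times, events, x, beta,
                              ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    risk <- which(times >= t)
    dead <- which(times == t & events == 1)
    d <- length(dead)
    ll <- ll + beta * sum(x[dead])
    sum_risk <- sum(exp(beta * x[risk]))
    sum_dead <- sum(exp(beta * x[dead]))
    for (k in seq_len(d) - 1) {
      denom <- if (ties == "efron") sum_risk - (k / d) * sum_dead
               else sum_risk
      ll <- ll - log(denom)
    }
  }
  ll
}

# Brute-force maximization of the naive partial likelihood.
oracle_cox_beta <- function(times, events, x, ties = "efron") {
  stats::optimize(function(b) oracle_cox_loglik(times, events, x, b, ties),
                  interval = c(-8, 8), maximum = TRUE,
                  tol = 1e-10)$maximum
}

# Exact hypergeometric upper tail P(X >= q) by pmf summation with choose().
oracle_hyper_tail <- function(q, set_size, universe_size, target_size) {
  total <- choose(universe_size, target_size)
  p <- 0
  for (i in q:min(set_size, target_size)) {
    if (target_size - i > universe_size - set_size) next
    p <- p + choose(set_size, i) *
      choose(universe_size - set_size, target_size - i) / total
  }
  p
}

# Random right-censored survival instance for property tests.
random_surv_instance <- function(n, tie_prob = 0.3, censor_prob = 0.3) {
  times <- round(rexp(n, 0.2), if (runif(1) < tie_prob) 0 else 3)
  times <- pmax(times, 0.1)
  events <- rbinom(n, 1, 1 - censor_prob)
  list(times = times, events = events)
}

# Normalized expression matrix from a plain numeric matrix.
norm_expr <- function(values) zscore_normalize(expression_matrix(values))

# Expression matrix whose rows are already exact Z-scores.
as_normalized <- function(values) expression_matrix(values, normalized = TRUE)

gene_mat <- function(nr, nc, data, genes = sprintf("g%02d", seq_len(nr)),
                     samples = sprintf("s%02d", seq_len(nc))) {
  matrix(data, nr, nc, dimnames = list(genes, samples))
}
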