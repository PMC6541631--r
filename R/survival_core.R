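#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function from right-censored data by the
#' product-limit formula S(t) = prod over event times t_i <= t of
#' (1 - d_i / n_i), where d_i is the number of events and n_i the number at
#' risk at t_i. Subjects censored at t remain at risk for events at t
#' (the standard convention). The median is the smallest event time at
#' which S drops to 0.5 or below, undefined (NA) if the curve never does.
#'
#' @param times Non-negative follow-up times (months).
#' @param events Event indicators, 1 = event observed, 0 = right-censored.
#' @return An object of class `SurvivalCurve`: list with `event_times`,
#'   `survival_prob`, `n_at_risk`, `n_events` (per distinct event time),
#'   `median_survival`, `n`, `n_events_total`.
#' @examples
#' km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))$median_survival  # 2
#' @export
km_estimate <- function(times, events) {
  check_surv_input(times, events)
  dt <- sort(unique(times[events == 1]))
  if (!length(dt)) {
    curve <- structure(list(event_times = numeric(0),
                            survival_prob = numeric(0),
                            n_at_risk = integer(0), n_events = integer(0),
                            median_survival = NA_real_,
                            n = length(times), n_events_total = 0L),
                       class = "SurvivalCurve")
    return(curve)
  }
  n_risk <- vapply(dt, function(x) sum(times >= x), integer(1))
  d <- vapply(dt, function(x) sum(times == x & events == 1), integer(1))
  s <- cumprod(1 - d / n_risk)
  med <- if (any(s <= 0.5)) dt[which(s <= 0.5)[1]] else NA_real_
  structure(list(event_times = dt, survival_prob = s, n_at_risk = n_risk,
                 n_events = d, median_survival = med,
                 n = length(times), n_events_total = sum(events == 1)),
            class = "SurvivalCurve")
}

check_surv_input <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input")
  if (length(times) != length(events))
    stop("'times' and 'events' must have equal length")
  if (any(is.na(times)) || any(is.na(events)))
    stop("missing values in survival input")
  if (any(times < 0)) stop("negative survival time")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  invisible(TRUE)
}

#' @export
print.SurvivalCurve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s months\n",
              x$n, x$n_events_total,
              if (is.na(x$median_survival)) "not reached"
              else format(x$median_survival)))
  invisible(x)
}

#' Export a survival curve as a step-function table
#'
#' @param x A `SurvivalCurve`.
#' @param path Optional path; if given the table is written as TSV.
#' @return A data.frame with columns `time`, `n_at_risk`, `n_events`,
#'   `survival` (invisibly if written to file).
#' @export
km_table <- function(x, path = NULL) {
  df <- data.frame(time = x$event_times, n_at_risk = x$n_at_risk,
                   n_events = x$n_events, survival = x$survival_prob)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

# Tabulate the two-group risk-set bookkeeping at each distinct event time.
# Returns per event time: n at risk (total / group 1), events (total /
# group 1 / group 0). x is the 0/1 covariate.
risk_set_table <- function(times, events, x) {
  dt <- sort(unique(times[events == 1]))
  n <- vapply(dt, function(t) sum(times >= t), numeric(1))
  n1 <- vapply(dt, function(t) sum(times >= t & x == 1), numeric(1))
  d <- vapply(dt, function(t) sum(times == t & events == 1), numeric(1))
  d1 <- vapply(dt, function(t) sum(times == t & events == 1 & x == 1),
               numeric(1))
  list(time = dt, n = n, n1 = n1, n0 = n - n1, d = d, d1 = d1, d0 = d - d1)
}

#' Two-group logrank test
#'
#' At each distinct event time, the expected number of events in each group
#' is the hypergeometric mean d * n_g / n and the variance is the
#' hypergeometric variance d (n - d) n_1 n_0 / (n^2 (n - 1)); the statistic
#' is (O - E)^2 / V on 1 degree of freedom.
#'
#' @inheritParams km_estimate
#' @param groups Group labels; exactly two distinct non-missing values.
#' @return An object of class `LogrankResult`: `chi_square`, `p_value`,
#'   `observed`, `expected` (named per group), `groups` (level names),
#'   `n` per group.
#' @export
logrank_test <- function(times, events, groups) {
  check_surv_input(times, events)
  g <- as.factor(groups)
  if (length(g) != length(times)) stop("'groups' length mismatch")
  lev <- levels(droplevels(g))
  if (length(lev) != 2L)
    stop("logrank test needs exactly two non-empty groups (got ",
         length(lev), ")")
  x <- as.integer(g == lev[2])
  rs <- risk_set_table(times, events, x)
  if (!length(rs$time)) {
    warning("no events observed; logrank p set to 1")
    res <- list(chi_square = 0, p_value = 1,
                observed = stats::setNames(c(0, 0), lev),
                expected = stats::setNames(c(0, 0), lev),
                groups = lev,
                n = stats::setNames(c(sum(x == 0), sum(x == 1)), lev))
    class(res) <- "LogrankResult"
    return(res)
  }
  e1 <- rs$d * rs$n1 / rs$n
  v <- ifelse(rs$n > 1,
              rs$d * (rs$n - rs$d) * rs$n1 * rs$n0 / (rs$n^2 * (rs$n - 1)),
              0)
  o1 <- sum(rs$d1)
  E1 <- sum(e1)
  V <- sum(v)
  chi <- if (V > 0) (o1 - E1)^2 / V else 0
  p <- if (V > 0) stats::pchisq(chi, df = 1, lower.tail = FALSE) else 1
  res <- list(chi_square = chi, p_value = p,
              observed = stats::setNames(c(sum(rs$d0), o1), lev),
              expected = stats::setNames(c(sum(rs$d) - E1, E1), lev),
              groups = lev,
              n = stats::setNames(c(sum(x == 0), sum(x == 1)), lev))
  class(res) <- "LogrankResult"
  res
}

#' @export
print.LogrankResult <- function(x, ...) {
  cat(sprintf("Logrank test: chi-square = %.4g (1 df), p = %.4g\n",
              x$chi_square, x$p_value))
  invisible(x)
}

#' Cox proportional hazards for a binary group covariate
#'
#' Maximizes the Cox partial likelihood for a single 0/1 covariate by
#' Newton-Raphson, with Efron (default) or Breslow handling of tied event
#' times. The standard error comes from the observed information at the
#' maximum; the p-value is a two-sided Wald test. Convergence is declared
#' when the absolute score falls below `tol` (default 1e-9) within 50
#' iterations. A monotone likelihood (all events stacked in one group's
#' favor) cannot be maximized at finite beta; the coefficient is then
#' capped at +/-20 and `converged` is set `FALSE` — the p-value is
#' unreliable in that case.
#'
#' @inheritParams logrank_test
#' @param groups Group labels; the second factor level is coded 1, so with
#'   `factor(labels, levels = c("low", "high"))` the hazard ratio is
#'   high vs low.
#' @param ties `"efron"` or `"breslow"`.
#' @param tol Score-norm convergence tolerance.
#' @return An object of class `CoxResult`: `beta` (log hazard ratio),
#'   `hazard_ratio`, `se_beta`, `wald_z`, `p_value`, `ties`, `converged`,
#'   `iterations`, `n_used`, `n_events`, `loglik`, `groups`.
#' @export
cox_fit_binary <- function(times, events, groups,
                           ties = c("efron", "breslow"), tol = 1e-9) {
  ties <- match.arg(ties)
  check_surv_input(times, events)
  g <- as.factor(groups)
  lev <- levels(droplevels(g))
  if (length(lev) != 2L)
    stop("cox_fit_binary needs exactly two non-empty groups (got ",
         length(lev), ")")
  x <- as.integer(g == lev[2])
  rs <- risk_set_table(times, events, x)
  n_ev <- sum(rs$d)
  out <- list(beta = 0, hazard_ratio = 1, se_beta = NA_real_,
              wald_z = NA_real_, p_value = 1, ties = ties,
              converged = FALSE, iterations = 0L,
              n_used = length(times), n_events = as.integer(n_ev),
              loglik = 0, groups = lev)
  class(out) <- "CoxResult"
  if (n_ev == 0) {
    warning("no events observed; Cox fit undefined, beta set to 0")
    return(out)
  }
  # Expanded per-(event time, k) vectors for the Efron correction:
  # the k-th of d tied events sees risk denominator R - (k/d) * D, where
  # R sums exp(beta x) over the risk set and D over the tied events.
  # Breslow is the special case k/d == 0 repeated d times.
  d_rep <- rep.int(rs$d, rs$d)
  frac <- if (ties == "efron") sequence(rs$d) - 1 else rep.int(0L, sum(rs$d))
  frac <- frac / d_rep
  n1e <- rep.int(rs$n1, rs$d)
  n0e <- rep.int(rs$n0, rs$d)
  d1e <- rep.int(rs$d1, rs$d)
  d0e <- rep.int(rs$d0, rs$d)
  a <- n1e - frac * d1e     # d/dw of the denominator, divided by nothing
  b0 <- n0e - frac * d0e    # group-0 part of the denominator
  s1 <- sum(rs$d1)          # sum of x over events
  score_info <- function(beta) {
    w <- exp(beta)
    denom <- b0 + a * w
    q <- a * w / denom
    list(u = s1 - sum(q), i = sum(q * (1 - q)),
         ll = beta * s1 - sum(log(denom)))
  }
  beta <- 0
  converged <- FALSE
  iter <- 0L
  repeat {
    si <- score_info(beta)
    if (abs(si$u) < tol) { converged <- TRUE; break }
    if (iter >= 50L) break
    step <- if (si$i > 0) si$u / si$i else sign(si$u) * 1
    # dampen huge steps so the iteration cannot overshoot into overflow
    if (abs(step) > 5) step <- sign(step) * 5
    beta <- beta + step
    iter <- iter + 1L
    if (abs(beta) > 20) { beta <- sign(beta) * 20; converged <- FALSE; break }
  }
  si <- score_info(beta)
  se <- if (si$i > 0) 1 / sqrt(si$i) else NA_real_
  z <- if (!is.na(se)) beta / se else NA_real_
  out$beta <- beta
  out$hazard_ratio <- exp(beta)
  out$se_beta <- se
  out$wald_z <- z
  out$p_value <- if (!is.na(z)) 2 * stats::pnorm(-abs(z)) else 1
  out$converged <- converged && abs(beta) < 20
  out$iterations <- iter
  out$loglik <- si$ll
  out
}

#' @export
print.CoxResult <- function(x, ...) {
  cat(sprintf(
    "Cox PH (binary, %s ties): HR = %.4g, beta = %.4g (se %.3g), p = %.4g%s\n",
    x$ties, x$hazard_ratio, x$beta, x$se_beta, x$p_value,
    if (!x$converged) " [NOT converged]" else ""))
  invisible(x)
}
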