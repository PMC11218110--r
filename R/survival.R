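#' Kaplan-Meier product-limit estimator
#'
#' Computes the product-limit survival curve with the standard convention
#' that subjects censored at an event time remain at risk for that event.
#' The median is the smallest observed time at which S(t) <= 0.5, and
#' `NA` when the curve never reaches 0.5.
#'
#' @param time positive, finite follow-up times (months)
#' @param event 1 = event observed, 0 = censored
#' @return object of class `km_curve`: list with `curve` (data.frame time,
#'   n_risk, n_event, n_censor, surv), `median`, `n`, `n_events`
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stop("empty survival table")
  stopifnot(length(time) == length(event),
            all(is.finite(time)), all(time > 0),
            all(event %in% c(0, 1)))
  times <- sort(unique(time))
  n_risk <- vapply(times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(times, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(times, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  curve <- data.frame(time = times, n_risk = n_risk, n_event = n_event,
                      n_censor = n_censor, surv = surv)
  med <- if (any(surv <= 0.5)) times[which(surv <= 0.5)[1]] else NA_real_
  structure(list(curve = curve, median = med, n = length(time),
                 n_events = sum(event)), class = "km_curve")
}

#' Kaplan-Meier curves per subgroup
#'
#' @param time,event as in [km_estimate()]
#' @param group subgroup label per subject
#' @return named list of `km_curve` objects
#' @export
km_by <- function(time, event, group) {
  stopifnot(length(group) == length(time))
  idx <- split(seq_along(time), group)
  lapply(idx, function(i) km_estimate(time[i], event[i]))
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic: at each distinct event time the observed
#' events in group A are compared with their hypergeometric expectation
#' given the pooled risk set; the squared standardized sum is referred to a
#' chi-square distribution with 1 degree of freedom.
#'
#' @param time,event as in [km_estimate()]
#' @param group label per subject, exactly 2 levels
#' @return list with `chisq`, `p`, `observed` and `expected` (per group)
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  g <- factor(group)
  if (nlevels(g) != 2) stop("log-rank test requires exactly 2 groups")
  if (sum(event) == 0) stop("no events observed in either group")
  is1 <- g == levels(g)[1]
  etimes <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in etimes) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & is1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & is1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (o1 - e1)^2 / v
  o <- c(o1, sum(event) - o1)
  e <- c(e1, sum(event) - e1)
  names(o) <- names(e) <- levels(g)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = o, expected = e)
}

# Cox partial log-likelihood, score and information for a single covariate,
# with Efron or Breslow handling of tied event times.
cox_derivs <- function(beta, time, event, x, ties) {
  etimes <- sort(unique(time[event == 1]))
  w <- exp(beta * x)
  ll <- sc <- info <- 0
  for (t in etimes) {
    risk <- time >= t
    dead <- time == t & event == 1
    d <- sum(dead)
    s0 <- sum(w[risk]); s1 <- sum(w[risk] * x[risk])
    s2 <- sum(w[risk] * x[risk]^2)
    xsum <- sum(x[dead])
    if (ties == "breslow" || d == 1) {
      ll <- ll + beta * xsum - d * log(s0)
      sc <- sc + xsum - d * s1 / s0
      info <- info + d * (s2 / s0 - (s1 / s0)^2)
    } else {
      s0d <- sum(w[dead]); s1d <- sum(w[dead] * x[dead])
      s2d <- sum(w[dead] * x[dead]^2)
      for (l in seq_len(d) - 1) {
        f <- l / d
        a0 <- s0 - f * s0d; a1 <- s1 - f * s1d; a2 <- s2 - f * s2d
        ll <- ll - log(a0)
        sc <- sc - a1 / a0
        info <- info + a2 / a0 - (a1 / a0)^2
      }
      ll <- ll + beta * xsum
      sc <- sc + xsum
    }
  }
  list(loglik = ll, score = sc, info = info)
}

#' Cox proportional-hazards fit for a single covariate
#'
#' Maximizes the partial likelihood by Newton-Raphson with Efron handling of
#' tied event times (Breslow available). Convergence is declared when the
#' step size falls below `tol`; a diverging coefficient (monotone
#' likelihood, i.e. complete separation of events by the covariate) raises
#' an error with a diagnostic.
#'
#' @param time,event as in [km_estimate()]
#' @param x numeric covariate (binary indicators coded 0/1 are typical)
#' @param ties "efron" (default) or "breslow"
#' @param tol convergence tolerance on the Newton step
#' @param max_iter iteration cap
#' @return object of class `cox_fit`: list with `coef`, `se`, `hr`,
#'   `ci_lower`, `ci_upper`, `loglik`, `iter`, `ties`
#' @export
cox_fit <- function(time, event, x, ties = c("efron", "breslow"),
                    tol = 1e-8, max_iter = 100) {
  ties <- match.arg(ties)
  stopifnot(length(time) == length(event), length(time) == length(x),
            all(is.finite(x)))
  if (length(unique(x)) < 2) stop("covariate is constant; cannot fit")
  if (sum(event) < 2) stop("need at least 2 observed events")
  beta <- 0
  for (i in seq_len(max_iter)) {
    d <- cox_derivs(beta, time, event, x, ties)
    if (!is.finite(d$info) || d$info <= 0)
      stop("singular information; check the covariate coding")
    step <- d$score / d$info
    beta <- beta + step
    if (abs(beta) > 15)
      stop("coefficient diverging (|beta| > 15): monotone partial ",
           "likelihood, the covariate perfectly separates event order")
    if (abs(step) < tol) break
  }
  if (abs(step) >= tol)
    warning("Newton-Raphson did not converge in ", max_iter, " iterations")
  d <- cox_derivs(beta, time, event, x, ties)
  se <- 1 / sqrt(d$info)
  structure(list(coef = beta, se = se, hr = exp(beta),
                 ci_lower = exp(beta - 1.96 * se),
                 ci_upper = exp(beta + 1.96 * se),
                 loglik = d$loglik, iter = i, ties = ties),
            class = "cox_fit")
}

#' Significance stars for p-values
#'
#' The conventional annotation: `***` p < 0.001, `**` p < 0.01, `*`
#' p < 0.05, empty otherwise.
#'
#' @param p numeric vector of p-values
#' @return character vector of stars
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
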