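# Product-limit survival estimation and the log-rank test.
#
# Both statistics are authored here; the survival package serves only as
# an independent cross-check in the test suite.

#' Kaplan-Meier product-limit survival estimate
#'
#' S(t) = prod over distinct death times t_i <= t of (1 - d_i / n_i).
#' Individuals censored at a death time remain at risk for that death
#' (the standard convention).
#'
#' @param time Non-negative follow-up times (days since tagging).
#' @param event 1/TRUE for death, 0/FALSE for censoring.
#' @return An object of class `vt_km`: data frame `table` with columns
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`, plus `n`.
#' @export
kaplan_meier <- function(time, event) {
  time <- as.numeric(time)
  event <- as.integer(as.logical(event))
  if (length(time) < 1L) stop("at least one observation is required")
  if (any(!is.finite(time)) || any(time < 0))
    stop("times must be finite and non-negative")
  if (length(event) != length(time)) stop("time/event length mismatch")

  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), 0)
  n_event <- vapply(ut, function(t) sum(time == t & event == 1L), 0)
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0L), 0)
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(table = data.frame(time = ut, n_risk = n_risk,
                                    n_event = n_event,
                                    n_censor = n_censor, surv = surv),
                 n = length(time)),
            class = "vt_km")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km A `vt_km` object.
#' @param t Times at which to evaluate S(t).
#' @return Numeric vector of survival probabilities (S = 1 before the
#'   first event time).
#' @export
km_surv_at <- function(km, t) {
  tab <- km$table
  idx <- findInterval(t, tab$time)
  out <- rep(1, length(t))
  out[idx > 0L] <- tab$surv[idx[idx > 0L]]
  out
}

#' @export
print.vt_km <- function(x, ...) {
  tab <- x$table
  deaths <- sum(tab$n_event)
  cat(sprintf("<vt_km> n = %d, deaths = %d, censored = %d\n",
              x$n, deaths, x$n - deaths))
  med <- tab$time[tab$surv <= 0.5][1L]
  cat(sprintf("  median survival: %s\n",
              if (is.na(med)) "not reached" else sprintf("%.0f days", med)))
  invisible(x)
}

#' @export
summary.vt_km <- function(object, ...) {
  tab <- object$table
  tab[tab$n_event > 0L | tab$n_censor > 0L, ]
}

#' @export
plot.vt_km <- function(x, xlab = "days since tagging",
                       ylab = "apparent survival", ...) {
  tab <- x$table
  graphics::plot(stats::stepfun(tab$time, c(1, tab$surv)),
                 do.points = FALSE, xlab = xlab, ylab = ylab,
                 ylim = c(0, 1), ...)
  cens <- tab$time[tab$n_censor > 0L]
  if (length(cens) > 0L)
    graphics::points(cens, km_surv_at(x, cens), pch = 3)
  invisible(x)
}

#' Log-rank test for two or more survival curves
#'
#' Observed-versus-expected deaths pooled over distinct event times,
#' with the usual hypergeometric variance; the statistic is
#' U' V^{-1} U over the first g-1 groups and is chi-squared with
#' `g - 1` degrees of freedom under the null.
#'
#' @param time Follow-up times.
#' @param event Death indicators (1 = death, 0 = censored).
#' @param group Group labels (>= 2 non-empty groups).
#' @return An object of class `vt_logrank`: list with `chisq`, `df`,
#'   `p`, and per-group observed/expected counts.
#' @export
log_rank <- function(time, event, group) {
  time <- as.numeric(time)
  event <- as.integer(as.logical(event))
  group <- as.factor(group)
  if (any(table(group) == 0L) || nlevels(group) < 2L)
    stop("log_rank needs at least two non-empty groups")
  if (length(time) != length(event) || length(time) != length(group))
    stop("time/event/group length mismatch")

  g <- nlevels(group)
  dtimes <- sort(unique(time[event == 1L]))
  O <- numeric(g); E <- numeric(g)
  V <- matrix(0, g, g)
  for (t in dtimes) {
    at_risk <- time >= t
    N <- sum(at_risk)
    d <- sum(time == t & event == 1L)
    n_g <- vapply(levels(group), function(l) sum(at_risk & group == l), 0)
    d_g <- vapply(levels(group),
                  function(l) sum(time == t & event == 1L & group == l), 0)
    O <- O + d_g
    E <- E + d * n_g / N
    if (N > 1L) {
      fac <- d * (N - d) / (N - 1) / N
      V <- V + fac * (diag(n_g, g) - tcrossprod(n_g) / N)
    }
  }
  U <- (O - E)[-g]
  Vm <- V[-g, -g, drop = FALSE]
  chisq <- if (all(abs(U) < 1e-12)) 0 else
    as.numeric(t(U) %*% solve(Vm, U))
  df <- g - 1L
  p <- stats::pchisq(chisq, df, lower.tail = FALSE)
  structure(list(chisq = chisq, df = df, p = p,
                 observed = stats::setNames(O, levels(group)),
                 expected = stats::setNames(E, levels(group))),
            class = "vt_logrank")
}

#' @export
print.vt_logrank <- function(x, ...) {
  cat(sprintf("<vt_logrank> chi-square = %.3f, df = %d, p = %.4g\n",
              x$chisq, x$df, x$p))
  tab <- data.frame(observed = x$observed, expected = round(x$expected, 2))
  print(tab)
  invisible(x)
}
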