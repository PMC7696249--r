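#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator (via \code{survival::survfit}) returned as a
#' tidy step table. Survival starts at 1 and is non-increasing; with no
#' censoring it equals 1 minus the empirical CDF of the event times.
#'
#' @param time positive times (or a data frame with \code{time},
#'   \code{event}).
#' @param event 1 = observed, 0 = censored (ignored when \code{time} is a
#'   data frame).
#' @return data frame of class \code{km_curve}: \code{time},
#'   \code{n_risk}, \code{n_event}, \code{n_censor}, \code{survival}.
#' @export
km_estimate <- function(time, event = NULL) {
  if (is.data.frame(time)) { event <- time$event; time <- time$time }
  if (!length(time)) stop("need at least one subject")
  if (any(time <= 0)) stop("times must be > 0")
  if (is.null(event)) event <- rep(1L, length(time))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, n_censor = sf$n.censor,
                    survival = sf$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @export
plot.km_curve <- function(x, ...) {
  plot(c(0, x$time), c(1, x$survival), type = "s", ylim = c(0, 1),
       xlab = "time", ylab = "survival", ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' The standard (unweighted) log-rank statistic
#' \eqn{(\sum O_1 - \sum E_1)^2 / \sum V} with the hypergeometric
#' variance at each distinct event time, referred to chi-square on 1 df.
#'
#' @param time,event,group vectors over all subjects (\code{group} with
#'   exactly two levels); alternatively two data frames \code{low} /
#'   \code{high}, each with \code{time} and \code{event}.
#' @param low,high optional data frames (used when \code{time} is
#'   missing).
#' @return object of class \code{logrank_test}: \code{statistic},
#'   \code{p_value}, observed/expected per group.
#' @export
logrank <- function(time, event, group, low = NULL, high = NULL) {
  if (missing(time)) {
    stopifnot(!is.null(low), !is.null(high))
    time <- c(low$time, high$time)
    event <- c(low$event, high$event)
    group <- rep(c("low", "high"), c(nrow(low), nrow(high)))
  }
  g <- factor(group)
  if (nlevels(g) != 2) stop("exactly two groups required")
  if (any(table(g) == 0)) stop("one group is empty")
  if (sum(event) < 1) stop("need at least one observed event")
  comp <- .logrank_stat(time, event, g == levels(g)[2])
  structure(list(statistic = comp$stat,
                 p_value = pchisq(comp$stat, df = 1, lower.tail = FALSE),
                 observed = comp$obs, expected = comp$exp,
                 groups = levels(g)),
            class = "logrank_test")
}

## core computation; z: logical membership of group 2
.logrank_stat <- function(time, event, z) {
  et <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  obs <- c(0, 0); expc <- c(0, 0)
  for (t in et) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & z)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & z)
    e <- d * n1 / n
    o1 <- o1 + d1; e1 <- e1 + e
    obs <- obs + c(d - d1, d1)
    expc <- expc + c(d - e, e)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  list(stat = stat, obs = obs, exp = expc)
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Log-rank test\n")
  cat(sprintf("  observed events: %s = %g, %s = %g\n",
              x$groups[1], x$observed[1], x$groups[2], x$observed[2]))
  cat(sprintf("  chi-square = %.4f (1 df), p = %.4g\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' Expression-cutoff scan minimizing the log-rank p-value
#'
#' Re-implementation of the "Kaplan-Meier by gene expression" scan modus:
#' every midpoint between consecutive distinct expression values that
#' leaves both groups with at least \code{min_group_frac} of the cohort
#' is tested with a two-group log-rank test; the reported best cutoff
#' minimizes p (ties broken toward the cutoff nearest the median
#' expression, then toward the lower cutoff). The minimum p over a scan
#' is anti-conservative; the number of cutoffs scanned is always reported
#' so users can correct for multiplicity.
#'
#' @param cohort data frame: \code{expression}, \code{time}, \code{event}.
#' @param min_group_frac minimum fraction of subjects on each side of an
#'   admissible cutoff (default 0.1).
#' @return object of class \code{km_scan}: scan table (cutoff, n_low,
#'   n_high, statistic, p), \code{best_cutoff}, \code{min_p},
#'   \code{n_cutoffs_scanned}.
#' @export
scan_cutoff <- function(cohort, min_group_frac = 0.1) {
  stopifnot(all(c("expression", "time", "event") %in% names(cohort)))
  ex <- cohort$expression
  ux <- sort(unique(ex))
  if (length(ux) < 2) stop("need at least 2 distinct expression values")
  n <- nrow(cohort)
  cand <- (ux[-1] + ux[-length(ux)]) / 2
  n_low <- vapply(cand, function(c) sum(ex <= c), integer(1))
  n_high <- n - n_low
  admis <- n_low >= min_group_frac * n & n_high >= min_group_frac * n
  cand <- cand[admis]; n_low <- n_low[admis]; n_high <- n_high[admis]
  if (!length(cand))
    stop("no admissible cutoff under min_group_frac = ", min_group_frac)
  stat <- p <- numeric(length(cand))
  for (i in seq_along(cand)) {
    comp <- .logrank_stat(cohort$time, cohort$event, ex > cand[i])
    stat[i] <- comp$stat
    p[i] <- pchisq(comp$stat, df = 1, lower.tail = FALSE)
  }
  tab <- data.frame(cutoff = cand, n_low = n_low, n_high = n_high,
                    statistic = stat, p = p)
  best <- which(p == min(p))
  if (length(best) > 1) {
    dmed <- abs(cand[best] - median(ex))
    best <- best[dmed == min(dmed)][1]
  }
  structure(list(table = tab, best_cutoff = cand[best], min_p = min(p),
                 n_cutoffs_scanned = length(cand),
                 min_group_frac = min_group_frac, n = n),
            class = "km_scan")
}

#' @export
print.km_scan <- function(x, ...) {
  cat("Expression-cutoff log-rank scan\n")
  cat(sprintf("  %d subjects; %d cutoffs scanned (min group fraction %g)\n",
              x$n, x$n_cutoffs_scanned, x$min_group_frac))
  cat(sprintf("  best cutoff %.4g with p = %.4g\n", x$best_cutoff, x$min_p))
  cat("  note: the scan minimum p is anti-conservative; correct for the\n",
      "  number of cutoffs scanned (e.g. Bonferroni) before interpreting\n",
      sep = "")
  invisible(x)
}

#' @export
plot.km_scan <- function(x, ...) {
  plot(x$table$cutoff, -log10(x$table$p), type = "b", pch = 19,
       xlab = "expression cutoff", ylab = "-log10 p", ...)
  abline(v = x$best_cutoff, lty = 2)
  invisible(x)
}
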