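#' Caliper tumor volume
#'
#' The standard xenograft ellipsoid approximation
#' \code{(length x width^2) / 2}, with width taken as the smaller caliper
#' reading (auto-swapped, so argument order is irrelevant).
#'
#' @param length_mm,width_mm caliper readings (mm), > 0; vectorized.
#' @return volume in cubic mm.
#' @export
#' @examples
#' tumor_volume(10, 5)   # 125
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm <= 0) || any(width_mm <= 0))
    stop("caliper dimensions must be > 0")
  l <- pmax(length_mm, width_mm)
  w <- pmin(length_mm, width_mm)
  l * w^2 / 2
}

#' Apply randomization and endpoint rules to a caliper table
#'
#' Bookkeeping for a treatment study: each mouse's study day 0 is
#' redefined as the first measurement day its volume reaches
#' \code{randomization_volume}; rows after the first crossing of
#' \code{endpoint_volume} (the crossing row itself is kept) or beyond
#' \code{endpoint_day} study days are excluded; mice that never reach the
#' randomization volume are excluded entirely. Every exclusion is listed
#' in the exclusion ledger.
#'
#' @param measurements data frame: \code{mouse_id}, \code{group},
#'   \code{day}, \code{length_mm}, \code{width_mm} (or a precomputed
#'   \code{volume_mm3}).
#' @param randomization_volume cubic mm (default 100).
#' @param endpoint_volume cubic mm (default 1500).
#' @param endpoint_day last retained study day (default 18).
#' @return object of class \code{tumor_study}: \code{$measurements}
#'   (with \code{volume_mm3} and \code{study_day}), \code{$exclusions}
#'   ledger, \code{$group_sizes}, \code{$params}.
#' @export
apply_study_rules <- function(measurements, randomization_volume = 100,
                              endpoint_volume = 1500, endpoint_day = 18) {
  m <- measurements
  need <- c("mouse_id", "group", "day")
  if (!all(need %in% names(m)))
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  if (any(m$day < 0)) stop("day values must be non-negative")
  n_swapped <- 0L
  if (!"volume_mm3" %in% names(m)) {
    n_swapped <- sum(m$width_mm > m$length_mm)
    m$volume_mm3 <- tumor_volume(m$length_mm, m$width_mm)
  }
  m <- m[order(m$mouse_id, m$day), ]
  keep <- logical(nrow(m))
  study_day <- rep(NA_real_, nrow(m))
  ledger <- list()
  for (mouse in unique(m$mouse_id)) {
    i <- which(m$mouse_id == mouse)
    v <- m$volume_mm3[i]
    d <- m$day[i]
    cross <- which(v >= randomization_volume)
    if (!length(cross)) {
      ledger[[length(ledger) + 1L]] <- data.frame(
        mouse_id = mouse, reason = "never_randomized", n_rows = length(i),
        detail = sprintf("max volume %.1f < %.0f mm3", max(v),
                         randomization_volume), stringsAsFactors = FALSE)
      next
    }
    d0 <- d[cross[1]]
    sd_i <- d - d0
    ok <- sd_i >= 0
    past_day <- ok & sd_i > endpoint_day
    if (any(past_day)) {
      ledger[[length(ledger) + 1L]] <- data.frame(
        mouse_id = mouse, reason = "past_endpoint_day",
        n_rows = sum(past_day),
        detail = sprintf("study days > %g", endpoint_day),
        stringsAsFactors = FALSE)
      ok <- ok & !past_day
    }
    hit_ep <- which(ok & v >= endpoint_volume)
    if (length(hit_ep)) {
      after <- ok & seq_along(i) > hit_ep[1]
      if (any(after)) {
        ledger[[length(ledger) + 1L]] <- data.frame(
          mouse_id = mouse, reason = "past_endpoint_volume",
          n_rows = sum(after),
          detail = sprintf("crossed %.0f mm3 on study day %g",
                           endpoint_volume, sd_i[hit_ep[1]]),
          stringsAsFactors = FALSE)
        ok <- ok & !after
      }
    }
    keep[i] <- ok
    study_day[i] <- sd_i
  }
  out <- m[keep, , drop = FALSE]
  out$study_day <- study_day[keep]
  rownames(out) <- NULL
  exclusions <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(mouse_id = character(), reason = character(),
               n_rows = integer(), detail = character(),
               stringsAsFactors = FALSE)
  gs <- table(out$group[!duplicated(out$mouse_id)])
  structure(list(
    measurements = out, exclusions = exclusions,
    group_sizes = gs, n_swapped = n_swapped,
    params = list(randomization_volume = randomization_volume,
                  endpoint_volume = endpoint_volume,
                  endpoint_day = endpoint_day,
                  volume_formula = "(length x width^2)/2")),
    class = "tumor_study")
}

#' @export
print.tumor_study <- function(x, ...) {
  cat("Tumor study\n")
  cat(sprintf("  %d retained measurements; groups: %s\n",
              nrow(x$measurements),
              paste(sprintf("%s (n=%d)", names(x$group_sizes),
                            as.integer(x$group_sizes)), collapse = ", ")))
  cat(sprintf(
    "  rules: randomize at %g mm3, endpoint %g mm3 / day %g; volume %s\n",
    x$params$randomization_volume, x$params$endpoint_volume,
    x$params$endpoint_day, x$params$volume_formula))
  if (nrow(x$exclusions))
    cat(sprintf("  exclusion ledger: %d entr%s (%s)\n", nrow(x$exclusions),
                if (nrow(x$exclusions) == 1) "y" else "ies",
                paste(unique(x$exclusions$reason), collapse = ", ")))
  if (x$n_swapped)
    cat(sprintf("  note: %d caliper pair(s) auto-oriented (width > length)\n",
                x$n_swapped))
  cat("  caveat: repeated measures within mouse are not modeled by the\n",
      "  two-way ANOVA stage\n", sep = "")
  invisible(x)
}

#' Two-way fixed-effects ANOVA of tumor volumes (group x day)
#'
#' Sums of squares by nested-model residual differences: Type II for
#' unbalanced data (noted in the output), which coincides with the
#' classical balanced decomposition
#' \code{SS_total = SS_group + SS_day + SS_interaction + SS_residual}
#' when cell counts are equal. Days are treated as a categorical factor;
#' repeated measures within mouse are not modeled.
#'
#' @param study a \code{\link{tumor_study}}, or a data frame with columns
#'   \code{group}, \code{study_day} (or \code{day}) and \code{volume_mm3}.
#' @param days \code{"all"} (default: an empty group x day cell is an
#'   error, named) or \code{"shared"} (restrict to days observed in every
#'   group, as happens when endpoint rules truncate some arms early).
#' @return object of class \code{tw_anova}: the ANOVA table (effect, ss,
#'   df, ms, f, p) and a balance note.
#' @export
two_way_anova <- function(study, days = c("all", "shared")) {
  days <- match.arg(days)
  d <- if (inherits(study, "tumor_study")) study$measurements else study
  if (!"study_day" %in% names(d)) d$study_day <- d$day
  stopifnot(all(c("group", "study_day", "volume_mm3") %in% names(d)))
  if (days == "shared") {
    tab <- table(d$group, d$study_day)
    shared <- colnames(tab)[colSums(tab == 0) == 0]
    if (length(shared) < 2) stop("fewer than 2 measurement days shared by ",
                                 "all groups")
    d <- d[as.character(d$study_day) %in% shared, , drop = FALSE]
  }
  g <- factor(d$group)
  t <- factor(d$study_day)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (nlevels(t) < 2) stop("need at least 2 measurement days")
  cells <- table(g, t)
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty group x day cell: group '%s', day %s",
                 rownames(cells)[idx[1]], colnames(cells)[idx[2]]))
  }
  y <- d$volume_mm3
  rss <- function(f) sum(lm(f, data = data.frame(y, g, t))$residuals^2)
  rss_g <- rss(y ~ g)
  rss_t <- rss(y ~ t)
  rss_gt <- rss(y ~ g + t)
  rss_full <- rss(y ~ g * t)
  ss <- c(group = rss_t - rss_gt,
          day = rss_g - rss_gt,
          interaction = rss_gt - rss_full,
          residual = rss_full)
  dfs <- c(group = nlevels(g) - 1L,
           day = nlevels(t) - 1L,
           interaction = (nlevels(g) - 1L) * (nlevels(t) - 1L),
           residual = length(y) - nlevels(g) * nlevels(t))
  if (dfs["residual"] < 1)
    warning("no residual degrees of freedom (one observation per cell); ",
            "F tests unavailable")
  ms <- ss / pmax(dfs, 1L)
  f <- c(ms[1:3] / ms["residual"], NA)
  p <- c(stats::pf(f[1:3], dfs[1:3], dfs["residual"], lower.tail = FALSE), NA)
  if (dfs["residual"] < 1) { f[] <- NA; p[] <- NA }
  balanced <- length(unique(as.vector(cells))) == 1
  tab <- data.frame(effect = names(ss), ss = unname(ss),
                    df = unname(dfs), ms = unname(ms),
                    f = unname(f), p = unname(p),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, balanced = balanced,
                 ss_total = sum((y - mean(y))^2),
                 note = if (balanced) "balanced design: classical SS"
                        else "unbalanced design: Type-II SS"),
            class = "tw_anova")
}

#' @export
print.tw_anova <- function(x, ...) {
  cat("Two-way ANOVA (group x day) -", x$note, "\n")
  tab <- x$table
  cat(sprintf("  %-12s %12s %4s %12s %8s %10s\n",
              "effect", "SS", "df", "MS", "F", "p"))
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-12s %12.4g %4d %12.4g %8s %10s\n", tab$effect[i],
                tab$ss[i], tab$df[i], tab$ms[i],
                if (is.na(tab$f[i])) "" else sprintf("%.3f", tab$f[i]),
                if (is.na(tab$p[i])) "" else format.pval(tab$p[i], digits = 3)))
  invisible(x)
}
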