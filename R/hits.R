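#' Call per-cell-line hits at a killing threshold
#'
#' A (cell line, compound) pair is a hit when its percent killing meets
#' the threshold; the default comparator is \code{">="} ("at least 50
#' percent killing"), a strict \code{">"} is available for the roll-up
#' convention.
#'
#' @param matrix a \code{\link{killing_matrix}}.
#' @param threshold percent-killing threshold (default 50).
#' @param op comparator, \code{">="} (default) or \code{">"}.
#' @return object of class \code{hit_table}: \code{$long} (cell_line,
#'   compound_id, percent_killing, is_hit), \code{$per_line} (n_hits,
#'   hit_fraction), \code{$per_compound} (n_lines_hit, mean_killing).
#' @export
call_hits <- function(matrix, threshold = 50, op = c(">=", ">")) {
  stopifnot(inherits(matrix, "killing_matrix"))
  op <- match.arg(op)
  v <- matrix$values
  if (nrow(v) == 0) stop("killing matrix has no cell lines")
  hit <- if (op == ">=") v >= threshold else v > threshold
  hit[is.na(hit)] <- FALSE
  cn <- colnames(v) %||% character(0)
  long <- data.frame(
    cell_line = rep(rownames(v), ncol(v)),
    compound_id = rep(cn, each = nrow(v)),
    percent_killing = as.vector(v),
    is_hit = as.vector(hit),
    stringsAsFactors = FALSE)
  per_line <- data.frame(
    cell_line = rownames(v),
    n_hits = rowSums(hit),
    n_compounds = ncol(v),
    hit_fraction = rowSums(hit) / ncol(v),
    stringsAsFactors = FALSE, row.names = NULL)
  per_compound <- data.frame(
    compound_id = cn,
    n_lines_hit = colSums(hit),
    mean_killing = colMeans(v, na.rm = TRUE),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(long = long, per_line = per_line,
                 per_compound = per_compound,
                 threshold = threshold, op = op),
            class = "hit_table")
}

#' @export
print.hit_table <- function(x, ...) {
  cat(sprintf("Hit table (killing %s %g):\n", x$op, x$threshold))
  pl <- x$per_line
  for (i in seq_len(nrow(pl)))
    cat(sprintf("  %-10s %4d / %d hits (%.1f%%)\n", pl$cell_line[i],
                pl$n_hits[i], pl$n_compounds[i], 100 * pl$hit_fraction[i]))
  invisible(x)
}

#' Analysis of Means for top-compound selection
#'
#' Flags compounds whose mean killing departs from the grand mean beyond
#' ANOM decision limits. Limits use the Bonferroni-t approximation to the
#' exact (multivariate-t) ANOM critical value: for group i of size
#' \eqn{n_i} among k groups totalling N observations,
#' \deqn{grand\ mean \pm t_{1-\alpha/(2k),\,N-k} \; s_p
#'       \sqrt{(N-n_i)/(N n_i)},}
#' which reduces to \eqn{s_p\sqrt{(k-1)/(kn)}} with \eqn{df = k(n-1)} when
#' balanced. Compounds above the upper limit are the "top candidates".
#'
#' @param x replicate killing per compound: a data frame with columns
#'   \code{group} and \code{value}, a named list of numeric vectors, or a
#'   matrix (columns = groups).
#' @param alpha family-wise level (default 0.05).
#' @return object of class \code{anom}: per-group table (n, mean, lcl,
#'   ucl, exceeds in above/below/within), grand mean, pooled sd, critical
#'   value, df.
#' @export
anom_top_drugs <- function(x, alpha = 0.05) {
  if (is.matrix(x)) {
    x <- data.frame(group = rep(colnames(x) %||% as.character(col(x)[1, ]),
                                each = nrow(x)),
                    value = as.vector(x), stringsAsFactors = FALSE)
  } else if (is.list(x) && !is.data.frame(x)) {
    x <- data.frame(group = rep(names(x), lengths(x)),
                    value = unlist(x, use.names = FALSE),
                    stringsAsFactors = FALSE)
  }
  stopifnot(all(c("group", "value") %in% names(x)))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  grp <- factor(x$group, levels = unique(x$group))
  k <- nlevels(grp)
  if (k < 2) stop("need at least 2 groups")
  n_i <- as.integer(table(grp))
  if (any(n_i < 2)) stop("every group needs >= 2 replicates")
  N <- sum(n_i)
  if (length(unique(n_i)) > 1)
    warning("unbalanced design: per-group n used in the decision limits; ",
            "this departs from classical ANOM")
  means <- tapply(x$value, grp, mean)
  gm <- mean(x$value)                      # weighted grand mean
  ss_within <- sum(tapply(x$value, grp,
                          function(v) sum((v - mean(v))^2)))
  df <- N - k
  sp <- sqrt(ss_within / df)
  h <- qt(1 - alpha / (2 * k), df)
  half <- h * sp * sqrt((N - n_i) / (N * n_i))
  zero_var <- sp == 0
  if (zero_var)
    warning("zero within-group variance everywhere: decision limits ",
            "collapse to the grand mean; every off-mean group is flagged")
  lcl <- gm - half
  ucl <- gm + half
  exceeds <- ifelse(means > ucl, "above",
                    ifelse(means < lcl, "below", "within"))
  tab <- data.frame(group = levels(grp), n = n_i, mean = as.numeric(means),
                    lcl = lcl, ucl = ucl, exceeds = exceeds,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, grand_mean = gm, pooled_sd = sp,
                 critical_value = h, alpha = alpha, k = k, df = df,
                 balanced = length(unique(n_i)) == 1),
            class = "anom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.anom <- function(x, ...) {
  cat(sprintf(
    "Analysis of Means (Bonferroni-t limits): k = %d groups, df = %d\n",
    x$k, x$df))
  cat(sprintf("  grand mean %.2f, pooled sd %.2f, alpha %.3g, h %.3f\n",
              x$grand_mean, x$pooled_sd, x$alpha, x$critical_value))
  ab <- x$table$group[x$table$exceeds == "above"]
  be <- x$table$group[x$table$exceeds == "below"]
  cat(sprintf("  above upper limit (top candidates): %d%s\n", length(ab),
              if (length(ab) && length(ab) <= 12)
                paste0(" [", paste(ab, collapse = ", "), "]") else ""))
  cat(sprintf("  below lower limit: %d\n", length(be)))
  invisible(x)
}

#' @export
summary.anom <- function(object, ...) {
  print(object)
  invisible(object$table)
}

#' ANOM decision chart
#'
#' Classic Analysis-of-Means plot: group means with the grand mean and
#' the upper/lower decision limits; flagged groups highlighted.
#'
#' @param x an \code{anom} object.
#' @param ... passed to \code{plot}.
#' @export
plot.anom <- function(x, ...) {
  tab <- x$table
  i <- seq_len(nrow(tab))
  ylim <- range(tab$mean, tab$lcl, tab$ucl)
  plot(i, tab$mean, pch = 19, xaxt = "n", xlab = "group",
       ylab = "group mean", ylim = ylim,
       col = ifelse(tab$exceeds == "within", "black", "red3"), ...)
  axis(1, at = i, labels = tab$group, las = 2, cex.axis = 0.7)
  abline(h = x$grand_mean, lty = 1)
  lines(i, tab$lcl, lty = 2, type = "s")
  lines(i, tab$ucl, lty = 2, type = "s")
  invisible(x)
}

#' Extract ANOM top candidates
#'
#' @param x an \code{anom} object.
#' @return character vector of groups above the upper decision limit.
#' @export
top_candidates <- function(x) {
  stopifnot(inherits(x, "anom"))
  x$table$group[x$table$exceeds == "above"]
}

#' Screen-level summary
#'
#' Per-line hit fractions, per-compound cross-line mean killing, and the
#' compounds whose mean killing across all lines exceeds a high bar
#' (default 95 percent, the "near-complete pan-line killing" flag).
#'
#' @param matrix a \code{\link{killing_matrix}}.
#' @param hits a \code{\link{call_hits}} result on the same matrix.
#' @param mean_bar pan-line mean-killing bar (default 95).
#' @return object of class \code{screen_summary}.
#' @export
summarize_screen <- function(matrix, hits, mean_bar = 95) {
  stopifnot(inherits(matrix, "killing_matrix"), inherits(hits, "hit_table"))
  if (!identical(sort(colnames(matrix$values) %||% character(0)),
                 sort(hits$per_compound$compound_id)))
    stop("matrix and hits disagree on the compound set")
  pc <- hits$per_compound
  pc$pan_line_flag <- pc$mean_killing > mean_bar
  pc <- pc[order(-pc$mean_killing, pc$compound_id), ]
  rownames(pc) <- NULL
  structure(list(per_line = hits$per_line, per_compound = pc,
                 mean_bar = mean_bar,
                 flagged = pc$compound_id[pc$pan_line_flag]),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("Screen summary\n  per-line hit fractions:\n")
  pl <- x$per_line
  for (i in seq_len(nrow(pl)))
    cat(sprintf("    %-10s %.1f%%\n", pl$cell_line[i],
                100 * pl$hit_fraction[i]))
  cat(sprintf("  compounds with mean killing > %g%% across all lines: %d\n",
              x$mean_bar, length(x$flagged)))
  if (length(x$flagged) && length(x$flagged) <= 10)
    cat("   ", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
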