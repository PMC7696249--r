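#' Roll compound hits up to annotated drug targets
#'
#' A drug counts toward a target when its killing exceeds the threshold
#' (strict \code{">"} by default, matching the "more than 50 percent
#' killing" filter convention) in the required cell lines; a target
#' passes the high-confidence filter when at least \code{min_drugs} of
#' its drugs qualify. Multi-target drugs (semicolon-separated
#' \code{targets}) count fully toward every annotated target.
#'
#' @param hits a \code{\link{call_hits}} result (its killing values are
#'   re-thresholded here with this function's own \code{threshold}/\code{op}).
#' @param annotation data frame: \code{compound_id}, \code{targets}
#'   (";"-separated for multi-target drugs), \code{pathway}.
#' @param level \code{"target"} (default) or \code{"pathway"}.
#' @param min_drugs minimum qualifying drugs for a passing target
#'   (default 3).
#' @param threshold percent-killing threshold (default 50).
#' @param op comparator, \code{">"} (default here) or \code{">="}.
#' @param require_lines \code{"all"} (default: a drug must qualify in
#'   every line), \code{"any"}, or a character vector of line names that
#'   must all qualify.
#' @return object of class \code{target_rollup}: ranked table (target,
#'   pathway, n_drugs_total, n_drugs_hit, hit_fraction, passes_filter)
#'   plus the parameters and the count of unannotated compounds.
#' @export
rollup <- function(hits, annotation, level = c("target", "pathway"),
                   min_drugs = 3, threshold = 50, op = c(">", ">="),
                   require_lines = "all") {
  stopifnot(inherits(hits, "hit_table"))
  level <- match.arg(level)
  op <- match.arg(op)
  if (is.null(annotation) || !nrow(annotation)) stop("empty annotation")
  long <- hits$long
  lines <- unique(long$cell_line)
  req <- if (identical(require_lines, "all")) lines
         else if (identical(require_lines, "any")) "any"
         else {
           if (!all(require_lines %in% lines))
             stop("require_lines not in the matrix: ",
                  paste(setdiff(require_lines, lines), collapse = ", "))
           require_lines
         }
  qual_w <- if (op == ">") long$percent_killing > threshold
            else long$percent_killing >= threshold
  qual_w[is.na(qual_w)] <- FALSE
  if (identical(req, "any")) {
    q <- tapply(qual_w, long$compound_id, any)
  } else {
    sub <- long$cell_line %in% req
    q <- tapply(qual_w[sub], long$compound_id[sub], all)
  }
  qualifies <- names(q)[q]

  ann <- annotation
  unann <- setdiff(unique(long$compound_id), ann$compound_id)
  key <- if (level == "target") "targets" else "pathway"
  if (level == "pathway") {
    bad <- is.na(ann$pathway) | ann$pathway == ""
    n_missing_pathway <- sum(bad)
    ann <- ann[!bad, , drop = FALSE]
  } else n_missing_pathway <- 0L
  parts <- strsplit(as.character(ann[[key]]), ";", fixed = TRUE)
  flat <- data.frame(compound_id = rep(ann$compound_id, lengths(parts)),
                     unit = trimws(unlist(parts)),
                     pathway = rep(ann$pathway, lengths(parts)),
                     stringsAsFactors = FALSE)
  flat <- flat[flat$unit != "", , drop = FALSE]
  n_total <- tapply(flat$compound_id, flat$unit,
                    function(z) length(unique(z)))
  hit_flat <- flat[flat$compound_id %in% qualifies, , drop = FALSE]
  n_hit <- tapply(hit_flat$compound_id, factor(hit_flat$unit,
                                               levels = names(n_total)),
                  function(z) length(unique(z)))
  n_hit[is.na(n_hit)] <- 0L
  pw <- flat$pathway[match(names(n_total), flat$unit)]
  tab <- data.frame(target = names(n_total),
                    pathway = if (level == "target") pw else names(n_total),
                    n_drugs_total = as.integer(n_total),
                    n_drugs_hit = as.integer(n_hit),
                    stringsAsFactors = FALSE, row.names = NULL)
  tab$hit_fraction <- tab$n_drugs_hit / tab$n_drugs_total
  tab$passes_filter <- tab$n_drugs_hit >= min_drugs
  tab <- tab[order(-tab$n_drugs_hit, -tab$hit_fraction, tab$target), ]
  rownames(tab) <- NULL
  structure(list(table = tab, level = level, min_drugs = min_drugs,
                 threshold = threshold, op = op,
                 require_lines = require_lines,
                 n_unannotated = length(unann),
                 n_missing_pathway = n_missing_pathway,
                 passing = tab$target[tab$passes_filter]),
            class = "target_rollup")
}

#' @export
print.target_rollup <- function(x, ...) {
  cat(sprintf(
    "Target roll-up (%s level; killing %s %g in %s line(s); pass: >= %d drugs)\n",
    x$level, x$op, x$threshold,
    if (identical(x$require_lines, "all")) "all"
    else if (identical(x$require_lines, "any")) "any"
    else paste(x$require_lines, collapse = "+"),
    x$min_drugs))
  cat(sprintf("  %d %ss; %d pass the filter\n", nrow(x$table), x$level,
              length(x$passing)))
  top <- utils::head(x$table, 8)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-24s %2d / %2d drugs%s\n", top$target[i],
                top$n_drugs_hit[i], top$n_drugs_total[i],
                if (top$passes_filter[i]) "  *" else ""))
  if (x$n_unannotated)
    cat(sprintf("  note: %d screened compound(s) missing from the annotation\n",
                x$n_unannotated))
  invisible(x)
}

#' Compare the passing-target sets of two roll-ups
#'
#' @param rollup_a,rollup_b \code{target_rollup} objects over the same
#'   annotation.
#' @return object of class \code{rollup_comparison} with sorted
#'   \code{both}, \code{only_a}, \code{only_b}, \code{either}.
#' @export
compare_rollups <- function(rollup_a, rollup_b) {
  stopifnot(inherits(rollup_a, "target_rollup"),
            inherits(rollup_b, "target_rollup"))
  a <- rollup_a$passing; b <- rollup_b$passing
  structure(list(both = sort(intersect(a, b)),
                 only_a = sort(setdiff(a, b)),
                 only_b = sort(setdiff(b, a)),
                 either = sort(union(a, b))),
            class = "rollup_comparison")
}

#' @export
print.rollup_comparison <- function(x, ...) {
  cat("Roll-up comparison\n")
  cat("  passing in both:  ", paste(x$both, collapse = ", "), "\n")
  cat("  only in first:    ", paste(x$only_a, collapse = ", "), "\n")
  cat("  only in second:   ", paste(x$only_b, collapse = ", "), "\n")
  invisible(x)
}
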