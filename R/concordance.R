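#' Hierarchically cluster cell lines by drug-response profile
#'
#' Clusters the rows of a killing matrix (euclidean distance on raw
#' percent killing by default, or a correlation distance) with
#' average-linkage agglomeration, cuts the tree at k = 2, and scores how
#' purely that 2-partition separates the species labels.
#'
#' Flagged or missing entries are imputed by the compound's cross-line
#' mean before computing distances; the imputation count is recorded.
#'
#' @param matrix a \code{\link{killing_matrix}} with >= 2 lines and >= 2
#'   compounds.
#' @param metric \code{"euclidean"} (default) or \code{"correlation"}
#'   (1 - Pearson r between profiles).
#' @param linkage \code{"average"} (default) or \code{"complete"}.
#' @return object of class \code{line_clustering}: the \code{hclust}
#'   record, leaf order, k = 2 partition, \code{species_purity} in
#'   [0, 1], and a \code{degenerate} flag when all profiles tie.
#' @export
cluster_cell_lines <- function(matrix, metric = c("euclidean", "correlation"),
                               linkage = c("average", "complete")) {
  stopifnot(inherits(matrix, "killing_matrix"))
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  v <- matrix$values
  if (nrow(v) < 2) stop("need at least 2 cell lines")
  if (ncol(v) < 2) stop("need at least 2 compounds (profile degenerate)")
  n_imputed <- 0L
  if (anyNA(v)) {
    cm <- colMeans(v, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- cm[idx[, 2]]
    n_imputed <- nrow(idx)
    if (anyNA(v)) stop("compound(s) with no observed value in any line")
  }
  d <- switch(metric,
              euclidean = dist(v),
              correlation = as.dist(1 - cor(t(v))))
  degenerate <- max(d) == 0
  hc <- hclust(d, method = linkage)
  part <- cutree(hc, k = 2)
  purity <- species_purity(part, matrix$species)
  structure(list(hclust = hc, merge = hc$merge, heights = hc$height,
                 leaf_order = rownames(v)[hc$order], partition = part,
                 species_purity = purity, metric = metric, linkage = linkage,
                 n_imputed = n_imputed, degenerate = degenerate),
            class = "line_clustering")
}

#' Fraction of lines whose k = 2 clade matches their species
#'
#' Best assignment of the two clusters to the two species labels; 1 means
#' the cut separates species exactly.
#'
#' @param partition integer cluster labels (values 1/2), named by line.
#' @param species character species labels in the same order.
#' @return purity in [0, 1].
#' @export
species_purity <- function(partition, species) {
  stopifnot(length(partition) == length(species))
  sp <- unique(species)
  if (length(sp) != 2) stop("species purity is defined for two species")
  acc <- mean((partition == 1) == (species == sp[1]))
  max(acc, 1 - acc)
}

#' @export
print.line_clustering <- function(x, ...) {
  cat(sprintf("Cell-line clustering (%s distance, %s linkage)\n",
              x$metric, x$linkage))
  cat(sprintf("  %d lines; k=2 species purity: %.3f%s\n",
              length(x$partition), x$species_purity,
              if (x$degenerate) " [degenerate: all profiles identical]" else ""))
  if (x$n_imputed)
    cat(sprintf("  %d flagged/missing entries mean-imputed\n", x$n_imputed))
  invisible(x)
}

#' @export
plot.line_clustering <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = "",
       main = sprintf("Drug-response clustering (purity %.2f)",
                      x$species_purity), ...)
  invisible(x)
}

#' Newick string for a line dendrogram
#'
#' @param x a \code{line_clustering}.
#' @return single Newick string (branch lengths = merge heights).
#' @export
as_newick <- function(x) {
  stopifnot(inherits(x, "line_clustering"))
  ape::write.tree(ape::as.phylo(x$hclust))
}

#' Cross-species concordance of per-compound killing
#'
#' Pearson correlation between the two species' per-compound mean killing
#' (species means when a species has more than one line), with the
#' two-sided t-approximation p-value
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n - 2 df.
#'
#' @param matrix a \code{\link{killing_matrix}} with exactly two species,
#'   or a 2-column numeric matrix/data frame of paired per-compound
#'   values.
#' @return object of class \code{concordance_result}: \code{r},
#'   \code{r_squared}, \code{p_value}, \code{n_compounds}, and the
#'   per-compound scatter table.
#' @export
species_concordance <- function(matrix) {
  if (inherits(matrix, "killing_matrix")) {
    sp <- unique(matrix$species)
    if (length(sp) != 2) stop("exactly two species required")
    v <- matrix$values
    x <- colMeans(v[matrix$species == sp[1], , drop = FALSE], na.rm = TRUE)
    y <- colMeans(v[matrix$species == sp[2], , drop = FALSE], na.rm = TRUE)
    scatter <- data.frame(compound_id = colnames(v), x, y,
                          stringsAsFactors = FALSE, row.names = NULL)
    names(scatter)[2:3] <- paste0("mean_killing_", sp)
  } else {
    m <- as.matrix(matrix)
    if (ncol(m) != 2) stop("need a two-column matrix or a killing_matrix")
    x <- m[, 1]; y <- m[, 2]
    sp <- colnames(m) %||% c("a", "b")
    scatter <- data.frame(compound_id = rownames(m) %||%
                            as.character(seq_along(x)),
                          x, y, stringsAsFactors = FALSE, row.names = NULL)
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 shared compounds")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in a species' killing vector: r undefined")
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), n - 2)
  }
  structure(list(r = r, r_squared = r^2, p_value = p, n_compounds = n,
                 species = sp, scatter = scatter),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Cross-species concordance (%s vs %s, n = %d compounds)\n",
              x$species[1], x$species[2], x$n_compounds))
  cat(sprintf("  r = %.3f, R^2 = %.3f, p %s\n", x$r, x$r_squared,
              if (x$p_value < 1e-4) "< 0.0001" else
                sprintf("= %.4g", x$p_value)))
  invisible(x)
}
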