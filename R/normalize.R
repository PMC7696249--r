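#' Percent killing from treated and control luminescence
#'
#' Defined as \code{100 * (1 - treated / control)}: 0 means no effect,
#' 100 complete killing, negative values growth stimulation (retained,
#' not clipped).
#'
#' @param treated_rlu treated-well luminescence (RLU), vectorized.
#' @param control_center plate control center (RLU), > 0.
#' @return percent killing (percentage points).
#' @export
#' @examples
#' percent_killing(2000, 10000)   # 80
percent_killing <- function(treated_rlu, control_center) {
  if (any(!is.finite(control_center)) || any(control_center <= 0))
    stop("control_center must be > 0 (unusable plate)")
  100 * (1 - treated_rlu / control_center)
}

#' Normalize well luminescence to per-well percent killing
#'
#' Each treated well is normalized against the vehicle-control center
#' (median by default) of its own plate. Blank wells are dropped. Plates
#' without any vehicle controls cannot be normalized: their wells are
#' excluded with a warning and listed in the \code{"excluded_plates"}
#' attribute.
#'
#' @param measurements data frame as produced by
#'   \code{\link{generate_screen}} (or read from the plate-map +
#'   measurement CSVs): columns \code{plate_id}, \code{well}, \code{role},
#'   \code{compound_id}, \code{replicate}, \code{luminescence_rlu},
#'   optionally \code{cell_line} and \code{species}.
#' @param control_stat \code{"median"} (robust to single dead control
#'   wells; default) or \code{"mean"}.
#' @return the treated rows with columns \code{percent_killing} and
#'   \code{control_center} added.
#' @export
normalize_plates <- function(measurements, control_stat = c("median", "mean")) {
  control_stat <- match.arg(control_stat)
  need <- c("plate_id", "role", "luminescence_rlu")
  if (!all(need %in% names(measurements)))
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  ctrl <- measurements[measurements$role == "vehicle_control", ]
  stat_fun <- if (control_stat == "median") median else mean
  centers <- tapply(ctrl$luminescence_rlu, ctrl$plate_id, stat_fun)
  n_ctrl <- tapply(ctrl$luminescence_rlu, ctrl$plate_id, length)
  if (any(n_ctrl < 2))
    warning("plate(s) with fewer than 2 vehicle controls: ",
            paste(names(n_ctrl)[n_ctrl < 2], collapse = ", "))
  treated <- measurements[measurements$role == "treated", ]
  missing_plates <- setdiff(unique(treated$plate_id), names(centers))
  if (length(missing_plates)) {
    warning("excluding plate(s) with no vehicle controls: ",
            paste(missing_plates, collapse = ", "))
    treated <- treated[!treated$plate_id %in% missing_plates, ]
  }
  cc <- as.numeric(centers[treated$plate_id])
  if (any(cc <= 0)) stop("non-positive control center on plate(s): ",
                         paste(unique(treated$plate_id[cc <= 0]), collapse = ", "))
  treated$control_center <- cc
  treated$percent_killing <- percent_killing(treated$luminescence_rlu, cc)
  rownames(treated) <- NULL
  attr(treated, "excluded_plates") <- missing_plates
  attr(treated, "control_stat") <- control_stat
  treated
}

#' Aggregate replicate wells into a killing matrix
#'
#' Averages per-well percent killing over replicates for each
#' (cell line, compound) and flags entries whose replicate luminescence
#' coefficient of variation exceeds \code{cv_threshold} (flag
#' \code{"high_cv"}) or that rest on a single well (flag \code{"n=1"}).
#' Flagged entries are kept, not dropped.
#'
#' @param per_well output of \code{\link{normalize_plates}}; must carry
#'   \code{cell_line}, \code{species}, \code{compound_id},
#'   \code{percent_killing}, \code{luminescence_rlu}.
#' @param cv_threshold replicate CV threshold, percent (default 20).
#' @param clip if \code{TRUE}, clip killing values into [0, 100]
#'   (default \code{FALSE}: stimulation and over-complete killing are
#'   signal, not artifacts).
#' @return A \code{killing_matrix} object.
#' @export
aggregate_replicates <- function(per_well, cv_threshold = 20, clip = FALSE) {
  need <- c("cell_line", "species", "compound_id", "percent_killing",
            "luminescence_rlu")
  if (!all(need %in% names(per_well)))
    stop("per_well must have columns: ", paste(need, collapse = ", "))
  ## sorted orders make the matrix invariant to well shuffling
  lines <- sort(unique(per_well$cell_line))
  species <- per_well$species[match(lines, per_well$cell_line)]
  compounds <- sort(unique(per_well$compound_id))
  li <- match(per_well$cell_line, lines)
  ci <- match(per_well$compound_id, compounds)
  cell <- (ci - 1L) * length(lines) + li
  dims <- c(length(lines), length(compounds))
  n <- matrix(0L, dims[1], dims[2], dimnames = list(lines, compounds))
  tab <- tabulate(cell, nbins = prod(dims))
  n[] <- tab
  sum_k <- matrix(0, dims[1], dims[2], dimnames = list(lines, compounds))
  sum_k[] <- .cell_sum(per_well$percent_killing, cell, prod(dims))
  values <- sum_k / pmax(n, 1L)
  values[n == 0L] <- NA_real_
  ## replicate CV of the raw luminescence
  sum_l <- .cell_sum(per_well$luminescence_rlu, cell, prod(dims))
  sum_l2 <- .cell_sum(per_well$luminescence_rlu^2, cell, prod(dims))
  mean_l <- sum_l / pmax(tab, 1L)
  var_l <- (sum_l2 - tab * mean_l^2) / pmax(tab - 1L, 1L)
  var_l <- pmax(var_l, 0)
  cv <- 100 * sqrt(var_l) / ifelse(mean_l > 0, mean_l, NA_real_)
  flags <- matrix("", dims[1], dims[2], dimnames = list(lines, compounds))
  flags[tab == 1L] <- "n=1"
  hi <- !is.na(cv) & cv > cv_threshold & tab > 1L
  flags[hi] <- "high_cv"
  if (clip) values <- pmin(pmax(values, 0), 100)
  killing_matrix(values, setNames(species, lines), qc_flags = flags,
                 n_reps = n, cv_threshold = cv_threshold, clipped = clip)
}

.cell_sum <- function(x, cell, nbins) {
  rs <- rowsum(x, cell)
  out <- numeric(nbins)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

#' Killing-matrix container
#'
#' The central screen object: percent killing for each cell line (rows)
#' by compound (columns), with a species label per line and per-entry QC
#' flags. Values may fall outside [0, 100] unless clipping was requested
#' at aggregation.
#'
#' @param values numeric matrix, lines x compounds, dimnames set.
#' @param species named character vector (by line name), e.g.
#'   \code{"human"} / \code{"dog"}.
#' @param qc_flags character matrix same shape ("" = clean).
#' @param n_reps integer matrix of replicate counts.
#' @param cv_threshold CV threshold used at aggregation (recorded).
#' @param clipped whether values were clipped into [0, 100].
#' @return object of class \code{killing_matrix}.
#' @export
killing_matrix <- function(values, species, qc_flags = NULL, n_reps = NULL,
                           cv_threshold = NA_real_, clipped = FALSE) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  if (is.null(colnames(values))) {
    if (ncol(values) > 0) stop("values must have compound column names")
    colnames(values) <- character(0)
  }
  if (!all(rownames(values) %in% names(species)))
    stop("species must be named by every cell line")
  if (is.null(qc_flags))
    qc_flags <- matrix("", nrow(values), ncol(values),
                       dimnames = dimnames(values))
  if (is.null(n_reps))
    n_reps <- matrix(1L, nrow(values), ncol(values),
                     dimnames = dimnames(values))
  if (any(is.na(values) & qc_flags == ""))
    stop("NaN/NA killing values must carry a qc flag")
  structure(list(values = values,
                 species = species[rownames(values)],
                 qc_flags = qc_flags, n_reps = n_reps,
                 cv_threshold = cv_threshold, clipped = clipped),
            class = "killing_matrix")
}

#' @export
print.killing_matrix <- function(x, ...) {
  cat(sprintf("Killing matrix: %d cell lines x %d compounds\n",
              nrow(x$values), ncol(x$values)))
  tb <- table(x$species)
  cat("  species:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "),
      "\n")
  cat(sprintf("  killing range: %.1f to %.1f pp; %d flagged entr%s\n",
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
              sum(x$qc_flags != ""),
              if (sum(x$qc_flags != "") == 1) "y" else "ies"))
  invisible(x)
}

#' @export
as.matrix.killing_matrix <- function(x, ...) x$values

#' @export
dim.killing_matrix <- function(x) dim(x$values)

#' One-call screen normalization
#'
#' \code{\link{normalize_plates}} followed by
#' \code{\link{aggregate_replicates}}.
#'
#' @inheritParams normalize_plates
#' @inheritParams aggregate_replicates
#' @return A \code{killing_matrix}.
#' @export
normalize_screen <- function(measurements, control_stat = "median",
                             cv_threshold = 20, clip = FALSE) {
  aggregate_replicates(
    normalize_plates(measurements, control_stat = control_stat),
    cv_threshold = cv_threshold, clip = clip)
}
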