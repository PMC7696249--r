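#' Serial dilution series
#'
#' \code{c_i = start / fold^i}, i = 0..n_points-1; the screening default
#' is four-fold dilutions from 20 micromolar.
#'
#' @param start top concentration (micromolar), > 0.
#' @param fold dilution factor, > 1.
#' @param n_points number of concentrations, >= 2.
#' @return strictly decreasing micromolar vector.
#' @export
#' @examples
#' dilution_series(20, 4, 4)   # 20 5 1.25 0.3125
dilution_series <- function(start = 20, fold = 4, n_points = 8) {
  if (start <= 0) stop("start must be > 0")
  if (fold <= 1) stop("fold must be > 1")
  if (n_points < 2) stop("n_points must be >= 2")
  start / fold^(seq_len(n_points) - 1)
}

#' Four-parameter logistic viability model
#'
#' \code{bottom + (top - bottom) / (1 + (c/ic50)^hill)}: viability
#' decreases from \code{top} (zero dose) to \code{bottom} (saturating
#' dose) with midpoint \code{ic50} and slope \code{hill} > 0.
#'
#' @param conc concentration(s), > 0.
#' @param top,bottom asymptotic viabilities.
#' @param ic50 inflection concentration.
#' @param hill Hill slope (> 0).
#' @return viability at \code{conc}.
#' @export
pl4 <- function(conc, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of \code{\link{pl4}} by Levenberg-Marquardt with
#' multi-start initialization (IC50 starts on a geometric grid over the
#' tested range, Hill starts at 0.5/1/2); the best-RSS start wins. The
#' Hill slope is constrained positive (viability decreasing in dose) by
#' fitting on the log scale. Alongside the relative IC50 (the model
#' inflection), the absolute IC50 (the fitted curve's crossing of 50
#' percent viability) is reported when it exists.
#'
#' @param concentrations micromolar doses (>= 4 distinct values);
#'   replicates allowed.
#' @param viabilities percent viability, same length.
#' @return object of class \code{fourpl} with coefficients \code{top},
#'   \code{bottom}, \code{ic50}, \code{hill}, the residual sum of squares,
#'   \code{converged}, \code{ic50_in_range} and \code{ic50_abs}.
#'   Non-convergence is flagged, never silent: the best-effort parameters
#'   are returned with \code{converged = FALSE}.
#' @export
fit_4pl <- function(concentrations, viabilities) {
  conc <- as.numeric(concentrations)
  v <- as.numeric(viabilities)
  stopifnot(length(conc) == length(v))
  keep <- is.finite(conc) & is.finite(v)
  conc <- conc[keep]; v <- v[keep]
  if (any(conc <= 0)) stop("concentrations must be > 0")
  if (length(unique(conc)) < 4)
    stop("need at least 4 distinct concentrations")
  dat <- data.frame(lc = log(conc), v = v)
  top0 <- max(v); bot0 <- min(v)
  ic_grid <- exp(seq(log(min(conc)), log(max(conc)), length.out = 5))
  starts <- expand.grid(lic = log(ic_grid), lh = log(c(0.5, 1, 2)))
  best <- NULL; best_rss <- Inf
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ bot + (top - bot) / (1 + exp(exp(lh) * (lc - lic))),
        data = dat,
        start = list(top = top0, bot = bot0,
                     lic = starts$lic[s], lh = starts$lh[s]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.finite(rss) && rss < best_rss) { best <- fit; best_rss <- rss }
  }
  if (is.null(best)) {
    cf <- c(top = top0, bottom = bot0, ic50 = exp(mean(log(conc))), hill = 1)
    return(.new_fourpl(cf, conc, v, rss = sum((v - mean(v))^2),
                       converged = FALSE))
  }
  p <- coef(best)
  cf <- c(top = unname(p["top"]), bottom = unname(p["bot"]),
          ic50 = exp(unname(p["lic"])), hill = exp(unname(p["lh"])))
  ## canonicalize: top is the low-dose asymptote
  if (cf["bottom"] > cf["top"]) {
    cf[c("top", "bottom")] <- cf[c("bottom", "top")]
  }
  conv <- is.null(best$convInfo) || isTRUE(best$convInfo$isConv)
  .new_fourpl(cf, conc, v, rss = best_rss, converged = conv)
}

.new_fourpl <- function(cf, conc, v, rss, converged) {
  in_range <- cf["ic50"] >= min(conc) && cf["ic50"] <= max(conc)
  ## flat response: no identifiable dose effect, flag the IC50 as unusable
  if (abs(cf["top"] - cf["bottom"]) < 1e-6 * (diff(range(v)) + 1))
    in_range <- FALSE
  ic50_abs <- NA_real_
  if (cf["top"] > 50 && cf["bottom"] < 50)
    ic50_abs <- unname(cf["ic50"] *
                         ((cf["top"] - 50) / (50 - cf["bottom"]))^(1 / cf["hill"]))
  structure(list(coefficients = cf, rss = unname(rss),
                 converged = converged,
                 ic50_in_range = unname(in_range), ic50_abs = ic50_abs,
                 data = data.frame(concentration_um = conc,
                                   viability_pct = v),
                 n = length(v)),
            class = "fourpl")
}

#' @export
print.fourpl <- function(x, ...) {
  cf <- x$coefficients
  cat("Four-parameter logistic dose-response fit\n")
  cat(sprintf("  top %.2f%%  bottom %.2f%%  IC50 %.4g uM  hill %.3f\n",
              cf["top"], cf["bottom"], cf["ic50"], cf["hill"]))
  cat(sprintf("  RSS %.4g on %d points%s%s\n", x$rss, x$n,
              if (!x$converged) "  [NOT CONVERGED]" else "",
              if (!x$ic50_in_range) "  [IC50 outside tested range]" else ""))
  if (is.finite(x$ic50_abs))
    cat(sprintf("  absolute IC50 (50%% viability crossing): %.4g uM\n",
                x$ic50_abs))
  invisible(x)
}

#' @export
coef.fourpl <- function(object, ...) object$coefficients

#' @export
predict.fourpl <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$concentration_um
          else if (is.data.frame(newdata)) newdata$concentration_um
          else as.numeric(newdata)
  cf <- object$coefficients
  pl4(conc, cf["top"], cf["bottom"], cf["ic50"], cf["hill"])
}

#' @export
fitted.fourpl <- function(object, ...) predict(object)

#' @export
residuals.fourpl <- function(object, ...)
  object$data$viability_pct - fitted(object)

#' @export
summary.fourpl <- function(object, ...) {
  print(object)
  invisible(data.frame(t(object$coefficients), rss = object$rss,
                       converged = object$converged,
                       ic50_in_range = object$ic50_in_range,
                       ic50_abs = object$ic50_abs))
}

#' @export
plot.fourpl <- function(x, ...) {
  d <- x$data
  cf <- x$coefficients
  grid <- exp(seq(log(min(d$concentration_um)), log(max(d$concentration_um)),
                  length.out = 100))
  plot(d$concentration_um, d$viability_pct, log = "x",
       xlab = "concentration (uM)", ylab = "viability (%)", pch = 19, ...)
  lines(grid, pl4(grid, cf["top"], cf["bottom"], cf["ic50"], cf["hill"]))
  abline(v = cf["ic50"], lty = 2)
  invisible(x)
}

#' Combination-grid container
#'
#' Fractional-inhibition checkerboard for a drug pair. The first row and
#' column are the zero-dose margins carrying the single-agent effects.
#'
#' @param doses_a,doses_b dose vectors including the leading 0.
#' @param observed inhibition matrix (fractions), doses_a x doses_b,
#'   margins included.
#' @return object of class \code{combination_grid}.
#' @export
combination_grid <- function(doses_a, doses_b, observed) {
  stopifnot(is.matrix(observed),
            nrow(observed) == length(doses_a),
            ncol(observed) == length(doses_b))
  if (doses_a[1] != 0 || doses_b[1] != 0)
    stop("zero-dose margins required: doses must start at 0")
  structure(list(doses_a = doses_a, doses_b = doses_b, observed = observed,
                 bliss_expected = NULL, excess = NULL,
                 summary_excess = NA_real_),
            class = "combination_grid")
}

#' Bliss-excess synergy surface
#'
#' Under Bliss independence two non-interacting drugs with fractional
#' inhibitions Ea and Eb combine to \code{Ea + Eb - Ea*Eb}. The excess
#' surface is observed minus expected; positive interior excess indicates
#' synergy. Single-agent effects are taken from the grid's zero-dose row
#' and column. \code{summary_excess} is the mean over interior cells.
#'
#' @param grid a \code{\link{combination_grid}}, or a data frame with
#'   columns \code{dose_a}, \code{dose_b}, \code{inhibition} containing
#'   the zero-dose margins.
#' @return the grid with \code{bliss_expected}, \code{excess} and
#'   \code{summary_excess} filled in. Inhibitions outside [0, 1] are
#'   clipped with a warning.
#' @export
bliss_excess <- function(grid) {
  if (is.data.frame(grid)) grid <- .grid_from_long(grid)
  stopifnot(inherits(grid, "combination_grid"))
  obs <- grid$observed
  if (any(obs < 0 | obs > 1)) {
    warning("inhibition values outside [0, 1] clipped")
    obs <- pmin(pmax(obs, 0), 1)
  }
  ea <- obs[, 1]   # single-agent A (dose_b = 0 column)
  eb <- obs[1, ]   # single-agent B (dose_a = 0 row)
  expected <- outer(ea, eb, function(a, b) a + b - a * b)
  excess <- obs - expected
  grid$observed <- obs
  grid$bliss_expected <- expected
  grid$excess <- excess
  grid$summary_excess <- mean(excess[-1, -1])
  grid
}

.grid_from_long <- function(df) {
  stopifnot(all(c("dose_a", "dose_b", "inhibition") %in% names(df)))
  da <- sort(unique(df$dose_a)); db <- sort(unique(df$dose_b))
  if (da[1] != 0 || db[1] != 0)
    stop("zero-dose single-agent rows/columns are required")
  m <- matrix(NA_real_, length(da), length(db))
  m[cbind(match(df$dose_a, da), match(df$dose_b, db))] <- df$inhibition
  if (anyNA(m)) stop("incomplete checkerboard: missing dose combinations")
  combination_grid(da, db, m)
}

#' @export
print.combination_grid <- function(x, ...) {
  cat(sprintf("Combination grid: %d x %d doses (zero margins included)\n",
              length(x$doses_a), length(x$doses_b)))
  if (!is.null(x$excess))
    cat(sprintf("  mean interior Bliss excess: %+.4f %s\n", x$summary_excess,
                if (x$summary_excess > 0.05) "(synergy)"
                else if (x$summary_excess < -0.05) "(antagonism)"
                else "(additive)"))
  invisible(x)
}

#' @export
plot.combination_grid <- function(x, ...) {
  z <- if (!is.null(x$excess)) x$excess else x$observed
  image(seq_along(x$doses_a), seq_along(x$doses_b), z,
        xlab = "dose A index", ylab = "dose B index",
        main = if (!is.null(x$excess)) "Bliss excess" else "Observed inhibition",
        ...)
  invisible(x)
}

#' Doubling time from a growth curve
#'
#' Log-linear least squares of \code{ln(abundance)} on time;
#' \code{Td = ln(2) / slope}. A zero slope yields \code{Inf}; a negative
#' slope (shrinking culture) yields a negative value with attribute
#' \code{declining = TRUE}.
#'
#' @param times hours (>= 3 points).
#' @param abundances cell counts or confluence, > 0.
#' @return doubling time in hours, with attributes \code{slope} and
#'   \code{r_squared}.
#' @export
#' @examples
#' doubling_time(c(0, 24, 48, 72), 1000 * 2^(c(0, 24, 48, 72) / 24))  # 24
doubling_time <- function(times, abundances) {
  stopifnot(length(times) == length(abundances))
  if (length(times) < 3) stop("need at least 3 time points")
  if (any(abundances <= 0)) stop("abundances must be > 0")
  fit <- lm(log(abundances) ~ times)
  slope <- unname(coef(fit)[2])
  ## constant cultures give a numerically-zero slope
  if (abs(slope) < 1e-12 / diff(range(times))) slope <- 0
  td <- if (slope == 0) Inf else log(2) / slope
  tss <- sum((log(abundances) - mean(log(abundances)))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(residuals(fit)^2) / tss
  attr(td, "slope") <- slope
  attr(td, "r_squared") <- r2
  if (slope < 0) attr(td, "declining") <- TRUE
  td
}
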