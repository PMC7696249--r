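#' Simulate a four-parameter logistic dilution series
#'
#' Expected viability at concentration c is
#' \code{bottom + (top - bottom) / (1 + (c/ic50)^hill)}, the same model
#' \code{\link{fit_4pl}} fits, with i.i.d. Gaussian noise added per well.
#'
#' @param true_top,true_bottom asymptotic viabilities (percent).
#' @param true_ic50 inflection concentration (micromolar), > 0.
#' @param true_hill Hill slope, > 0.
#' @param concentrations micromolar doses (strictly positive); default the
#'   8-point 4-fold series from 20 uM.
#' @param noise_sd response noise sd (percent viability).
#' @param n_reps replicate wells per concentration.
#' @param seed integer seed.
#' @return data frame: \code{concentration_um}, \code{replicate},
#'   \code{viability_pct}.
#' @export
generate_dose_response <- function(true_top = 100, true_bottom = 0,
                                   true_ic50 = 1.25, true_hill = 1,
                                   concentrations = dilution_series(20, 4, 8),
                                   noise_sd = 0, n_reps = 1, seed = 1L) {
  if (true_ic50 <= 0) stop("true_ic50 must be > 0")
  if (true_hill <= 0) stop("true_hill must be > 0")
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  set.seed(as.integer(seed))
  conc <- rep(concentrations, each = n_reps)
  mu <- pl4(conc, true_top, true_bottom, true_ic50, true_hill)
  v <- mu + if (noise_sd > 0) rnorm(length(mu), 0, noise_sd) else 0
  data.frame(concentration_um = conc,
             replicate = rep(seq_len(n_reps), times = length(concentrations)),
             viability_pct = v)
}

#' Simulate a drug-combination checkerboard with planted Bliss excess
#'
#' The expected observed fractional inhibition at dose pair (i, j) is the
#' Bliss-independence expectation \code{Ea + Eb - Ea*Eb} plus the planted
#' excess, clipped to [0, 1] (clipping is counted in the
#' \code{"n_clipped_expectation"} attribute). Zero-dose margins carry the
#' single-agent effects, as \code{\link{bliss_excess}} requires.
#'
#' @param effect_a,effect_b single-agent fractional inhibition at each
#'   non-zero dose of drugs A and B (values in [0, 1]).
#' @param planted_excess scalar or matrix (length(effect_a) x
#'   length(effect_b)) of planted synergy (positive) or antagonism.
#' @param noise_sd Gaussian noise sd on the inhibition fraction.
#' @param doses_a,doses_b optional dose labels (micromolar) for the
#'   non-zero doses.
#' @param seed integer seed.
#' @return A \code{\link{combination_grid}} with observed inhibition
#'   (margins included) and the planted excess stored in
#'   \code{$planted_excess}.
#' @export
generate_combination_grid <- function(effect_a, effect_b, planted_excess = 0,
                                      noise_sd = 0, doses_a = NULL,
                                      doses_b = NULL, seed = 1L) {
  if (any(effect_a < 0 | effect_a > 1) || any(effect_b < 0 | effect_b > 1))
    stop("single-agent effects must be fractions in [0, 1]")
  na <- length(effect_a); nb <- length(effect_b)
  if (is.matrix(planted_excess)) {
    if (!all(dim(planted_excess) == c(na, nb)))
      stop("planted_excess matrix shape must match effect vectors")
    ex <- planted_excess
  } else ex <- matrix(planted_excess, na, nb)
  set.seed(as.integer(seed))
  if (is.null(doses_a)) doses_a <- seq_len(na)
  if (is.null(doses_b)) doses_b <- seq_len(nb)
  interior <- outer(effect_a, effect_b, function(a, b) a + b - a * b) + ex
  n_clip <- sum(interior < 0 | interior > 1)
  interior <- pmin(pmax(interior, 0), 1)
  obs <- matrix(0, na + 1L, nb + 1L)
  obs[1, -1] <- effect_b
  obs[-1, 1] <- effect_a
  obs[-1, -1] <- interior
  if (noise_sd > 0)
    obs <- pmin(pmax(obs + rnorm(length(obs), 0, noise_sd), 0), 1)
  g <- combination_grid(c(0, doses_a), c(0, doses_b), obs)
  g$planted_excess <- ex
  if (n_clip) {
    warning(n_clip, " expectation cell(s) clipped to [0, 1]")
    attr(g, "n_clipped_expectation") <- n_clip
  }
  g
}

#' Simulate a caliper-measured xenograft growth study
#'
#' Each mouse's underlying tumor volume follows
#' \code{v0 * exp(rate * day)} with additive Gaussian noise (floored at a
#' small positive volume). Volumes are emitted as caliper length/width
#' pairs with a fixed per-mouse aspect ratio, satisfying
#' \code{(length * width^2) / 2 = volume} exactly.
#'
#' @param groups data frame with columns \code{name}, \code{n_mice},
#'   \code{rate} (per-day exponential growth rate; negative allowed), or a
#'   list of 3-element lists.
#' @param v0 volume at day 0 (cubic mm).
#' @param measure_days measurement days; default a thrice-weekly schedule
#'   through day 18.
#' @param noise_sd additive volume noise sd (cubic mm).
#' @param seed integer seed.
#' @return data frame: \code{mouse_id}, \code{group}, \code{day},
#'   \code{length_mm}, \code{width_mm}.
#' @export
generate_tumor_study <- function(groups, v0 = 150,
                                 measure_days = c(0, 2, 4, 7, 9, 11, 14, 16, 18),
                                 noise_sd = 0, seed = 1L) {
  if (!is.data.frame(groups))
    groups <- do.call(rbind, lapply(groups, function(g) {
      g <- as.list(g)
      names(g) <- c("name", "n_mice", "rate")[seq_along(g)]
      data.frame(name = as.character(g$name), n_mice = as.integer(g$n_mice),
                 rate = as.numeric(g$rate), stringsAsFactors = FALSE)
    }))
  if (any(groups$n_mice < 1)) stop("each group needs at least one mouse")
  if (v0 <= 0) stop("v0 must be > 0")
  set.seed(as.integer(seed))
  rows <- list()
  mouse_no <- 0L
  for (gi in seq_len(nrow(groups))) {
    for (m in seq_len(groups$n_mice[gi])) {
      mouse_no <- mouse_no + 1L
      vol <- v0 * exp(groups$rate[gi] * measure_days)
      if (noise_sd > 0) vol <- vol + rnorm(length(vol), 0, noise_sd)
      vol <- pmax(vol, 0.5)
      rho <- runif(1, 1.15, 1.6)          # length/width aspect ratio
      w <- (2 * vol / rho)^(1 / 3)
      rows[[mouse_no]] <- data.frame(
        mouse_id = sprintf("M%03d", mouse_no),
        group = groups$name[gi], day = measure_days,
        length_mm = rho * w, width_mm = w, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a two-hazard survival cohort split by marker expression
#'
#' Subjects with expression above \code{cutoff} draw exponential event
#' times at \code{hazard_high}; the rest at \code{hazard_low}. A fraction
#' \code{censor_rate} of subjects is censored at a uniform time before
#' their event.
#'
#' @param n cohort size (>= 4; the cutoff scan is undefined below that).
#' @param cutoff expression threshold separating the two hazard groups.
#' @param hazard_low,hazard_high exponential hazards (> 0) for subjects
#'   below / above the cutoff.
#' @param censor_rate probability a subject is censored, in [0, 1).
#' @param expression_range uniform range the marker is drawn from.
#' @param seed integer seed.
#' @return data frame: \code{subject}, \code{expression}, \code{time},
#'   \code{event} (1 observed, 0 censored).
#' @export
generate_survival_cohort <- function(n, cutoff = 5, hazard_low = 0.05,
                                     hazard_high = 0.2, censor_rate = 0,
                                     expression_range = c(0, 10), seed = 1L) {
  if (n < 4) stop("n must be >= 4 (cutoff scan undefined)")
  if (hazard_low <= 0 || hazard_high <= 0) stop("hazards must be > 0")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)")
  set.seed(as.integer(seed))
  expr <- runif(n, expression_range[1], expression_range[2])
  hz <- ifelse(expr > cutoff, hazard_high, hazard_low)
  t_event <- rexp(n, hz)
  event <- rbinom(n, 1, 1 - censor_rate)
  time <- ifelse(event == 1, t_event, runif(n, 0, 1) * t_event)
  data.frame(subject = sprintf("S%04d", seq_len(n)), expression = expr,
             time = time, event = event)
}
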