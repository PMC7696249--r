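#' Standard cell-line panels
#'
#' Convenience constructors for the two panels the pipeline emulates: the
#' nine-line osteosarcoma panel (five human, four dog) used for the
#' 119-compound oncology screen, and the two-line low-passage PDX-derived
#' pair (17-3X human, D418 dog) used for the 2100-compound bioactives
#' screen.
#'
#' @return A data frame with columns \code{name} and \code{species}
#'   (\code{"human"} or \code{"dog"}).
#' @export
nine_line_panel <- function() {
  data.frame(
    name = c("143B", "MG63", "SAOS", "U2OS", "17-3X",
             "Abrams", "Moresco", "D17", "D418"),
    species = c(rep("human", 5), rep("dog", 4)),
    stringsAsFactors = FALSE
  )
}

#' @rdname nine_line_panel
#' @export
two_line_panel <- function() {
  data.frame(name = c("17-3X", "D418"),
             species = c("human", "dog"),
             stringsAsFactors = FALSE)
}

#' Construct a screen ground-truth object
#'
#' A \code{screen_truth} holds the per-(cell line, compound) expected
#' percent killing that the synthetic plate generator emits, decomposed
#' into a shared compound effect, additive per-(species, compound)
#' offsets, and per-(line, compound) offsets, plus the well-level noise
#' standard deviation. The invariant
#' \code{true_killing = compound_effects + species_offsets + line_offsets}
#' holds exactly.
#'
#' @param true_killing numeric matrix, cell lines in rows, compounds in
#'   columns (dimnames required).
#' @param cell_lines data frame with \code{name}, \code{species}; row order
#'   must match \code{true_killing}.
#' @param compound_effects per-compound shared mean killing (percentage
#'   points); recycled/derived if \code{NULL}.
#' @param species_offsets matrix species x compounds, or \code{NULL}.
#' @param noise_sd well-level residual standard deviation, in percentage
#'   points of killing.
#' @param driver_targets character vector of targets planted as
#'   multi-drug-sensitive.
#' @param sensitive_compounds named list, target -> compound ids planted as
#'   sensitive in all lines.
#' @param seed integer seed recorded for provenance.
#' @return An object of class \code{screen_truth}.
#' @export
screen_truth <- function(true_killing, cell_lines, noise_sd,
                         compound_effects = NULL, species_offsets = NULL,
                         driver_targets = character(),
                         sensitive_compounds = list(), seed = NA_integer_) {
  stopifnot(is.matrix(true_killing), nrow(true_killing) == nrow(cell_lines))
  if (is.null(rownames(true_killing)))
    rownames(true_killing) <- cell_lines$name
  if (is.null(colnames(true_killing)))
    stop("true_killing must have compound ids as column names")
  if (!all(is.finite(true_killing)))
    stop("true killing expectations must be finite")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(compound_effects))
    compound_effects <- colMeans(true_killing)
  if (is.null(species_offsets)) {
    sp <- unique(cell_lines$species)
    species_offsets <- matrix(0, length(sp), ncol(true_killing),
                              dimnames = list(sp, colnames(true_killing)))
    for (s in sp) {
      rows <- cell_lines$species == s
      species_offsets[s, ] <- colMeans(true_killing[rows, , drop = FALSE]) -
        compound_effects
    }
  }
  line_offsets <- true_killing -
    matrix(compound_effects, nrow(true_killing), ncol(true_killing),
           byrow = TRUE) -
    species_offsets[cell_lines$species, , drop = FALSE]
  structure(list(
    true_killing = true_killing,
    cell_lines = cell_lines,
    compound_effects = compound_effects,
    species_offsets = species_offsets,
    line_offsets = line_offsets,
    noise_sd = noise_sd,
    driver_targets = driver_targets,
    sensitive_compounds = sensitive_compounds,
    seed = seed
  ), class = "screen_truth")
}

#' @export
print.screen_truth <- function(x, ...) {
  cat("Synthetic screen truth\n")
  cat(sprintf("  %d cell lines (%s), %d compounds\n",
              nrow(x$cell_lines),
              paste(sprintf("%d %s", table(x$cell_lines$species),
                            names(table(x$cell_lines$species))),
                    collapse = ", "),
              ncol(x$true_killing)))
  cat(sprintf("  well noise sd: %.1f pp; seed: %s\n", x$noise_sd,
              format(x$seed)))
  if (length(x$driver_targets))
    cat("  planted driver targets:",
        paste(x$driver_targets, collapse = ", "), "\n")
  invisible(x)
}

#' Generate an annotated compound library with planted driver targets
#'
#' Builds a compound annotation table (compound -> target, pathway) and the
#' matching \code{\link{screen_truth}}. Background compounds draw their
#' expected killing from a shared + species + line additive model; no
#' background compound exceeds 50 percent killing in every line (its
#' minimum over lines is capped at \code{background_cap}), so multi-line
#' sensitivity exists only where planted. Driver targets are planted via
#' \code{driver_spec}: for each, \code{n_sensitive} of its \code{n_drugs}
#' drugs kill > 50 percent in all lines and the rest stay below 50 in all
#' lines. Optionally the per-line hit counts (compounds with expected
#' killing > 50 in that line) are forced to exact values to emulate the
#' per-line hit fractions seen in real screens.
#'
#' @param n_targets number of background targets in the annotation.
#' @param n_compounds total library size (background + driver drugs).
#' @param driver_spec list of \code{list(target=, n_drugs=, n_sensitive=)}.
#' @param cell_lines panel data frame (\code{name}, \code{species}).
#' @param seed integer; all randomness flows from it.
#' @param mean_kill,shared_sd background shared-effect mean and sd (pp).
#' @param species_sd,line_sd additive offset sds (pp).
#' @param noise_sd well-level noise sd recorded into the truth (pp).
#' @param line_hit_counts optional named integer vector (per line name):
#'   exact number of compounds with expected killing > 50 in that line.
#'   Forced single-line hits are disjoint across lines so the background
#'   cap is preserved.
#' @param background_cap ceiling on a background compound's minimum
#'   expected killing over lines (default 45 pp).
#' @param super_killers number of planted pan-line near-complete killers
#'   (expected killing > 95 in every line; exempt from the cap). Emulates
#'   the screen's strongest proteasome inhibitors.
#' @return list with \code{annotation} (data frame: compound_id, name,
#'   targets, pathway) and \code{truth} (\code{screen_truth}).
#' @export
generate_compound_library <- function(n_targets = 200, n_compounds = 2100,
                                      driver_spec = list(),
                                      cell_lines = two_line_panel(),
                                      seed = 1L,
                                      mean_kill = 18, shared_sd = 18,
                                      species_sd = 10, line_sd = 5,
                                      noise_sd = 8,
                                      line_hit_counts = NULL,
                                      background_cap = 45,
                                      super_killers = 0) {
  stopifnot(n_targets >= 1, n_compounds >= 1)
  drv <- .as_driver_spec(driver_spec)
  if (anyDuplicated(drv$target))
    stop("duplicate target names in driver_spec: ",
         paste(unique(drv$target[duplicated(drv$target)]), collapse = ", "))
  if (any(drv$n_sensitive > drv$n_drugs))
    stop("driver_spec: n_sensitive must be <= n_drugs")
  n_driver <- sum(drv$n_drugs)
  n_bg <- n_compounds - n_driver - super_killers
  if (n_bg < 0)
    stop("driver drugs plus super killers exceed n_compounds")

  set.seed(as.integer(seed))
  nl <- nrow(cell_lines)
  ids <- sprintf("CPD%05d", seq_len(n_compounds))
  nms <- sprintf("compound_%05d", seq_len(n_compounds))

  ## background additive model
  mu <- rnorm(n_compounds, mean_kill, shared_sd)
  sp <- unique(cell_lines$species)
  a <- matrix(rnorm(length(sp) * n_compounds, 0, species_sd),
              length(sp), n_compounds, dimnames = list(sp, ids))
  b <- matrix(rnorm(nl * n_compounds, 0, line_sd), nl, n_compounds,
              dimnames = list(cell_lines$name, ids))
  kill <- matrix(mu, nl, n_compounds, byrow = TRUE) +
    a[cell_lines$species, , drop = FALSE] + b
  dimnames(kill) <- list(cell_lines$name, ids)

  ## partition compounds: drivers first, then supers, then background
  idx <- seq_len(n_compounds)
  drv_idx <- if (n_driver) idx[seq_len(n_driver)] else integer()
  sup_idx <- if (super_killers) idx[n_driver + seq_len(super_killers)] else integer()
  bg_idx <- setdiff(idx, c(drv_idx, sup_idx))

  ## plant drivers
  sensitive <- list()
  targets <- character(n_compounds)
  pos <- 0L
  for (k in seq_along(drv$target)) {
    tg <- drv$target[k]
    these <- drv_idx[pos + seq_len(drv$n_drugs[k])]
    pos <- pos + drv$n_drugs[k]
    targets[these] <- tg
    sens <- these[seq_len(drv$n_sensitive[k])]
    for (j in sens)
      kill[, j] <- runif(1, 65, 90) + runif(nl, -4, 4)
    for (j in setdiff(these, sens))
      kill[, j] <- runif(1, 15, 38) + runif(nl, -4, 4)
    sensitive[[tg]] <- ids[sens]
  }

  ## plant pan-line near-complete killers
  for (j in sup_idx)
    kill[, j] <- runif(1, 96.5, 99.5) + runif(nl, -0.8, 0.8)
  if (super_killers)
    targets[sup_idx] <- sprintf("T%03d", sample.int(n_targets, super_killers,
                                                    replace = TRUE))

  ## cap background compounds: min over lines <= background_cap
  if (length(bg_idx)) {
    mins <- apply(kill[, bg_idx, drop = FALSE], 2, min)
    over <- which(mins > background_cap)
    if (length(over)) {
      shift <- mins[over] - (background_cap - runif(length(over), 0, 5))
      kill[, bg_idx[over]] <- sweep(kill[, bg_idx[over], drop = FALSE], 2,
                                    shift, "-")
    }
    targets[bg_idx] <- sprintf("T%03d", sample.int(n_targets, length(bg_idx),
                                                   replace = TRUE))
  }

  ## force exact per-line hit counts among background compounds
  if (!is.null(line_hit_counts)) {
    if (is.null(names(line_hit_counts)) ||
        !all(names(line_hit_counts) %in% cell_lines$name))
      stop("line_hit_counts must be named by cell line")
    reserved <- integer()   # background compounds already forced in a line
    for (ln in names(line_hit_counts)) {
      want <- line_hit_counts[[ln]]
      fixed_hits <- sum(kill[ln, c(drv_idx, sup_idx)] > 50)
      need <- want - fixed_hits
      if (need < 0)
        stop("line_hit_counts[", ln, "] below planted driver hits")
      cur <- bg_idx[kill[ln, bg_idx] > 50]
      ## background hits forced for another line stay put; adjust the rest
      cur_free <- setdiff(cur, reserved)
      n_have <- length(intersect(cur, reserved)) + length(cur_free)
      if (n_have > need) {
        ## demote the weakest surplus free hits to just under 50
        drop_n <- n_have - need
        ord <- cur_free[order(kill[ln, cur_free])]
        dem <- ord[seq_len(min(drop_n, length(ord)))]
        kill[ln, dem] <- 50 - runif(length(dem), 2, 8)
      } else if (n_have < need) {
        ## promote the strongest eligible non-hits (not forced elsewhere,
        ## not a hit in any other line - keeps the cap invariant)
        other <- setdiff(rownames(kill), ln)
        elig <- setdiff(bg_idx, c(reserved, cur))
        if (length(other))
          elig <- elig[apply(kill[other, elig, drop = FALSE] > 50, 2, sum) == 0]
        elig <- elig[order(kill[ln, elig], decreasing = TRUE)]
        pro <- elig[seq_len(need - n_have)]
        kill[ln, pro] <- 50 + runif(length(pro), 4, 40)
        reserved <- c(reserved, pro)
      }
      reserved <- union(reserved, bg_idx[kill[ln, bg_idx] > 50])
    }
  }

  pathway <- paste0("PW", formatC(
    (as.integer(factor(targets, levels = unique(targets))) - 1L) %/% 8L + 1L,
    width = 2, flag = "0"))
  pathway[targets %in% drv$target] <-
    paste0(targets[targets %in% drv$target], "_pathway")

  annotation <- data.frame(compound_id = ids, name = nms, targets = targets,
                           pathway = pathway, stringsAsFactors = FALSE)
  truth <- screen_truth(kill, cell_lines, noise_sd,
                        compound_effects = colMeans(kill),
                        driver_targets = drv$target,
                        sensitive_compounds = sensitive,
                        seed = as.integer(seed))
  list(annotation = annotation, truth = truth)
}

.as_driver_spec <- function(driver_spec) {
  if (is.data.frame(driver_spec))
    return(data.frame(target = as.character(driver_spec$target),
                      n_drugs = as.integer(driver_spec$n_drugs),
                      n_sensitive = as.integer(driver_spec$n_sensitive),
                      stringsAsFactors = FALSE))
  if (!length(driver_spec))
    return(data.frame(target = character(), n_drugs = integer(),
                      n_sensitive = integer(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(driver_spec, function(d) {
    d <- as.list(d)
    names(d) <- c("target", "n_drugs", "n_sensitive")[seq_along(d)]
    data.frame(target = as.character(d$target),
               n_drugs = as.integer(d$n_drugs),
               n_sensitive = as.integer(d$n_sensitive),
               stringsAsFactors = FALSE)
  }))
}

#' Ground truth with a planted cross-species concordance
#'
#' Builds a \code{screen_truth} whose per-compound species-mean killing
#' values have a planted squared Pearson correlation (R squared) between
#' the two species, once well noise averaged over replicates is accounted
#' for. The shared compound effect's variance fraction is set to
#' \code{sqrt(target_r2)} of the total per-species-mean variance, which
#' makes the expected correlation \code{sqrt(target_r2)} and hence the
#' expected R squared equal to \code{target_r2}.
#'
#' @param target_r2 planted R squared between species-mean killing vectors.
#' @param n_compounds library size.
#' @param cell_lines panel (exactly two species).
#' @param total_sd total sd of a species-mean killing value (pp).
#' @param line_sd,noise_sd per-line offset and well-noise sds (pp).
#' @param n_replicates wells per (line, compound), used to account for
#'   noise averaging.
#' @param mean_kill overall mean killing (pp).
#' @param seed integer seed.
#' @return A \code{screen_truth}.
#' @export
screen_truth_concordant <- function(target_r2 = 0.54, n_compounds = 2100,
                                    cell_lines = two_line_panel(),
                                    total_sd = 25, line_sd = 0, noise_sd = 8,
                                    n_replicates = 3, mean_kill = 20,
                                    seed = 1L) {
  stopifnot(target_r2 > 0, target_r2 < 1)
  sp <- unique(cell_lines$species)
  if (length(sp) != 2) stop("exactly two species required")
  set.seed(as.integer(seed))
  n_per <- table(factor(cell_lines$species, levels = sp))
  r <- sqrt(target_r2)
  tot_var <- total_sd^2
  shared_var <- r * tot_var
  ## species-mean residual variance: species offset + averaged line/noise
  resid_var <- tot_var - shared_var
  meas_var <- (line_sd^2 + noise_sd^2 / n_replicates) / as.numeric(n_per)
  species_var <- resid_var - meas_var      # one value per species
  if (any(species_var < 0))
    stop("total_sd too small for the requested noise/line structure")
  ids <- sprintf("CPD%05d", seq_len(n_compounds))
  mu <- rnorm(n_compounds, mean_kill, sqrt(shared_var))
  a <- rbind(rnorm(n_compounds, 0, sqrt(species_var[1])),
             rnorm(n_compounds, 0, sqrt(species_var[2])))
  dimnames(a) <- list(sp, ids)
  nl <- nrow(cell_lines)
  b <- matrix(rnorm(nl * n_compounds, 0, line_sd), nl, n_compounds,
              dimnames = list(cell_lines$name, ids))
  kill <- matrix(mu, nl, n_compounds, byrow = TRUE) +
    a[cell_lines$species, , drop = FALSE] + b
  dimnames(kill) <- list(cell_lines$name, ids)
  screen_truth(kill, cell_lines, noise_sd, compound_effects = mu,
               species_offsets = a, seed = as.integer(seed))
}

#' Simulate well-level plate measurements from a screen truth
#'
#' Lays compounds out in replicate wells across 384- or 96-well plates
#' (vehicle-control wells occupy fixed outer columns), draws a per-plate
#' control luminescence level log-normally around \code{control_level},
#' and emits raw luminescence
#' \code{level * (1 - true_killing/100) + level * noise_sd/100 * N(0,1)}.
#' Negative luminescence after noise is clipped at 0 and counted in the
#' \code{"n_clipped"} attribute.
#'
#' @param truth a \code{\link{screen_truth}}.
#' @param n_replicates treated wells per (line, compound).
#' @param control_wells_per_plate minimum vehicle wells per plate; whole
#'   outer columns are reserved so the actual count can be larger.
#' @param plate_size 384 or 96.
#' @param seed integer seed.
#' @param control_level median per-plate control luminescence (RLU).
#' @param control_level_sdlog log-sd of the per-plate level.
#' @param edge_effects if \code{TRUE}, signal in edge wells is attenuated
#'   by \code{edge_loss} (off by default).
#' @param edge_loss fractional signal loss in edge wells.
#' @return data frame with columns \code{cell_line}, \code{species},
#'   \code{plate_id}, \code{well}, \code{role}, \code{compound_id},
#'   \code{replicate}, \code{luminescence_rlu}.
#' @export
generate_screen <- function(truth, n_replicates = 3,
                            control_wells_per_plate = 32,
                            plate_size = 384, seed = 1L,
                            control_level = 1e6, control_level_sdlog = 0.05,
                            edge_effects = FALSE, edge_loss = 0.1) {
  stopifnot(inherits(truth, "screen_truth"), n_replicates >= 1)
  if (!plate_size %in% c(96, 384))
    stop("plate_size must be 96 or 384")
  set.seed(as.integer(seed))
  nr <- if (plate_size == 384) 16L else 8L
  nc <- plate_size / nr
  ## control columns: outermost first (1, nc, 2, nc-1, ...)
  col_order <- as.vector(rbind(seq_len(nc), rev(seq_len(nc))))[seq_len(nc)]
  n_ctrl_cols <- ceiling(control_wells_per_plate / nr)
  ctrl_cols <- sort(col_order[seq_len(n_ctrl_cols)])
  treat_cols <- setdiff(seq_len(nc), ctrl_cols)
  cap <- length(treat_cols) * nr
  rowlab <- if (nr <= 26) LETTERS[seq_len(nr)] else
    c(LETTERS, paste0("A", LETTERS))[seq_len(nr)]
  well_id <- function(r, c) sprintf("%s%02d", rowlab[r], c)

  kmat <- truth$true_killing
  ids <- colnames(kmat)
  n_cpd <- length(ids)
  out <- vector("list", nrow(truth$cell_lines))
  n_clipped <- 0L
  for (li in seq_len(nrow(truth$cell_lines))) {
    line <- truth$cell_lines$name[li]
    species <- truth$cell_lines$species[li]
    cpd_seq <- rep(ids, each = n_replicates)
    rep_seq <- rep(seq_len(n_replicates), times = n_cpd)
    n_tot <- length(cpd_seq)
    n_plates <- ceiling(n_tot / cap)
    plate_of <- rep(seq_len(n_plates), each = cap)[seq_len(n_tot)]
    slot <- (seq_len(n_tot) - 1L) %% cap
    tcol <- treat_cols[slot %/% nr + 1L]
    trow <- slot %% nr + 1L
    level <- rlnorm(n_plates, log(control_level), control_level_sdlog)

    treated <- data.frame(
      cell_line = line, species = species,
      plate_id = sprintf("%s_P%02d", gsub("[^A-Za-z0-9]", "", line), plate_of),
      well = well_id(trow, tcol), role = "treated",
      compound_id = cpd_seq, replicate = rep_seq,
      stringsAsFactors = FALSE)
    exp_sig <- level[plate_of] * (1 - kmat[li, cpd_seq] / 100)
    noise <- level[plate_of] * truth$noise_sd / 100 *
      if (truth$noise_sd > 0) rnorm(n_tot) else 0
    treated$luminescence_rlu <- exp_sig + noise

    cg <- expand.grid(row = seq_len(nr), col = ctrl_cols,
                      plate = seq_len(n_plates))
    ctrl_noise <- level[cg$plate] * truth$noise_sd / 100 *
      if (truth$noise_sd > 0) rnorm(nrow(cg)) else 0
    ctrl <- data.frame(
      cell_line = line, species = species,
      plate_id = sprintf("%s_P%02d", gsub("[^A-Za-z0-9]", "", line), cg$plate),
      well = well_id(cg$row, cg$col), role = "vehicle_control",
      compound_id = NA_character_, replicate = NA_integer_,
      luminescence_rlu = level[cg$plate] + ctrl_noise,
      stringsAsFactors = FALSE)
    df <- rbind(treated, ctrl)
    if (edge_effects) {
      rw <- match(substr(df$well, 1, 1), rowlab)
      cl <- as.integer(substr(df$well, 2, 3))
      edge <- rw == 1L | rw == nr | cl == 1L | cl == nc
      df$luminescence_rlu[edge] <- df$luminescence_rlu[edge] * (1 - edge_loss)
    }
    out[[li]] <- df
  }
  res <- do.call(rbind, out)
  neg <- res$luminescence_rlu < 0
  if (any(neg)) {
    res$luminescence_rlu[neg] <- 0
    n_clipped <- sum(neg)
  }
  rownames(res) <- NULL
  attr(res, "n_clipped") <- n_clipped
  attr(res, "seed") <- as.integer(seed)
  res
}
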