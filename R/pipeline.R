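#' Default pipeline configuration
#'
#' Nested list of stage parameters mirroring the study's printed
#' settings: triplicate wells at 1 micromolar for 72 h, hit threshold 50
#' percent killing, target filter of at least 3 drugs above 50 percent in
#' all lines, 20 micromolar / 4-fold dilution series, randomization at
#' 100 cubic mm, endpoint at day 18 or 1500 cubic mm, 5 mice per group.
#' Two screens are simulated: the 119-compound oncology screen on the
#' nine-line panel and the 2100-compound bioactives screen on the
#' two-line PDX pair with planted proteasome (9 of 11 sensitive) and CRM1
#' (3 of 4) driver targets.
#'
#' @param out_dir output directory for all stage files.
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @return config list, ready for \code{\link{run_pipeline}}.
#' @export
default_run_config <- function(out_dir = "crosskill_run", seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    screen_panel = list(n_compounds = 119, n_targets = 40,
                        species_sd = 12, line_sd = 3, noise_sd = 6,
                        super_killers = 2, n_replicates = 3,
                        concentration_um = 1, exposure_h = 72),
    screen_bioactives = list(
      n_compounds = 2100, n_targets = 200, noise_sd = 8, n_replicates = 3,
      concentration_um = 1, exposure_h = 72,
      drivers = list(list(target = "proteasome", n_drugs = 11, n_sensitive = 9),
                     list(target = "CRM1", n_drugs = 4, n_sensitive = 3)),
      line_hit_counts = list(`D418` = 250, `17-3X` = 183)),
    hits = list(threshold = 50, op = ">="),
    anom = list(alpha = 0.05),
    cluster = list(metric = "euclidean", linkage = "average"),
    rollup = list(min_drugs = 3, threshold = 50, op = ">",
                  require_lines = "all"),
    dose_response = list(start_um = 20, fold = 4, n_points = 8,
                         noise_sd = 3, n_reps = 3,
                         true_top = 100, true_bottom = 2,
                         true_ic50 = 1.25, true_hill = 1.2),
    combination = list(effect_a = c(0.15, 0.3, 0.5, 0.65),
                       effect_b = c(0.1, 0.25, 0.45, 0.6),
                       planted_excess = 0.10, noise_sd = 0.05),
    invivo = list(groups = data.frame(
      name = c("vehicle", "bortezomib", "alvespimycin", "verdinexor"),
      n_mice = c(5, 5, 5, 5),
      rate = c(0.16, 0.05, 0.08, 0.06), stringsAsFactors = FALSE),
      v0 = 150, noise_sd = 30,
      randomization_volume = 100, endpoint_volume = 1500, endpoint_day = 18),
    survival = list(n = 120, cutoff = 5, hazard_low = 0.04,
                    hazard_high = 0.16, censor_rate = 0.2,
                    min_group_frac = 0.1),
    inputs = NULL   # optional: list(plate_map=, measurements=, annotation=)
  )
}

#' Validate a pipeline configuration
#'
#' Checks required fields, parameter ranges and (when external inputs are
#' configured) path existence; errors name the offending field.
#'
#' @param config list as from \code{\link{default_run_config}} or read
#'   from YAML.
#' @return the config, invisibly, on success.
#' @export
validate_run_config <- function(config) {
  fail <- function(field, why) stop("config field '", field, "': ", why,
                                    call. = FALSE)
  for (f in c("seed", "out_dir", "hits", "rollup"))
    if (is.null(config[[f]])) fail(f, "missing")
  if (!is.numeric(config$seed)) fail("seed", "must be an integer")
  th <- config$hits$threshold
  if (is.null(th) || !is.numeric(th)) fail("hits$threshold", "missing")
  if (!is.null(config$anom$alpha) &&
      (config$anom$alpha <= 0 || config$anom$alpha >= 1))
    fail("anom$alpha", "must be in (0, 1)")
  if (!is.null(config$rollup$min_drugs) && config$rollup$min_drugs < 1)
    fail("rollup$min_drugs", "must be >= 1")
  if (!is.null(config$inputs)) {
    for (f in c("plate_map", "measurements", "annotation"))
      if (is.null(config$inputs[[f]])) fail(paste0("inputs$", f), "missing")
    for (f in c("plate_map", "measurements", "annotation")) {
      p <- config$inputs[[f]]
      if (!file.exists(p)) fail(paste0("inputs$", f),
                                paste0("path does not exist: ", p))
    }
  }
  if (!is.null(config$survival) &&
      (config$survival$hazard_low <= 0 || config$survival$hazard_high <= 0))
    fail("survival", "hazards must be > 0")
  invisible(config)
}

#' Run the full screen-to-validation pipeline
#'
#' Stages, in dependency order: simulate (or load) the screens ->
#' normalize -> hits / ANOM / screen summary -> clustering and
#' cross-species concordance -> target roll-up -> dose-response fits ->
#' Bliss synergy -> in-vivo growth ANOVA -> expression-cutoff survival
#' scan. Every output file is recorded with its MD5 hash in a JSON run
#' manifest; two runs with the same config and seed are bit-identical.
#' Any stage failure halts the run with the stage name in the error.
#'
#' @param config a config list (see \code{\link{default_run_config}}) or
#'   the path to a YAML file with the same structure.
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.list(config$invivo$groups) && !is.data.frame(config$invivo$groups))
    config$invivo$groups <- as.data.frame(config$invivo$groups)
  validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  sub_seed <- function(k) (seed * 97L + k) %% 2147483647L
  outputs <- character()
  note <- function(paths) outputs <<- c(outputs, unname(paths))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  results <- list()

  ## --- bioactives screen (2 lines x 2100 compounds) -------------------
  stage("simulate_bioactives", {
    if (is.null(config$inputs)) {
      sb <- config$screen_bioactives
      lib <- generate_compound_library(
        n_targets = sb$n_targets, n_compounds = sb$n_compounds,
        driver_spec = sb$drivers, cell_lines = two_line_panel(),
        seed = sub_seed(1L), noise_sd = sb$noise_sd,
        line_hit_counts = unlist(sb$line_hit_counts))
      wells <- generate_screen(lib$truth, n_replicates = sb$n_replicates,
                               seed = sub_seed(2L))
      note(write_screen_csv(wells, out_dir, "bioactives"))
      note(write_annotation_csv(lib$annotation,
                                file.path(out_dir, "bioactives_annotation.csv")))
      results$bio_annotation <- lib$annotation
      results$bio_truth <- lib$truth
      results$bio_wells <- wells
    } else {
      results$bio_wells <- read_screen_csv(config$inputs$plate_map,
                                            config$inputs$measurements)
      results$bio_annotation <- read_annotation_csv(config$inputs$annotation)
    }
  })
  stage("normalize_bioactives", {
    km <- normalize_screen(results$bio_wells)
    note(write_killing_matrix(km, out_dir, "bioactives_killing"))
    results$bio_km <- km
  })
  stage("hits_bioactives", {
    hits <- call_hits(results$bio_km, threshold = config$hits$threshold,
                      op = config$hits$op)
    write.table(hits$long, file.path(out_dir, "bioactives_hits.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    note(file.path(out_dir, "bioactives_hits.tsv"))
    results$bio_hits <- hits
  })
  stage("concordance_bioactives", {
    conc <- species_concordance(results$bio_km)
    jsonlite::write_json(
      list(r = conc$r, r_squared = conc$r_squared, p_value = conc$p_value,
           n_compounds = conc$n_compounds),
      file.path(out_dir, "bioactives_concordance.json"),
      auto_unbox = TRUE, digits = NA)
    write.csv(conc$scatter, file.path(out_dir, "bioactives_concordance.csv"),
              row.names = FALSE)
    note(file.path(out_dir, c("bioactives_concordance.json",
                              "bioactives_concordance.csv")))
    results$bio_concordance <- conc
  })
  stage("rollup_bioactives", {
    rc <- config$rollup
    ro <- rollup(results$bio_hits, results$bio_annotation,
                 min_drugs = rc$min_drugs, threshold = rc$threshold,
                 op = rc$op, require_lines = rc$require_lines)
    write.csv(ro$table, file.path(out_dir, "bioactives_rollup.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(level = ro$level, min_drugs = ro$min_drugs,
           threshold = ro$threshold, op = ro$op,
           passing = ro$passing, n_unannotated = ro$n_unannotated),
      file.path(out_dir, "bioactives_rollup.json"), auto_unbox = TRUE)
    note(file.path(out_dir, c("bioactives_rollup.csv",
                              "bioactives_rollup.json")))
    results$bio_rollup <- ro
  })

  ## --- panel screen (9 lines x 119 compounds) -------------------------
  stage("panel_screen", {
    sp <- config$screen_panel
    lib <- generate_compound_library(
      n_targets = sp$n_targets, n_compounds = sp$n_compounds,
      driver_spec = list(), cell_lines = nine_line_panel(),
      seed = sub_seed(3L), species_sd = sp$species_sd,
      line_sd = sp$line_sd, noise_sd = sp$noise_sd,
      super_killers = sp$super_killers)
    wells <- generate_screen(lib$truth, n_replicates = sp$n_replicates,
                             seed = sub_seed(4L))
    note(write_screen_csv(wells, out_dir, "panel"))
    km <- normalize_screen(wells)
    note(write_killing_matrix(km, out_dir, "panel_killing"))
    hits <- call_hits(km, threshold = config$hits$threshold,
                      op = config$hits$op)
    summ <- summarize_screen(km, hits)
    cl <- cluster_cell_lines(km, metric = config$cluster$metric,
                             linkage = config$cluster$linkage)
    link_tab <- data.frame(step = seq_along(cl$heights),
                           left = cl$merge[, 1], right = cl$merge[, 2],
                           height = cl$heights)
    write.table(link_tab, file.path(out_dir, "panel_linkage.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(as_newick(cl), file.path(out_dir, "panel_dendrogram.nwk"))
    ## ANOM on per-well killing replicates, compounds as groups
    pw <- normalize_plates(wells)
    an <- anom_top_drugs(data.frame(group = pw$compound_id,
                                    value = pw$percent_killing),
                         alpha = config$anom$alpha)
    write.table(an$table, file.path(out_dir, "panel_anom.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(alpha = an$alpha, k = an$k, df = an$df,
           grand_mean = an$grand_mean, pooled_sd = an$pooled_sd,
           top_candidates = top_candidates(an)),
      file.path(out_dir, "panel_anom.json"), auto_unbox = TRUE, digits = NA)
    note(file.path(out_dir, c("panel_linkage.tsv", "panel_dendrogram.nwk",
                              "panel_anom.tsv", "panel_anom.json")))
    results$panel_km <- km
    results$panel_cluster <- cl
    results$panel_anom <- an
    results$panel_summary <- summ
  })

  ## --- dose response, synergy -----------------------------------------
  stage("dose_response", {
    dr <- config$dose_response
    conc <- dilution_series(dr$start_um, dr$fold, dr$n_points)
    dat <- generate_dose_response(dr$true_top, dr$true_bottom, dr$true_ic50,
                                  dr$true_hill, conc, dr$noise_sd,
                                  dr$n_reps, seed = sub_seed(5L))
    fit <- fit_4pl(dat$concentration_um, dat$viability_pct)
    jsonlite::write_json(
      c(as.list(coef(fit)),
        list(rss = fit$rss, converged = fit$converged,
             ic50_in_range = fit$ic50_in_range, ic50_abs = fit$ic50_abs)),
      file.path(out_dir, "dose_response_fit.json"), auto_unbox = TRUE,
      digits = NA)
    note(file.path(out_dir, "dose_response_fit.json"))
    results$dr_fit <- fit
  })
  stage("synergy", {
    cb <- config$combination
    grid <- generate_combination_grid(cb$effect_a, cb$effect_b,
                                      cb$planted_excess, cb$noise_sd,
                                      seed = sub_seed(6L))
    grid <- bliss_excess(grid)
    long <- expand.grid(dose_a = grid$doses_a, dose_b = grid$doses_b)
    long$observed <- as.vector(grid$observed)
    long$expected <- as.vector(grid$bliss_expected)
    long$excess <- as.vector(grid$excess)
    write.table(long, file.path(out_dir, "synergy_grid.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    note(file.path(out_dir, "synergy_grid.tsv"))
    results$synergy <- grid
  })

  ## --- in vivo ----------------------------------------------------------
  stage("invivo", {
    iv <- config$invivo
    cal <- generate_tumor_study(iv$groups, v0 = iv$v0,
                                noise_sd = iv$noise_sd, seed = sub_seed(7L))
    study <- apply_study_rules(cal,
                               randomization_volume = iv$randomization_volume,
                               endpoint_volume = iv$endpoint_volume,
                               endpoint_day = iv$endpoint_day)
    aov_tab <- two_way_anova(study, days = "shared")
    write.csv(study$measurements, file.path(out_dir, "invivo_volumes.csv"),
              row.names = FALSE)
    write.table(study$exclusions, file.path(out_dir, "invivo_exclusions.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(aov_tab$table, file.path(out_dir, "invivo_anova.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    note(file.path(out_dir, c("invivo_volumes.csv", "invivo_exclusions.tsv",
                              "invivo_anova.tsv")))
    results$invivo_study <- study
    results$invivo_anova <- aov_tab
  })

  ## --- survival scan ----------------------------------------------------
  stage("kmscan", {
    sv <- config$survival
    cohort <- generate_survival_cohort(sv$n, sv$cutoff, sv$hazard_low,
                                       sv$hazard_high, sv$censor_rate,
                                       seed = sub_seed(8L))
    scan <- scan_cutoff(cohort, min_group_frac = sv$min_group_frac)
    write.table(scan$table, file.path(out_dir, "kmscan_table.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(best_cutoff = scan$best_cutoff, min_p = scan$min_p,
           n_cutoffs_scanned = scan$n_cutoffs_scanned),
      file.path(out_dir, "kmscan_summary.json"), auto_unbox = TRUE,
      digits = NA)
    note(file.path(out_dir, c("kmscan_table.tsv", "kmscan_summary.json")))
    results$km_scan <- scan
  })

  ## --- manifest ---------------------------------------------------------
  manifest <- list(
    seed = seed,
    parameters = config[setdiff(names(config), c("inputs"))],
    outputs = lapply(setNames(nm = sort(outputs)), function(p)
      list(md5 = unname(tools::md5sum(p)))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  manifest$results <- results
  invisible(manifest)
}
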