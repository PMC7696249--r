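test_that("compound library plants drivers exactly as specified", {
  lib <- generate_compound_library(
    n_targets = 200, n_compounds = 400,
    driver_spec = list(list("proteasome", 11, 9), list("CRM1", 4, 3)),
    seed = 7)
  ann <- lib$annotation
  tk <- lib$truth$true_killing
  expect_equal(nrow(ann), 400)
  expect_false(anyDuplicated(ann$compound_id) > 0)
  expect_true(all(c("proteasome", "CRM1") %in% ann$targets))
  prot <- ann$compound_id[ann$targets == "proteasome"]
  expect_length(prot, 11)
  sens <- lib$truth$sensitive_compounds$proteasome
  expect_length(sens, 9)
  ## sensitive drugs kill > 50 in every line, non-sensitive < 50 everywhere
  expect_true(all(apply(tk[, sens, drop = FALSE] > 50, 2, all)))
  nonsens <- setdiff(prot, sens)
  expect_true(all(tk[, nonsens] < 50))
  crm <- lib$truth$sensitive_compounds$CRM1
  expect_length(crm, 3)
  expect_true(all(tk[, crm] > 50))
})

test_that("without drivers no compound is sensitive in all lines", {
  lib <- generate_compound_library(n_targets = 50, n_compounds = 500,
                                   driver_spec = list(), seed = 11)
  mins <- apply(lib$truth$true_killing, 2, min)
  expect_true(all(mins < 50))
})

test_that("duplicate driver targets are rejected", {
  expect_error(
    generate_compound_library(driver_spec = list(list("x", 4, 2),
                                                 list("x", 5, 1)), seed = 1),
    "duplicate target")
  expect_error(
    generate_compound_library(driver_spec = list(list("x", 3, 5)), seed = 1),
    "n_sensitive")
})

test_that("generators are pure functions of (parameters, seed)", {
  a <- generate_compound_library(n_compounds = 120, n_targets = 20, seed = 5)
  b <- generate_compound_library(n_compounds = 120, n_targets = 20, seed = 5)
  expect_identical(a, b)
  wa <- generate_screen(a$truth, seed = 9)
  wb <- generate_screen(b$truth, seed = 9)
  expect_identical(wa, wb)
  expect_identical(generate_survival_cohort(50, seed = 3),
                   generate_survival_cohort(50, seed = 3))
  ga <- generate_combination_grid(c(.2, .4), c(.3, .5), 0.05,
                                  noise_sd = 0.02, seed = 4)
  gb <- generate_combination_grid(c(.2, .4), c(.3, .5), 0.05,
                                  noise_sd = 0.02, seed = 4)
  expect_identical(ga, gb)
})

test_that("zero-noise wells read exactly the planted fraction of control", {
  tk <- matrix(80, 1, 1, dimnames = list("L1", "CPD1"))
  tr <- screen_truth(tk, data.frame(name = "L1", species = "human"),
                     noise_sd = 0)
  w <- generate_screen(tr, n_replicates = 3, seed = 2)
  ctrl <- w$luminescence_rlu[w$role == "vehicle_control"]
  treated <- w$luminescence_rlu[w$role == "treated"]
  expect_equal(treated, rep(median(ctrl) * 0.2, 3), tolerance = 1e-12)
})

test_that("screen layout paginates and counts replicates correctly", {
  lib <- generate_compound_library(n_compounds = 2100, n_targets = 100,
                                   seed = 1)
  w <- generate_screen(lib$truth, n_replicates = 3, seed = 2)
  treated <- w[w$role == "treated", ]
  ## 2 lines x 2100 compounds x 3 replicates
  expect_equal(nrow(treated), 2 * 2100 * 3)
  cnt <- table(treated$cell_line, treated$compound_id)
  expect_true(all(cnt == 3))
  ## 352 treated wells on a 384-well plate with 2 control columns
  expect_gte(length(unique(w$plate_id[w$cell_line == "D418"])),
             ceiling(2100 * 3 / 352))
  ## every plate has >= requested control wells
  ctrl_per_plate <- table(w$plate_id[w$role == "vehicle_control"])
  expect_true(all(ctrl_per_plate >= 32))
})

test_that("nine-line panel screen emits the expected treated rows", {
  lib <- generate_compound_library(n_compounds = 119, n_targets = 30,
                                   cell_lines = nine_line_panel(), seed = 3)
  w <- generate_screen(lib$truth, n_replicates = 3, seed = 4)
  expect_equal(sum(w$role == "treated"), 9 * 119 * 3)
})

test_that("planted per-line hit counts are honored exactly", {
  lib <- generate_compound_library(
    n_targets = 200, n_compounds = 2100,
    driver_spec = list(list("proteasome", 11, 9), list("CRM1", 4, 3)),
    seed = 17, line_hit_counts = c("D418" = 250, "17-3X" = 183))
  tk <- lib$truth$true_killing
  expect_equal(sum(tk["D418", ] > 50), 250)
  expect_equal(sum(tk["17-3X", ] > 50), 183)
  ## background compounds still never exceed 50 in both lines
  drv <- unlist(lib$truth$sensitive_compounds)
  bg <- setdiff(colnames(tk), drv)
  expect_true(all(apply(tk[, bg] > 50, 2, sum) <= 1))
})

test_that("dose-response generator matches the 4PL expectation", {
  d <- generate_dose_response(100, 0, 1.25, 1, concentrations = 1.25,
                              noise_sd = 0, seed = 1)
  expect_equal(d$viability_pct, 50)   # midpoint symmetry
  d2 <- generate_dose_response(90, 10, 2, 1.5, concentrations = 1e-9,
                               noise_sd = 0, seed = 1)
  expect_equal(d2$viability_pct, 90, tolerance = 1e-6)   # c -> 0 limit
  expect_error(generate_dose_response(concentrations = c(1, -2), seed = 1),
               "> 0")
})

test_that("combination generator plants Bliss structure", {
  g <- generate_combination_grid(0.5, 0.5, planted_excess = 0.1,
                                 noise_sd = 0, seed = 1)
  expect_equal(g$observed[2, 2], 0.85)
  g0 <- generate_combination_grid(c(.2, .6), c(.3, .5), 0, noise_sd = 0,
                                  seed = 1)
  b <- bliss_excess(g0)
  expect_equal(max(abs(b$excess)), 0, tolerance = 1e-12)
  expect_warning(
    generate_combination_grid(0.9, 0.9, planted_excess = 0.5, seed = 1),
    "clipped")
})

test_that("tumor-study generator satisfies the caliper identity", {
  g <- data.frame(name = c("ctrl", "rx"), n_mice = c(5, 5),
                  rate = c(0.1, 0))
  st <- generate_tumor_study(g, v0 = 150, noise_sd = 0, seed = 2)
  expect_equal(sum(st$group == "rx") , 5 * 9)
  expect_true(all(st$width_mm <= st$length_mm))
  vol <- st$length_mm * st$width_mm^2 / 2
  expect_equal(vol[st$group == "rx"], rep(150, 45), tolerance = 1e-9)
  expect_equal(vol[st$group == "ctrl" & st$day == 0], rep(150, 5),
               tolerance = 1e-9)
  expect_error(generate_tumor_study(
    data.frame(name = "a", n_mice = 0, rate = 0), seed = 1), "at least one")
})

test_that("survival cohort generator respects censoring and hazards", {
  co <- generate_survival_cohort(200, censor_rate = 0, seed = 5)
  expect_true(all(co$event == 1))
  expect_true(all(co$time > 0))
  expect_error(generate_survival_cohort(3, seed = 1), ">= 4")
  expect_error(generate_survival_cohort(10, hazard_low = 0, seed = 1),
               "hazards")
  ## high-expression subjects die faster when hazard_high >> hazard_low
  co2 <- generate_survival_cohort(2000, cutoff = 5, hazard_low = 0.05,
                                  hazard_high = 0.5, seed = 6)
  expect_lt(median(co2$time[co2$expression > 5]),
            median(co2$time[co2$expression <= 5]))
})
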