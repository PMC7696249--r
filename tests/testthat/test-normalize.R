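test_that("percent killing is the complementary signal ratio", {
  expect_equal(percent_killing(2000, 10000), 80)
  expect_equal(percent_killing(10000, 10000), 0)
  expect_equal(percent_killing(12000, 10000), -20)  # stimulation retained
  expect_error(percent_killing(1000, 0), "control_center")
  expect_error(percent_killing(1000, -5), "control_center")
})

well_df <- function(plate, role, rlu, compound = NA, rep = NA,
                    line = "L1", species = "human") {
  data.frame(cell_line = line, species = species, plate_id = plate,
             well = sprintf("W%02d", seq_along(rlu)), role = role,
             compound_id = compound, replicate = rep,
             luminescence_rlu = rlu, stringsAsFactors = FALSE)
}

test_that("plates are normalized against their own control center", {
  m <- rbind(
    well_df("P1", "vehicle_control", c(9000, 10000, 11000)),
    well_df("P1", "treated", 5000, "C1", 1),
    well_df("P2", "vehicle_control", c(20000, 20000)),
    well_df("P2", "treated", 5000, "C1", 2))
  pw <- normalize_plates(m)
  expect_equal(pw$percent_killing[pw$plate_id == "P1"], 50)
  expect_equal(pw$percent_killing[pw$plate_id == "P2"], 75)
  ## mean statistic by flag
  pw_mean <- normalize_plates(m, control_stat = "mean")
  expect_equal(pw_mean$percent_killing[pw_mean$plate_id == "P1"], 50)
})

test_that("plates without controls are excluded with a warning", {
  m <- rbind(
    well_df("P1", "vehicle_control", c(10000, 10000)),
    well_df("P1", "treated", 4000, "C1", 1),
    well_df("P2", "treated", 4000, "C1", 2))
  expect_warning(pw <- normalize_plates(m), "no vehicle controls")
  expect_equal(unique(pw$plate_id), "P1")
  expect_equal(attr(pw, "excluded_plates"), "P2")
})

test_that("replicate aggregation averages and flags", {
  m <- rbind(
    well_df("P1", "vehicle_control", c(10000, 10000)),
    well_df("P1", "treated", c(5000, 4000, 3000), "C1", 1:3),
    well_df("P1", "treated", 5800, "C2", 1),
    well_df("P1", "treated", c(7000, 7000, 7000), "C3", 1:3))
  km <- aggregate_replicates(normalize_plates(m), cv_threshold = 20)
  expect_equal(unname(km$values["L1", "C1"]), mean(c(50, 60, 70)))
  expect_equal(km$qc_flags["L1", "C2"], "n=1")
  expect_equal(km$qc_flags["L1", "C3"], "")          # CV 0, unflagged
  expect_equal(km$qc_flags["L1", "C1"], "high_cv")   # CV 25%
  expect_equal(unname(km$n_reps["L1", ]), c(3L, 1L, 3L))
})

test_that("matrix is invariant to well order and plate-level scaling", {
  lib <- generate_compound_library(n_compounds = 60, n_targets = 10,
                                   seed = 21)
  w <- generate_screen(lib$truth, seed = 22)
  km1 <- normalize_screen(w)
  set.seed(1)
  km2 <- normalize_screen(w[sample(nrow(w)), ])
  expect_equal(km1$values, km2$values)
  expect_identical(km1$qc_flags, km2$qc_flags)
  ## scale every plate's luminescence by its own positive factor
  w3 <- w
  fac <- setNames(runif(length(unique(w$plate_id)), 0.5, 2),
                  unique(w$plate_id))
  w3$luminescence_rlu <- w3$luminescence_rlu * fac[w3$plate_id]
  km3 <- normalize_screen(w3)
  expect_equal(km1$values, km3$values, tolerance = 1e-12)
})

test_that("zero-noise screens recover the planted killing exactly", {
  lib <- generate_compound_library(
    n_compounds = 300, n_targets = 40,
    driver_spec = list(list("proteasome", 11, 9)), seed = 31, noise_sd = 0)
  w <- generate_screen(lib$truth, seed = 32)
  km <- normalize_screen(w)
  tk <- lib$truth$true_killing[rownames(km$values), colnames(km$values)]
  expect_lt(max(abs(km$values - tk)), 1e-9)
})

test_that("clipping into [0, 100] is available but off by default", {
  m <- rbind(well_df("P1", "vehicle_control", c(10000, 10000)),
             well_df("P1", "treated", c(12000, 12000), "C1", 1:2))
  km <- normalize_screen(m)
  expect_equal(unname(km$values["L1", "C1"]), -20)
  kmc <- normalize_screen(m, clip = TRUE)
  expect_equal(unname(kmc$values["L1", "C1"]), 0)
})

test_that("screen tables round-trip through the CSV dialect", {
  lib <- generate_compound_library(n_compounds = 40, n_targets = 8, seed = 41)
  w <- generate_screen(lib$truth, seed = 42)
  dir <- withr::local_tempdir()
  paths <- write_screen_csv(w, dir)
  w2 <- read_screen_csv(paths["plate_map"], paths["measurements"])
  km1 <- normalize_screen(w)
  km2 <- normalize_screen(w2)
  expect_equal(km1$values, km2$values, tolerance = 1e-9)
  kp <- write_killing_matrix(km1, dir)
  km3 <- read_killing_matrix(kp["wide"])
  expect_equal(km3$values, km1$values, tolerance = 1e-9)
  expect_identical(km3$species, km1$species)
})
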