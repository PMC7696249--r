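mk_hits <- function(kill_by_line) {
  ## kill_by_line: list(line -> named killing vector over compounds)
  lines <- names(kill_by_line)
  v <- do.call(rbind, kill_by_line)
  rownames(v) <- lines
  km <- killing_matrix(v, setNames(rep(c("human", "dog"),
                                       length.out = length(lines)), lines))
  call_hits(km)
}

test_that("the at-least-m-drugs filter reproduces the 3-of-4 pattern", {
  kills <- c(A = 90, B = 80, C = 70, D = 40)
  hits <- mk_hits(list(L1 = kills, L2 = kills))
  ann <- data.frame(compound_id = names(kills), name = names(kills),
                    targets = "CRM1", pathway = "nuclear_export",
                    stringsAsFactors = FALSE)
  ro <- rollup(hits, ann, min_drugs = 3)
  expect_equal(ro$table$n_drugs_hit, 3L)
  expect_equal(ro$table$n_drugs_total, 4L)
  expect_true(ro$table$passes_filter)
})

test_that("9 of 11 passes and 2 of 11 fails at m = 3", {
  kills <- setNames(c(rep(80, 9), rep(30, 2)), paste0("P", 1:11))
  hits <- mk_hits(list(L1 = kills, L2 = kills))
  ann <- data.frame(compound_id = names(kills), name = names(kills),
                    targets = "proteasome", pathway = "ubiquitin",
                    stringsAsFactors = FALSE)
  ro <- rollup(hits, ann)
  expect_equal(ro$table$n_drugs_hit, 9L)
  expect_true(ro$table$passes_filter)
  kills2 <- setNames(c(rep(80, 2), rep(30, 9)), paste0("P", 1:11))
  hits2 <- mk_hits(list(L1 = kills2, L2 = kills2))
  ro2 <- rollup(hits2, ann)
  expect_equal(ro2$table$n_drugs_hit, 2L)
  expect_false(ro2$table$passes_filter)
})

test_that("the roll-up comparator is strict by default", {
  kills <- c(A = 50, B = 50.0001, C = 80)
  hits <- mk_hits(list(L1 = kills))
  ann <- data.frame(compound_id = names(kills), name = names(kills),
                    targets = "T", pathway = "p", stringsAsFactors = FALSE)
  expect_equal(rollup(hits, ann)$table$n_drugs_hit, 2L)       # ">"
  expect_equal(rollup(hits, ann, op = ">=")$table$n_drugs_hit, 3L)
})

test_that("a drug must qualify in every required line", {
  hits <- mk_hits(list(L1 = c(A = 90, B = 90), L2 = c(A = 90, B = 10)))
  ann <- data.frame(compound_id = c("A", "B"), name = c("A", "B"),
                    targets = "T", pathway = "p", stringsAsFactors = FALSE)
  expect_equal(rollup(hits, ann, min_drugs = 1)$table$n_drugs_hit, 1L)
  expect_equal(rollup(hits, ann, min_drugs = 1,
                      require_lines = "any")$table$n_drugs_hit, 2L)
  expect_equal(rollup(hits, ann, min_drugs = 1,
                      require_lines = "L1")$table$n_drugs_hit, 2L)
})

test_that("multi-target drugs count toward every annotated target", {
  hits <- mk_hits(list(L1 = c(A = 90, B = 90, C = 90)))
  ann <- data.frame(compound_id = c("A", "B", "C"), name = c("A", "B", "C"),
                    targets = c("T1;T2", "T1", "T2"), pathway = "p",
                    stringsAsFactors = FALSE)
  ro <- rollup(hits, ann, min_drugs = 2)
  tab <- ro$table[order(ro$table$target), ]
  expect_equal(tab$n_drugs_hit, c(2L, 2L))
  expect_true(all(tab$passes_filter))
})

test_that("unannotated compounds are counted, not fatal; empty is fatal", {
  hits <- mk_hits(list(L1 = c(A = 90, B = 90)))
  ann <- data.frame(compound_id = "A", name = "A", targets = "T",
                    pathway = "p", stringsAsFactors = FALSE)
  ro <- rollup(hits, ann, min_drugs = 1)
  expect_equal(ro$n_unannotated, 1L)
  expect_error(rollup(hits, ann[0, ]), "empty annotation")
})

test_that("pathway-level roll-up drops records without a pathway", {
  hits <- mk_hits(list(L1 = c(A = 90, B = 90, C = 90)))
  ann <- data.frame(compound_id = c("A", "B", "C"), name = c("A", "B", "C"),
                    targets = c("T1", "T2", "T3"),
                    pathway = c("p1", "p1", ""), stringsAsFactors = FALSE)
  ro <- rollup(hits, ann, level = "pathway", min_drugs = 2)
  expect_equal(ro$n_missing_pathway, 1L)
  expect_equal(ro$table$target, "p1")
  expect_equal(ro$table$n_drugs_hit, 2L)
})

test_that("relaxing threshold or min_drugs never removes a passing target", {
  set.seed(6)
  lib <- generate_compound_library(
    n_compounds = 300, n_targets = 30,
    driver_spec = list(list("proteasome", 11, 9), list("CRM1", 4, 3)),
    seed = 6)
  km <- normalize_screen(generate_screen(lib$truth, seed = 7))
  hits <- call_hits(km)
  base <- rollup(hits, lib$annotation, min_drugs = 3, threshold = 50)
  lower_th <- rollup(hits, lib$annotation, min_drugs = 3, threshold = 40)
  lower_m <- rollup(hits, lib$annotation, min_drugs = 2, threshold = 50)
  expect_true(all(base$passing %in% lower_th$passing))
  expect_true(all(base$passing %in% lower_m$passing))
})

test_that("roll-up comparison is plain set algebra", {
  hits <- mk_hits(list(L1 = c(A = 90, B = 90)))
  ann <- data.frame(compound_id = c("A", "B"), name = c("A", "B"),
                    targets = c("T1", "T2"), pathway = "p",
                    stringsAsFactors = FALSE)
  r1 <- rollup(hits, ann, min_drugs = 1)
  cmp <- compare_rollups(r1, r1)
  expect_identical(cmp$both, cmp$either)
  hits2 <- mk_hits(list(L1 = c(A = 90, B = 10)))
  hits3 <- mk_hits(list(L1 = c(A = 10, B = 90)))
  cmp2 <- compare_rollups(rollup(hits2, ann, min_drugs = 1),
                          rollup(hits3, ann, min_drugs = 1))
  expect_length(cmp2$both, 0)
  expect_setequal(cmp2$either, c("T1", "T2"))
})

test_that("planted drivers are exactly the passing set in a clean screen", {
  lib <- generate_compound_library(
    n_compounds = 500, n_targets = 60,
    driver_spec = list(list("proteasome", 11, 9), list("CRM1", 4, 3)),
    seed = 77, noise_sd = 0)
  km <- normalize_screen(generate_screen(lib$truth, seed = 78))
  ro <- rollup(call_hits(km), lib$annotation)
  expect_setequal(ro$passing, c("proteasome", "CRM1"))
})
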