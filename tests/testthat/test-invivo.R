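test_that("tumor volume uses the ellipsoid halving rule", {
  expect_equal(tumor_volume(10, 5), 125)
  expect_equal(tumor_volume(5, 10), 125)        # caliper order irrelevant
  expect_equal(tumor_volume(7, 7), 7^3 / 2)
  expect_error(tumor_volume(0, 5), "> 0")
  ## monotone in both dimensions
  expect_gt(tumor_volume(11, 5), tumor_volume(10, 5))
  expect_gt(tumor_volume(10, 6), tumor_volume(10, 5))
})

toy_measurements <- function() {
  ## three mice: M1 grows through the endpoint volume at day 10,
  ## M2 stays small but reaches randomization late, M3 never randomizes
  data.frame(
    mouse_id = rep(c("M1", "M2", "M3"), each = 5),
    group = rep(c("ctrl", "rx", "rx"), each = 5),
    day = rep(c(0, 4, 7, 10, 14), 3),
    volume_mm3 = c(120, 400, 900, 1600, 2000,
                   60, 110, 150, 200, 260,
                   40, 50, 60, 70, 80),
    stringsAsFactors = FALSE)
}

test_that("study rules match hand bookkeeping on the toy table", {
  ts <- apply_study_rules(toy_measurements())
  ## M1: randomized at day 0; crosses 1500 at day 10 -> day 14 dropped
  m1 <- ts$measurements[ts$measurements$mouse_id == "M1", ]
  expect_equal(m1$study_day, c(0, 4, 7, 10))
  ## M2: randomized at day 4 -> study days 0,3,6,10; none past endpoint
  m2 <- ts$measurements[ts$measurements$mouse_id == "M2", ]
  expect_equal(m2$study_day, c(0, 3, 6, 10))
  ## M3 excluded entirely
  expect_false("M3" %in% ts$measurements$mouse_id)
  expect_equal(nrow(ts$measurements), 8)
  led <- ts$exclusions
  expect_equal(sort(led$reason), sort(c("past_endpoint_volume",
                                        "never_randomized")))
  expect_equal(led$n_rows[led$mouse_id == "M1"], 1L)
  expect_equal(led$n_rows[led$mouse_id == "M3"], 5L)
})

test_that("degenerate and clean studies are handled", {
  small <- toy_measurements()
  small$volume_mm3 <- small$volume_mm3 / 100
  ts <- apply_study_rules(small)
  expect_equal(nrow(ts$measurements), 0)
  expect_equal(nrow(ts$exclusions), 3)
  ## generator output with no crossings is fully retained
  st <- generate_tumor_study(data.frame(name = "a", n_mice = 3, rate = 0.05),
                             v0 = 150, noise_sd = 0, seed = 1)
  ts2 <- apply_study_rules(st)
  expect_equal(nrow(ts2$measurements), nrow(st))
  expect_equal(nrow(ts2$exclusions), 0)
})

test_that("study rules are idempotent", {
  ts1 <- apply_study_rules(toy_measurements())
  again <- ts1$measurements
  again$day <- again$study_day
  again$study_day <- NULL
  ts2 <- apply_study_rules(again)
  expect_equal(ts2$measurements$volume_mm3, ts1$measurements$volume_mm3)
  expect_equal(ts2$measurements$study_day, ts1$measurements$study_day)
  expect_equal(nrow(ts2$exclusions), 0)
})

test_that("caliper pairs with width > length are auto-oriented", {
  m <- data.frame(mouse_id = "M1", group = "g", day = c(0, 2),
                  length_mm = c(5, 8), width_mm = c(10, 4))
  ts <- apply_study_rules(m, randomization_volume = 50)
  expect_equal(ts$n_swapped, 1L)
  expect_equal(ts$measurements$volume_mm3, c(125, 64))
})

test_that("two-way ANOVA decomposes balanced sums of squares exactly", {
  set.seed(12)
  d <- expand.grid(group = c("a", "b", "c"), study_day = 1:4, mouse = 1:4)
  d$volume_mm3 <- rnorm(nrow(d), 100, 10)
  a <- two_way_anova(d)
  expect_true(a$balanced)
  expect_equal(sum(a$table$ss), a$ss_total, tolerance = 1e-9)
  expect_equal(sum(a$table$df), nrow(d) - 1)
  ## against the stock R fit
  ref <- summary(aov(volume_mm3 ~ group * factor(study_day), data = d))[[1]]
  expect_equal(a$table$ss, ref[["Sum Sq"]], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(a$table$p[1:3], ref[["Pr(>F)"]][1:3], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a planted group effect is detected on noiseless curves", {
  st <- generate_tumor_study(
    data.frame(name = c("ctrl", "rx"), n_mice = c(5, 5),
               rate = c(0.12, 0.02)), v0 = 150, noise_sd = 0, seed = 3)
  a <- two_way_anova(apply_study_rules(st, endpoint_volume = 1e9))
  expect_lt(a$table$p[a$table$effect == "group"], 0.05)
  ## identical groups, zero noise: zero group SS
  st0 <- generate_tumor_study(
    data.frame(name = c("a", "b"), n_mice = c(4, 4), rate = c(0.05, 0.05)),
    v0 = 150, noise_sd = 0, seed = 4)
  a0 <- two_way_anova(apply_study_rules(st0, endpoint_volume = 1e9))
  expect_equal(a0$table$ss[a0$table$effect == "group"], 0, tolerance = 1e-9)
})

test_that("empty design cells are named in the error", {
  d <- data.frame(group = c("a", "a", "b"), study_day = c(1, 2, 1),
                  volume_mm3 = c(1, 2, 3))
  expect_error(two_way_anova(d), "group 'b', day 2")
  ## shared-days restriction drops the offending day instead
  d2 <- rbind(d, data.frame(group = c("a", "b", "b"),
                            study_day = c(1, 1, 3), volume_mm3 = c(4, 5, 6)))
  expect_error(two_way_anova(d2, days = "shared"), "fewer than 2")
})

test_that("unbalanced designs fall back to Type-II sums of squares", {
  set.seed(8)
  d <- expand.grid(group = c("a", "b"), study_day = 1:3, mouse = 1:4)
  d$volume_mm3 <- rnorm(nrow(d), 100, 10)
  d <- d[-1, ]   # unbalance one cell
  a <- two_way_anova(d)
  expect_false(a$balanced)
  rss <- function(f) sum(lm(f, data = transform(
    d, g = factor(group), t = factor(study_day)))$residuals^2)
  expect_equal(a$table$ss[1], rss(volume_mm3 ~ t) - rss(volume_mm3 ~ g + t),
               tolerance = 1e-9)
})
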