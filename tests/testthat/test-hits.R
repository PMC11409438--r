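make_screen_table <- function(test_rows) {
  rbind(score_row(well = "H01", compound = "trametinib",
                  role = "positive_control", n_vulvae = 0, n_adults = 10,
                  conc_um = 7),
        test_rows)
}

test_that("the four-well worked example reproduces its hand-derived calls", {
  sc <- make_screen_table(rbind(
    score_row(well = "B01", compound = "A", role = "test", n_vulvae = 25,
              n_adults = 10),
    score_row(well = "B02", compound = "B", role = "test", n_vulvae = 1,
              n_adults = 2),
    score_row(well = "B03", compound = "C", role = "test", n_vulvae = 3,
              n_adults = 10),
    score_row(well = "B04", compound = "D", role = "test", n_vulvae = 8,
              n_adults = 10)))
  hits <- call_primary_hits(sc)
  calls <- setNames(hits$calls$status, hits$calls$compound)
  expect_identical(calls[["A"]], "excluded_artifact")  # 25 > 2 x 10
  expect_identical(calls[["B"]], "excluded_toxic")     # 2 < 3
  expect_identical(calls[["C"]], "primary_hit")        # 0.3 < 0.4
  expect_identical(calls[["D"]], "non_hit")            # 0.8 >= 0.4
  expect_identical(hits$summary$pos_control_adult_mean$P1, 10)
  expect_match(hits$calls$reason[hits$calls$compound == "A"], "criterion i:")
  expect_match(hits$calls$reason[hits$calls$compound == "B"], "criterion ii:")
})

test_that("boundary values never trigger the strict inequalities", {
  sc <- make_screen_table(rbind(
    # vulvae exactly 2x the positive-control adults: not an artifact
    score_row(well = "B01", compound = "E1", role = "test", n_vulvae = 20,
              n_adults = 20),
    # adults exactly 30% of the positive control: not toxic
    score_row(well = "B02", compound = "E2", role = "test", n_vulvae = 3,
              n_adults = 3),
    # vulvae/adult exactly 0.4: not a hit
    score_row(well = "B03", compound = "E3", role = "test", n_vulvae = 4,
              n_adults = 10)))
  hits <- call_primary_hits(sc)
  calls <- setNames(hits$calls$status, hits$calls$compound)
  expect_identical(calls[["E1"]], "non_hit")   # 20 = 2x10, va = 1
  expect_identical(calls[["E2"]], "non_hit")   # 3 = 0.3x10, va = 1
  expect_identical(calls[["E3"]], "non_hit")   # va = 0.4 exactly
})

test_that("every compound receives exactly one status and counts sum", {
  set.seed(11)
  test_rows <- do.call(rbind, lapply(1:40, function(i)
    score_row(well = sprintf("C%02d", i), compound = sprintf("X%02d", i),
              role = "test", n_vulvae = rpois(1, 8),
              n_adults = sample(0:20, 1))))
  hits <- call_primary_hits(make_screen_table(test_rows))
  expect_identical(nrow(hits$calls), 40L)
  expect_identical(anyDuplicated(hits$calls$compound), 0L)
  expect_true(all(hits$calls$status %in% c("excluded_artifact",
                                           "excluded_toxic", "primary_hit",
                                           "non_hit")))
  expect_identical(sum(unlist(hits$summary$status_counts)), 40L)
})

test_that("lowering the hit threshold never adds hits", {
  set.seed(12)
  test_rows <- do.call(rbind, lapply(1:30, function(i)
    score_row(well = sprintf("C%02d", i), compound = sprintf("X%02d", i),
              role = "test", n_vulvae = rpois(1, 5), n_adults = 10)))
  sc <- make_screen_table(test_rows)
  hit_sets <- lapply(c(0.8, 0.4, 0.2, 0.05), function(thr) {
    h <- call_primary_hits(sc, screen_config(primary_hit_va_threshold = thr))
    h$calls$compound[h$calls$status == "primary_hit"]
  })
  for (i in 2:length(hit_sets))
    expect_true(all(hit_sets[[i]] %in% hit_sets[[i - 1]]))
})

test_that("a screen without positive controls is refused", {
  sc <- score_row(well = "B01", compound = "A", role = "test",
                  n_vulvae = 1, n_adults = 10)
  expect_error(call_primary_hits(sc), "positive-control")
  # a plate lacking its own positive controls is refused too
  sc2 <- rbind(make_screen_table(sc),
               score_row(plate = "P2", well = "B01", compound = "B",
                         role = "test", n_vulvae = 1, n_adults = 10))
  expect_error(call_primary_hits(sc2), "P2")
})

test_that("an empty test set yields an empty call list with a summary", {
  sc <- make_screen_table(score_row(well = "B01", compound = "A",
                                    role = "test", n_vulvae = 1,
                                    n_adults = 10))
  hits <- call_primary_hits(sc[sc$role != "test", , drop = FALSE])
  expect_identical(nrow(hits$calls), 0L)
  expect_identical(sum(unlist(hits$summary$status_counts)), 0L)
})

test_that("validation keeps compounds rescued at any concentration", {
  val_rows <- function(compound, vas) {
    do.call(rbind, lapply(seq_along(vas), function(j)
      score_row(well = sprintf("%s%02d", LETTERS[j + 1], match(compound, c("ok", "bad"))),
                compound = compound, role = "test",
                n_vulvae = round(vas[j] * 10), n_adults = 10,
                conc_um = c(5, 10, 20)[j])))
  }
  sc <- make_screen_table(rbind(val_rows("ok", c(0.6, 0.3, 0.2)),
                                val_rows("bad", c(0.5, 0.5, 0.5))))
  val <- validate_hits(sc)
  expect_true(val$survives[val$compound == "ok"])
  expect_identical(val$best_conc[val$compound == "ok"], 20)
  expect_equal(val$best_va[val$compound == "ok"], 0.2)
  expect_false(val$survives[val$compound == "bad"])
  expect_match(val$reason[val$compound == "bad"], "all concentrations")
})

test_that("validation removes compounds with no evaluable wells", {
  sc <- make_screen_table(
    score_row(well = "B01", compound = "storm", role = "test",
              n_vulvae = 500, n_adults = 10))
  val <- validate_hits(sc)
  expect_false(val$survives)
  expect_identical(val$reason, "no evaluable wells")
  expect_identical(val$n_evaluable, 0L)
})

test_that("validation averages over experiments before thresholding", {
  sc <- make_screen_table(rbind(
    score_row(well = "B01", compound = "x", role = "test", n_vulvae = 3,
              n_adults = 10, conc_um = 10, experiment = "E1"),
    score_row(well = "B02", compound = "x", role = "test", n_vulvae = 6,
              n_adults = 10, conc_um = 10, experiment = "E2")))
  # experiment means 0.3 and 0.6 average to 0.45 > 0.4: removed
  val <- validate_hits(sc)
  expect_false(val$survives)
  expect_equal(val$best_va, 0.45)
})

test_that("counter-screen classification follows the rule order", {
  counter <- data.frame(
    compound = c("on", "down", "slow"),
    reporter_va = c(0.1, 0.1, 0.1),
    lin1_muv_fraction = c(0.95, 0.2, 1.0),
    lin1_adult_fraction_of_control = c(1.0, 0.9, 0.1))
  calls <- counter_screen_classify(counter, control_muv_fraction = 1.0)
  expect_identical(calls$class,
                   c("on_pathway_hit", "downstream_or_parallel",
                     "indeterminate_growth"))
  # growth rule precedes suppression: a slow well with low Muv is still
  # indeterminate
  counter2 <- data.frame(compound = "both", lin1_muv_fraction = 0.1,
                         lin1_adult_fraction_of_control = 0.05)
  expect_identical(counter_screen_classify(counter2, 1.0)$class,
                   "indeterminate_growth")
  expect_error(counter_screen_classify(counter, NA), "control")
  expect_error(counter_screen_classify(counter[, 1:2], 1.0), "lacks column")
})

test_that("screen thresholds validate and serialize", {
  expect_error(screen_config(primary_hit_va_threshold = 0), "> 0")
  expect_error(screen_config(min_adult_fraction_of_pos = 1.5), "\\(0, 1\\]")
  dir <- withr::local_tempdir()
  sc <- make_screen_table(score_row(well = "B01", compound = "A",
                                    role = "test", n_vulvae = 1,
                                    n_adults = 10))
  hits <- call_primary_hits(sc)
  write_hit_calls(hits, dir)
  j <- jsonlite::read_json(file.path(dir, "hits.json"))
  expect_equal(j$thresholds$primary_hit_va_threshold, 0.4)
  expect_equal(j$thresholds$artifact_vulvae_multiplier, 2)
  summ <- read.csv(file.path(dir, "screen_summary.csv"))
  expect_equal(sum(summ$n), 1)
})
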