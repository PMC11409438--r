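test_that("Z-factor matches the closed form on hand-computed cases", {
  # zero spread, separated means: a perfect assay
  z <- zfactor(c(1, 1, 1), c(0, 0, 0))
  expect_identical(z$z, 1)
  expect_identical(z$interpretation, "excellent")

  # sd exactly 0.1 in both groups, unit separation: z = 1 - 3*0.2/1 = 0.4
  z <- zfactor(c(0.9, 1.0, 1.1), c(-0.1, 0, 0.1))
  expect_equal(z$z, 0.4)
  expect_identical(z$interpretation, "marginal")
  expect_equal(z$neg$mean, 1)
  expect_equal(z$neg$sd, 0.1)
  expect_equal(z$pos$mean, 0)
  expect_equal(z$pos$sd, 0.1)

  expect_identical(zfactor(c(1, 1.2, 0.8), c(0.9, 1.3, 0.5))$interpretation,
                   "unusable")
})

test_that("Z-factor rejects degenerate control groups", {
  expect_error(zfactor(c(1, 1), c(1, 1)), "means are equal")
  expect_error(zfactor(c(1), c(0, 0)), ">= 2")
  expect_error(zfactor(c(1, NA), c(0, 0)), ">= 2")
  expect_error(zfactor(c(1, 1, NA), c(0, 0), na_drop = FALSE), "NA")
})

test_that("Z-factor is invariant under affine rescaling of both groups", {
  set.seed(77)
  for (i in 1:200) {
    neg <- rnorm(6, 1, 0.1)
    pos <- rnorm(6, 0, 0.05)
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    z0 <- zfactor(neg, pos)$z
    z1 <- zfactor(a * neg + b, a * pos + b)$z
    expect_equal(z1, z0, tolerance = 1e-10)
    expect_lte(z0, 1)
  }
})

test_that("Z-factor strictly decreases as control spread grows", {
  neg <- c(0.95, 1.0, 1.05)
  pos <- c(-0.05, 0, 0.05)
  z1 <- zfactor(neg, pos)$z
  z2 <- zfactor(1 + (neg - 1) * 2, pos)$z
  expect_lt(z2, z1)
})

test_that("undefined wells are dropped from control statistics with a count", {
  z <- zfactor(c(1, 1.1, 0.9, NA), c(0, 0.05, NA, NA, -0.05))
  expect_identical(z$neg$n_dropped, 1L)
  expect_identical(z$pos$n_dropped, 2L)
  expect_identical(z$neg$n_wells, 3L)
})

test_that("zfactor_from_scores selects wells by role or compound", {
  sc <- rbind(score_row(well = "A01", compound = "DMSO",
                        role = "negative_control", n_vulvae = 10,
                        n_adults = 10, conc_um = 0),
              score_row(well = "A02", compound = "DMSO",
                        role = "negative_control", n_vulvae = 11,
                        n_adults = 10, conc_um = 0),
              score_row(well = "B01", compound = "trametinib",
                        role = "positive_control", n_vulvae = 0,
                        n_adults = 10),
              score_row(well = "B02", compound = "trametinib",
                        role = "positive_control", n_vulvae = 1,
                        n_adults = 10))
  z1 <- zfactor_from_scores(sc)
  z2 <- zfactor_from_scores(sc, neg = "DMSO", pos = "trametinib")
  expect_equal(z1$z, z2$z)
  expect_error(zfactor_from_scores(sc, metric = "nope"), "unknown metric")
})

test_that("dose-response aggregation is experiment-first", {
  sc <- rbind(
    score_row(well = "A01", compound = "d", role = "test", n_vulvae = 0,
              n_adults = 10, experiment = "E1"),
    score_row(well = "A02", compound = "d", role = "test", n_vulvae = 1,
              n_adults = 10, experiment = "E2"),
    score_row(well = "A03", compound = "d", role = "test", n_vulvae = 2,
              n_adults = 10, experiment = "E3"))
  dr <- aggregate_dose_response(sc)
  expect_identical(nrow(dr), 1L)
  expect_equal(dr$mean_va, 0.1)
  expect_equal(dr$sd_va, 0.1)
  expect_identical(dr$n_experiments, 3L)

  # replicate wells are averaged within experiment before the cross-experiment
  # mean, so an unbalanced experiment does not dominate
  sc2 <- rbind(sc,
    score_row(well = "A04", compound = "d", role = "test", n_vulvae = 10,
              n_adults = 10, experiment = "E3"),
    score_row(well = "A05", compound = "d", role = "test", n_vulvae = 10,
              n_adults = 10, experiment = "E3"))
  dr2 <- aggregate_dose_response(sc2)
  expect_equal(dr2$mean_va, mean(c(0, 0.1, mean(c(0.2, 1, 1)))))
})

test_that("undefined wells and single experiments are handled explicitly", {
  sc <- rbind(
    score_row(well = "A01", compound = "d", role = "test", n_vulvae = 0,
              n_adults = 0, n_larvae = 10),
    score_row(well = "A02", compound = "d", role = "test", n_vulvae = 0,
              n_adults = 0, n_larvae = 8))
  dr <- aggregate_dose_response(sc)
  expect_true(is.na(dr$mean_va))
  expect_identical(dr$n_wells, 0L)
  expect_identical(dr$n_dropped, 2L)

  sc1 <- score_row(well = "A01", compound = "d", role = "test",
                   n_vulvae = 5, n_adults = 10)
  dr1 <- aggregate_dose_response(sc1)
  expect_equal(dr1$mean_va, 0.5)
  expect_true(is.na(dr1$sd_va))
})

test_that("aggregation is invariant to well order", {
  set.seed(5)
  sc <- do.call(rbind, lapply(1:12, function(i)
    score_row(well = sprintf("A%02d", i), compound = sample(c("a", "b"), 1),
              role = "test", n_vulvae = rpois(1, 5), n_adults = 10,
              experiment = sample(c("E1", "E2"), 1))))
  dr1 <- aggregate_dose_response(sc)
  dr2 <- aggregate_dose_response(sc[sample(nrow(sc)), ])
  expect_equal(dr1, dr2)
})

test_that("pipeline-comparison regression matches closed-form OLS", {
  r <- compare_scorings(c(0, 0.5, 1), c(0, 0.5, 1))
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0)
  expect_equal(r$r_squared, 1)

  r <- compare_scorings(c(0, 1, 2), c(0, 2, 4))
  expect_equal(r$slope, 0.5)
  expect_equal(r$r_squared, 1)

  # anti-correlated but collinear: r^2 stays 1, slope -1
  r <- compare_scorings(c(0, 1, 0, 1), c(1, 0, 1, 0))
  expect_equal(r$slope, -1)
  expect_equal(r$r_squared, 1)
})

test_that("regression guards its preconditions", {
  expect_error(compare_scorings(c(1, 2), c(1, 2)), ">= 3")
  expect_error(compare_scorings(c(1, 2, 3), c(2, 2, 2)), "zero variance")
  expect_error(compare_scorings(c(1, 2, 3), c(1, 2)), "paired")
  # NA pairs are dropped before fitting
  r <- compare_scorings(c(0, 1, 2, NA), c(0, 1, 2, 5))
  expect_identical(r$n_points, 3L)
})

test_that("heatmap export pivots the aggregate means faithfully", {
  dir <- withr::local_tempdir()
  sc <- rbind(
    score_row(well = "A01", compound = "a", role = "test", n_vulvae = 2,
              n_adults = 10, conc_um = 5),
    score_row(well = "A02", compound = "a", role = "test", n_vulvae = 4,
              n_adults = 10, conc_um = 10),
    score_row(well = "A03", compound = "b", role = "test", n_vulvae = 6,
              n_adults = 10, conc_um = 5),
    score_row(well = "A04", compound = "b", role = "test", n_vulvae = 8,
              n_adults = 10, conc_um = 10),
    score_row(well = "A05", compound = "a", role = "test", n_vulvae = 0,
              n_adults = 0, conc_um = 20))
  dr <- aggregate_dose_response(sc)
  csv <- file.path(dir, "m.csv")
  m <- heatmap_export(dr, "mean_va", csv = csv)
  expect_identical(dim(m), c(2L, 3L))
  expect_equal(m["a", "5uM"], 0.2)
  expect_equal(m["b", "10uM"], 0.8)
  expect_true(is.na(m["b", "20uM"]))    # missing cell stays missing
  expect_true(file.exists(csv))
  png <- file.path(dir, "m.png")
  heatmap_export(dr, "mean_va", csv = csv, png = png)
  expect_gt(file.info(png)$size, 0)
  expect_error(heatmap_export(dr, "", csv = csv), "unknown metric")
  expect_error(heatmap_export(dr[0, ], "mean_va", csv = csv), "empty")
})
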