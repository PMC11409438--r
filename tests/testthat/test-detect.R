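test_that("a constant raster yields no objects", {
  m <- blank_raster(150)
  expect_identical(nrow(segment_gfp(m)), 0L)
})

test_that("non-finite or empty rasters are rejected", {
  m <- blank_raster(50)
  m[10, 10] <- NA
  expect_error(segment_gfp(m), "non-finite")
  expect_error(segment_gfp(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("one adult with one vulva segments into two gated objects", {
  p <- well_sim_params(n_worms = 1, adult_fraction = 1, vulva_rate_adult = 1,
                       vulva_mode = "fixed", speckle_rate = 0, noise_sd = 0,
                       field_size = 300, seed = 11)
  res <- render_well(p)
  k <- res$truth$worms$field[1]
  obj <- segment_gfp(res$image$fields[[k]]$gfp)
  expect_identical(nrow(obj), 2L)
  cfg <- detection_config()
  lab <- classify_objects(obj, cfg)
  expect_setequal(lab$label, c("adult_pharynx", "vulva"))
  # measured features agree with the simulator's nominal object table
  tt <- res$truth$object_table
  for (cl in c("adult_pharynx", "vulva")) {
    got <- lab[lab$label == cl, ]
    want <- tt[tt$class == cl, ]
    expect_lt(sqrt((got$x - want$x)^2 + (got$y - want$y)^2), 3)
    gate <- cfg$gates[[cl]]
    expect_gte(got$area, gate$area_min)
    expect_lte(got$area, gate$area_max)
    expect_gte(got$peak_intensity, gate$peak_min)
  }
  # the pharynx is the elongated object
  expect_gt(lab$eccentricity[lab$label == "adult_pharynx"],
            lab$eccentricity[lab$label == "vulva"])
})

test_that("two foci closer than the smoothing scale merge into one object", {
  m <- blank_raster(120)
  m <- paint_blob(m, 50, 60, 16000, 1.8)
  m <- paint_blob(m, 55, 60, 16000, 1.8)   # 5 px apart: valley above threshold
  expect_identical(nrow(segment_gfp(m)), 1L)
  m2 <- blank_raster(120)
  m2 <- paint_blob(m2, 40, 60, 16000, 1.8)
  m2 <- paint_blob(m2, 80, 60, 16000, 1.8) # well separated
  expect_identical(nrow(segment_gfp(m2)), 2L)
})

test_that("object count is non-increasing in the segmentation threshold", {
  set.seed(1)
  m <- blank_raster(200)
  centers <- expand.grid(x = c(40, 90, 140, 190) - 10,
                         y = c(40, 90, 140) - 10)   # separated: no merging
  for (i in seq_len(nrow(centers)))
    m <- paint_blob(m, centers$x[i] + runif(1, -5, 5),
                    centers$y[i] + runif(1, -5, 5),
                    runif(1, 4000, 20000), runif(1, 1.5, 4))
  m <- m + rnorm(length(m), 0, 400)
  counts <- vapply(seq(1000, 20000, by = 1000), function(thr) {
    cfg <- detection_config(threshold_mode = "absolute", gfp_threshold = thr,
                            min_object_area = 10)
    nrow(segment_gfp(m, cfg))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("gates are applied in precedence order and labels are exclusive", {
  cfg <- detection_config()
  obj <- data.frame(
    x = 0, y = 0, mean_intensity = 0, eccentricity = 0,
    area          = c(100,   100,  300,  100,   25,    1500),
    peak_intensity = c(13500, 8000, 8000, 2000, 20000, 20000))
  lab <- classify_objects(obj, cfg)$label
  # area 100 fits both vulva and larval gates; bright one goes to vulva first
  expect_identical(lab, c("vulva", "larval_pharynx", "adult_pharynx",
                          "rejected", "rejected", "rejected"))
  expect_identical(nrow(classify_objects(obj[0, ], cfg)), 0L)
})

test_that("misconfigured gates and precedence fail at load time", {
  expect_error(detection_config(gates = list(
    vulva = list(area_min = 50, area_max = 10, peak_min = 1))), "area_min")
  expect_error(detection_config(precedence = c("vulva", "adult_pharynx")),
               "without a precedence")
  expect_error(detection_config(precedence = c("vulva", "vulva",
                                               "adult_pharynx",
                                               "larval_pharynx")),
               "duplicates")
})

test_that("a full noise-free well recovers its labeled counts exactly", {
  p <- well_sim_params(n_worms = 8, adult_fraction = 5 / 8,
                       stage_mode = "fixed", vulva_rate_adult = 1,
                       vulva_mode = "fixed", speckle_rate = 0, noise_sd = 0,
                       seed = 23)
  res <- render_well(p)
  expect_equal(unname(res$truth$true_counts), c(5, 3, 5, 0),
               ignore_attr = TRUE)
  obj <- detect_well(res$image)
  expect_exact_recovery(obj, res$truth)
})

test_that("foci are assigned to containing bodies and Muv flags raised", {
  p <- well_sim_params(n_worms = 1, adult_fraction = 1, vulva_mode = "mixture",
                       muv_fraction = 1, muv_count = 2, speckle_rate = 0,
                       noise_sd = 0, field_size = 300, seed = 7)
  res <- render_well(p)
  cfg <- detection_config(body_detection = TRUE)
  obj <- detect_well(res$image, cfg)
  asg <- assign_foci_to_bodies(obj, res$image, cfg)
  expect_identical(nrow(asg$worms), 1L)
  expect_identical(asg$worms$n_foci, 2L)
  expect_true(asg$worms$muv)
  expect_identical(asg$muv_fraction, 1)
  expect_identical(asg$n_unassigned, 0L)
})

test_that("a focus beyond the assignment radius stays unassigned", {
  m <- blank_raster(200)
  m <- paint_bar(m, 40, 160, 60, 7, 900)          # body
  m <- paint_blob(m, 50, 60, 7000, 5.5)           # adult pharynx on body
  m <- paint_blob(m, 100, 60, 16000, 1.8)         # vulva on body
  m <- paint_blob(m, 100, 150, 16000, 1.8)        # vulva far from any body
  img <- as_well_image(list(m, blank_raster(200), blank_raster(200),
                            blank_raster(200)))
  cfg <- detection_config(body_detection = TRUE)
  obj <- detect_well(img, cfg)
  expect_identical(sum(obj$label == "vulva"), 2L)
  asg <- assign_foci_to_bodies(obj, img, cfg)
  expect_identical(asg$n_unassigned, 1L)
  expect_identical(sum(asg$worms$n_foci), 1L)
  expect_false(any(asg$worms$muv))   # one contained focus: not Muv
})

test_that("body-dependent operations demand body detection", {
  cfg <- detection_config()   # body_detection = FALSE
  img <- as_well_image(lapply(1:4, function(k) blank_raster(50)))
  expect_error(assign_foci_to_bodies(data.frame(), img, cfg), "disabled")
  expect_error(segment_bodies(blank_raster(50), cfg), "disabled")
})

test_that("a lin-1-like well shows full Muv penetrance", {
  p <- well_sim_params(n_worms = 6, adult_fraction = 1,
                       vulva_mode = "mixture", muv_fraction = 1,
                       muv_count = 4, speckle_rate = 0, noise_sd = 0,
                       seed = 31)
  res <- render_well(p)
  expect_true(all(res$truth$worms$n_vulvae == 4))
  cfg <- detection_config(body_detection = TRUE)
  obj <- detect_well(res$image, cfg)
  asg <- assign_foci_to_bodies(obj, res$image, cfg)
  expect_identical(asg$adult_bodies, 6L)
  expect_identical(asg$muv_fraction, 1)
})

test_that("exact recovery holds across many random noise-free wells", {
  for (s in 101:115) {
    p <- well_sim_params(speckle_rate = 0, noise_sd = 0, seed = s)
    res <- render_well(p)
    expect_exact_recovery(detect_well(res$image), res$truth)
  }
})
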