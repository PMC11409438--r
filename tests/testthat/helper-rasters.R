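# Crafted-raster helpers, deliberately independent of the package's own
# rendering code so they can serve as oracles for it.

blank_raster <- function(size = 200, background = 500)
  matrix(background, size, size)

# paint an isotropic Gaussian blob (x = column, y = row), plain R
paint_blob <- function(m, x, y, amp, sigma) {
  xs <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
  ys <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  m + amp * exp(-((xs - x)^2 + (ys - y)^2) / (2 * sigma^2))
}

# paint a horizontal soft-edged bar (a crude worm body)
paint_bar <- function(m, x0, x1, y, halfwidth, amp, edge = 2.5) {
  xs <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
  ys <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  dx <- pmax(pmax(x0 - xs, xs - x1), 0)
  dy <- abs(ys - y)
  d <- pmax(sqrt(dx^2 + dy^2) - halfwidth, 0)
  m + amp * exp(-d^2 / (2 * edge^2))
}

# wrap four field matrices (gfp only; flat bf) into a well_image
as_well_image <- function(fields, plate = "T", well = "A01") {
  structure(list(plate_id = plate, well_id = well, pixel_size = 2.5,
                 fields = lapply(fields, function(f)
                   list(gfp = f, bf = matrix(30000, nrow(f), ncol(f))))),
            class = "well_image")
}

# score-table row builder for decision-layer tests
score_row <- function(plate = "P1", well, compound, role, n_vulvae, n_adults,
                      n_larvae = 0, conc_um = 10, experiment = "E1",
                      genotype = "reporter") {
  va <- if (n_adults > 0) n_vulvae / n_adults else NA_real_
  data.frame(plate = plate, well = well, compound = compound,
             conc_um = conc_um, role = role, experiment = experiment,
             genotype = genotype, n_vulvae = n_vulvae, n_adults = n_adults,
             n_larvae = n_larvae, n_rejected = 0L,
             vulvae_per_adult = va,
             pct_larvae = if (n_adults + n_larvae > 0)
               100 * n_larvae / (n_adults + n_larvae) else NA_real_,
             outlier_flag = isTRUE(va > 1.5), notes = "")
}

counts_by_label <- function(objects) {
  c(vulva = sum(objects$label == "vulva"),
    adult = sum(objects$label == "adult_pharynx"),
    larva = sum(objects$label == "larval_pharynx"),
    rejected = sum(objects$label == "rejected"))
}

expect_exact_recovery <- function(objects, truth) {
  cnt <- counts_by_label(objects)
  tc <- truth$true_counts
  expect_identical(unname(cnt[["vulva"]]), unname(as.integer(tc[["n_vulvae"]])))
  expect_identical(unname(cnt[["adult"]]), unname(as.integer(tc[["n_adults"]])))
  expect_identical(unname(cnt[["larva"]]), unname(as.integer(tc[["n_larvae"]])))
  expect_identical(unname(cnt[["rejected"]]), 0L)
}
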