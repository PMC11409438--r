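#' Planted-truth validation screen design
#'
#' Builds the plate map and per-well simulation parameters for an end-to-end
#' screen of 433 test compounds laid out on five 96-well plates (4 negative-
#' and 4 positive-control wells in column 1 of each plate; spare wells carry
#' extra vehicle controls), with three planted well classes whose parameters
#' place them unambiguously on the far side of the decision thresholds:
#'
#' * 7 suppressors: `vulva_rate_adult = 0.05` (strong vulval-induction
#'   suppression, the screen's true positives);
#' * 20 artifact wells: speckle storms (50 confounder foci per field) that
#'   flood the vulva channel, exercising exclusion criterion (i);
#' * 15 toxic wells: `adult_fraction = 0.05` (almost no animals reach
#'   adulthood), exercising exclusion criterion (ii).
#'
#' Planted suppressor and toxic wells use a fixed worm count (26) and
#' deterministic stage rounding so their separation from the thresholds holds
#' for every seed; unplanted test wells and controls keep the assay's
#' empirical worm-count distribution. Non-artifact wells are speckle-free so
#' artifact exclusion is attributable to the planted storms. Positive
#' controls model the MEK-inhibitor reference compound (7 uM trametinib,
#' vulval induction suppressed); negative controls are vehicle only.
#'
#' @param seed top-level seed; all well parameters derive substreams from it.
#' @param n_compounds,n_suppressors,n_artifact,n_toxic screen composition.
#' @param field_size passed to [well_sim_params()] (smaller fields speed up
#'   reduced-scale runs).
#' @return list with `plate_map`, `params` (named list keyed
#'   `"<plate>:<well>"`), and `planted` (compound sets: suppressor, artifact,
#'   toxic).
#' @export
planted_screen_design <- function(seed = 1, n_compounds = 433,
                                  n_suppressors = 7, n_artifact = 20,
                                  n_toxic = 15, field_size = 600) {
  wells96 <- as.vector(t(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0)))
  test_per_plate <- 88
  n_plates <- ceiling(n_compounds / test_per_plate)

  planted <- with_seed(derive_seed(seed, "planted"), {
    idx <- sample.int(n_compounds, n_suppressors + n_artifact + n_toxic)
    list(suppressor = sprintf("CMP%03d", idx[seq_len(n_suppressors)]),
         artifact = sprintf("CMP%03d",
                            idx[n_suppressors + seq_len(n_artifact)]),
         toxic = sprintf("CMP%03d",
                         idx[n_suppressors + n_artifact + seq_len(n_toxic)]))
  })

  rows <- list(); params <- list()
  compound_i <- 0
  for (p in seq_len(n_plates)) {
    plate <- sprintf("PL%d", p)
    for (w in wells96) {
      row_letter <- substr(w, 1, 1)
      col <- as.integer(substr(w, 2, 3))
      if (col == 1) {
        role <- if (row_letter %in% c("A", "B", "C", "D"))
          "negative_control" else "positive_control"
        compound <- if (role == "negative_control") "DMSO" else "trametinib"
        conc <- if (role == "negative_control") 0 else 7
      } else if (compound_i < n_compounds) {
        compound_i <- compound_i + 1
        role <- "test"; compound <- sprintf("CMP%03d", compound_i); conc <- 10
      } else {
        role <- "negative_control"; compound <- "DMSO"; conc <- 0
      }
      rows[[length(rows) + 1]] <- data.frame(
        plate = plate, well = w, compound = compound, conc_um = conc,
        role = role, experiment = "SCREEN", genotype = "reporter")

      base <- list(seed = derive_seed(seed, plate, w), speckle_rate = 0,
                   field_size = field_size)
      extra <- if (compound %in% planted$suppressor) {
        list(vulva_rate_adult = 0.05, n_worms = 26, stage_mode = "fixed")
      } else if (compound %in% planted$artifact) {
        list(speckle_rate = 50)
      } else if (compound %in% planted$toxic) {
        list(adult_fraction = 0.05, n_worms = 26, stage_mode = "fixed")
      } else if (role == "positive_control") {
        list(vulva_rate_adult = 0.05)
      } else list()
      params[[paste0(plate, ":", w)]] <-
        do.call(well_sim_params, utils::modifyList(base, extra))
    }
  }
  list(plate_map = do.call(rbind, rows), params = params, planted = planted)
}

#' Calibration plate design spanning the assay's dynamic range
#'
#' A 96-well plate whose columns step the expected vulvae-per-adult rate from
#' 0 (full suppression) through 1 (wild type) to just above 2 (Muv-like), 12
#' wells per level, under default imaging noise. Used to measure detection
#' robustness and pipeline-vs-truth agreement across the whole readout range.
#'
#' @param seed top-level seed.
#' @param rates vulva rates assigned to the 8 plate rows.
#' @param speckle_rate confounder rate per field.
#' @param noise_sd imaging noise SD.
#' @param field_size field side length (px).
#' @return list with `plate_map` and `params` as in
#'   [planted_screen_design()].
#' @export
calibration_plate_design <- function(seed = 1,
                                     rates = seq(0, 2.1, by = 0.3),
                                     speckle_rate = 2, noise_sd = 1600,
                                     field_size = 600) {
  stopifnot(length(rates) == 8)
  rows <- list(); params <- list()
  for (r in 1:8) {
    for (col in 1:12) {
      w <- paste0(LETTERS[r], sprintf("%02d", col))
      rows[[length(rows) + 1]] <- data.frame(
        plate = "CAL", well = w, compound = sprintf("RATE%.1f", rates[r]),
        conc_um = 10, role = "test", experiment = "CAL",
        genotype = "reporter")
      params[[paste0("CAL:", w)]] <- well_sim_params(
        vulva_rate_adult = rates[r], speckle_rate = speckle_rate,
        noise_sd = noise_sd, field_size = field_size,
        seed = derive_seed(seed, "CAL", w))
    }
  }
  list(plate_map = do.call(rbind, rows), params = params)
}

#' Counter-screen plate design in a lin-1-like Muv background
#'
#' Simulates the genetic counter-screen: untreated lin-1-like control wells
#' where every adult carries `muv_count` ectopic vulval foci, plus one well
#' per test compound whose planted effect is known: `"on_pathway"` leaves the
#' Muv phenotype intact (Muv fraction about 0.95), `"downstream"` suppresses
#' it (driven to `suppressed_muv`), `"growth"` retards larval growth
#' (adult fraction 0.05).
#'
#' @param compounds named character vector: names are compound ids, values
#'   one of `"on_pathway"`, `"downstream"`, `"growth"`.
#' @param seed top-level seed.
#' @param suppressed_muv Muv fraction planted for downstream-acting compounds.
#' @param n_controls untreated control wells.
#' @param field_size field side length (px).
#' @return list with `plate_map` and `params`.
#' @export
counter_screen_design <- function(compounds, seed = 1, suppressed_muv = 0.2,
                                  n_controls = 4, field_size = 600) {
  rows <- list(); params <- list()
  add <- function(well, compound, conc, role, extra) {
    rows[[length(rows) + 1]] <<- data.frame(
      plate = "LIN1", well = well, compound = compound, conc_um = conc,
      role = role, experiment = "CS", genotype = "lin1")
    base <- list(seed = derive_seed(seed, "LIN1", well), speckle_rate = 0,
                 noise_sd = 0, n_worms = 20, stage_mode = "fixed",
                 vulva_mode = "mixture", field_size = field_size)
    params[[paste0("LIN1:", well)]] <<-
      do.call(well_sim_params, utils::modifyList(base, extra))
  }
  for (i in seq_len(n_controls))
    add(paste0(LETTERS[i], "01"), "DMSO", 0, "negative_control",
        list(muv_fraction = 1))
  for (i in seq_along(compounds)) {
    extra <- switch(compounds[[i]],
      on_pathway = list(muv_fraction = 0.95),
      downstream = list(muv_fraction = suppressed_muv),
      growth = list(muv_fraction = 1, adult_fraction = 0.05),
      stop_ws("unknown planted effect: ", compounds[[i]]))
    add(paste0(LETTERS[i %% 8 + 1], sprintf("%02d", i %/% 8 + 2)),
        names(compounds)[i], 10, "test", extra)
  }
  list(plate_map = do.call(rbind, rows), params = params)
}

#' Score a simulated plate end to end, in memory
#'
#' Renders each well of a design, detects and classifies objects, and scores
#' wells without touching the file system. Convenience wrapper used by the
#' statistics examples and tests; the CLI path exercises the TIFF round trip
#' instead.
#'
#' @param design list with `plate_map` and `params` (as returned by the
#'   design builders).
#' @param config a [detection_config()].
#' @param keep_truth also return ground truths and raw detections.
#' @return a score table ([score_plate()] schema); if `keep_truth`, a list
#'   with `scores`, `truths`, `detections`.
#' @export
simulate_and_score <- function(design, config = detection_config(),
                               keep_truth = FALSE) {
  pm <- validate_plate_map(design$plate_map)
  objects <- list(); truths <- list()
  for (i in seq_len(nrow(pm))) {
    key <- paste0(pm$plate[i], ":", pm$well[i])
    res <- render_well(design$params[[key]], plate_id = pm$plate[i],
                       well_id = pm$well[i])
    objects[[i]] <- detect_well(res$image, config)
    if (keep_truth) truths[[key]] <- res$truth
  }
  scores <- score_plate(do.call(rbind, objects), pm)
  if (keep_truth)
    list(scores = scores, truths = truths,
         detections = do.call(rbind, objects))
  else scores
}

#' Flatten a design's per-well parameters into a CSV-ready override table
#'
#' Produces the `--paramtable` companion of a design's plate map, so the CLI
#' `simulate` subcommand reproduces exactly the wells the in-memory design
#' describes (seeds are re-derived from the run seed per plate and well).
#'
#' @param design a design list with `plate_map` and `params`.
#' @return data frame with plate, well and the scalar simulation fields.
#' @export
design_param_table <- function(design) {
  pm <- design$plate_map
  fields <- c("n_worms", "adult_fraction", "stage_mode", "vulva_rate_adult",
              "vulva_mode", "muv_fraction", "muv_count", "max_vulvae",
              "speckle_rate", "noise_sd", "background_level", "field_size")
  rows <- lapply(seq_len(nrow(pm)), function(i) {
    p <- design$params[[paste0(pm$plate[i], ":", pm$well[i])]]
    vals <- lapply(fields, function(f) if (is.null(p[[f]])) NA else p[[f]])
    names(vals) <- fields
    cbind(data.frame(plate = pm$plate[i], well = pm$well[i]),
          as.data.frame(vals, stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
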