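#' Score one well from labeled detections
#'
#' Reduces a well's labeled objects to the assay's two readouts: vulvae per
#' adult (MAPK/ERK pathway activity) and percent larvae (putative toxicity).
#' Counts are sums over the well's four fields. Degenerate wells (no adults,
#' or no animals at all) produce `NA` markers with an explanatory note, never
#' a silent zero. Wells averaging more than 1.5 vulvae per adult are flagged
#' as outliers for manual inspection.
#'
#' @param objects labeled object data frame for one well ([detect_well()]),
#'   or `NULL`/empty for an empty well.
#' @param well_id,plate_id identifiers for the output row.
#' @return one-row data frame: plate, well, n_vulvae, n_adults, n_larvae,
#'   n_rejected, vulvae_per_adult, pct_larvae, outlier_flag, notes.
#' @export
score_well <- function(objects = NULL, well_id = "A01", plate_id = "P1") {
  lab <- if (is.null(objects) || !nrow(objects)) character(0) else objects$label
  score_from_counts(n_vulvae = sum(lab == "vulva"),
                    n_adults = sum(lab == "adult_pharynx"),
                    n_larvae = sum(lab == "larval_pharynx"),
                    n_rejected = sum(lab == "rejected"),
                    well_id = well_id, plate_id = plate_id)
}

#' @rdname score_well
#' @param n_vulvae,n_adults,n_larvae,n_rejected class counts for the well.
#' @export
score_from_counts <- function(n_vulvae, n_adults, n_larvae, n_rejected = 0,
                              well_id = "A01", plate_id = "P1") {
  for (v in c(n_vulvae, n_adults, n_larvae, n_rejected))
    if (!is_count(v)) stop_ws("counts must be non-negative integers")
  notes <- character(0)
  va <- if (n_adults > 0) n_vulvae / n_adults else {
    notes <- c(notes, "no adults: vulvae/adult undefined")
    NA_real_
  }
  n_animals <- n_adults + n_larvae
  pct <- if (n_animals > 0) 100 * n_larvae / n_animals else {
    notes <- c(notes, "no animals: percent larvae undefined")
    NA_real_
  }
  outlier <- isTRUE(va > 1.5)
  if (outlier) notes <- c(notes, ">1.5 vulvae/adult: inspect for artifacts")
  data.frame(plate = plate_id, well = well_id,
             n_vulvae = as.integer(n_vulvae), n_adults = as.integer(n_adults),
             n_larvae = as.integer(n_larvae),
             n_rejected = as.integer(n_rejected),
             vulvae_per_adult = va, pct_larvae = pct,
             outlier_flag = outlier,
             notes = paste(notes, collapse = "; "))
}

#' Score every well of a plate and join the plate map
#'
#' @param objects labeled object data frame for the whole plate (with `plate`
#'   and `well` columns), or a path to such a CSV.
#' @param plate_map plate map data frame or CSV path (see [read_plate_map()]).
#'   Wells in the map with no detected objects score zero counts; objects in
#'   wells absent from the map are a hard error.
#' @param drop_outliers remove wells flagged `outlier_flag` (the default keeps
#'   and flags them; removal mirrors manual artifact triage).
#' @return data frame, one row per plate-map well, ordered by (plate, well):
#'   plate map columns joined to the [score_well()] columns.
#' @export
score_plate <- function(objects, plate_map, drop_outliers = FALSE) {
  if (is.character(objects)) objects <- read.csv(objects, stringsAsFactors = FALSE)
  if (is.character(plate_map)) plate_map <- read_plate_map(plate_map)
  plate_map <- validate_plate_map(plate_map)

  okey <- unique(paste(objects$plate, objects$well))
  mkey <- paste(plate_map$plate, plate_map$well)
  orphan <- setdiff(okey, mkey)
  if (length(orphan))
    stop_ws("scored well(s) missing from plate map: ",
            paste(orphan, collapse = ", "))

  plate_map <- plate_map[order(plate_map$plate, plate_map$well), , drop = FALSE]
  rows <- lapply(seq_len(nrow(plate_map)), function(i) {
    pm <- plate_map[i, ]
    obj <- objects[objects$plate == pm$plate & objects$well == pm$well, ,
                   drop = FALSE]
    sc <- score_well(obj, well_id = pm$well, plate_id = pm$plate)
    cbind(pm[c("plate", "well", "compound", "conc_um", "role", "experiment",
               "genotype")],
          sc[c("n_vulvae", "n_adults", "n_larvae", "n_rejected",
               "vulvae_per_adult", "pct_larvae", "outlier_flag", "notes")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (drop_outliers) out <- out[!out$outlier_flag, , drop = FALSE]
  out
}

#' Write a well-score table to CSV with empty cells for undefined values
#'
#' @param scores data frame from [score_plate()].
#' @param path output CSV path.
#' @export
write_scores <- function(scores, path) {
  write.csv(scores, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a well-score CSV written by [write_scores()]
#'
#' @param path CSV path.
#' @return score data frame with `NA` for empty (undefined) cells.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop_ws("score file not found: ", path)
  sc <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(notes = "character"))
  sc$outlier_flag <- as.logical(sc$outlier_flag)
  sc
}
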