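PLATE_ROLES <- c("negative_control", "positive_control", "test")

#' Read and validate a plate map CSV
#'
#' A plate map assigns each well a compound, concentration and role. Required
#' columns: `plate`, `well`, `compound`, `conc_um`, `role` (one of
#' `negative_control`, `positive_control`, `test`). Optional columns
#' `experiment` (default `"E1"`) and `genotype` (default `"reporter"`) are
#' added if absent, so reporter-strain and counter-screen runs share one
#' schema.
#'
#' @param path CSV file path.
#' @return a validated plate map data frame.
#' @export
read_plate_map <- function(path) {
  if (!file.exists(path)) stop_ws("plate map file not found: ", path)
  pm <- read.csv(path, stringsAsFactors = FALSE)
  validate_plate_map(pm)
}

#' @rdname read_plate_map
#' @param pm a plate map data frame to validate in memory.
#' @export
validate_plate_map <- function(pm) {
  required <- c("plate", "well", "compound", "conc_um", "role")
  missing <- setdiff(required, names(pm))
  if (length(missing))
    stop_ws("plate map is missing column(s): ", paste(missing, collapse = ", "))
  if (!"experiment" %in% names(pm)) pm$experiment <- "E1"
  if (!"genotype" %in% names(pm)) pm$genotype <- "reporter"
  key <- paste(pm$plate, pm$well)
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop_ws("duplicate well(s) in plate map: ", paste(dups, collapse = ", "))
  }
  bad_role <- !pm$role %in% PLATE_ROLES
  if (any(bad_role)) {
    i <- which(bad_role)[1]
    stop_ws("unknown role '", pm$role[i], "' in plate map row ", i,
            " (", pm$plate[i], " ", pm$well[i], "); expected one of: ",
            paste(PLATE_ROLES, collapse = ", "))
  }
  pm$conc_um <- as.numeric(pm$conc_um)
  if (any(!is.finite(pm$conc_um)) || any(pm$conc_um < 0)) {
    i <- which(!is.finite(pm$conc_um) | pm$conc_um < 0)[1]
    stop_ws("invalid concentration in plate map row ", i,
            " (", pm$plate[i], " ", pm$well[i], ")")
  }
  neg_bad <- pm$role == "negative_control" & pm$conc_um != 0
  if (any(neg_bad)) {
    i <- which(neg_bad)[1]
    stop_ws("negative-control well ", pm$plate[i], " ", pm$well[i],
            " must have concentration 0 (vehicle only)")
  }
  pm
}
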