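DETECT_CLASSES <- c("vulva", "adult_pharynx", "larval_pharynx")

#' Detection and classification configuration
#'
#' Gates and thresholds for segmenting GFP objects and sorting them into the
#' three counted classes: vulva-sized foci, adult-sized pharynges and
#' non-adult-sized pharynges (everything else is `rejected`). Gates may
#' overlap in area; classification applies them in `precedence` order and the
#' first match wins, so vulval foci (the brightest, most compact class) are
#' claimed before the pharynx gates see them.
#'
#' @param threshold_mode `"background_relative"` sets the segmentation
#'   threshold to `gfp_threshold` times the field median (robust to the
#'   background level); `"absolute"` uses `gfp_threshold` intensity units.
#' @param gfp_threshold threshold value, units per `threshold_mode`.
#' @param smooth_sigma Gaussian blur sigma (px) applied before thresholding to
#'   suppress pixel noise; object features are measured on the original
#'   intensities.
#' @param min_object_area smallest component area (px^2) kept.
#' @param gates named list of class gates, each `list(area_min, area_max,
#'   peak_min)`.
#' @param precedence class evaluation order; must cover every gated class.
#' @param body_detection enable autofluorescent body segmentation (needed for
#'   focus-to-worm assignment in the counter-screen).
#' @param body_threshold body segmentation threshold as a multiple of the
#'   field median.
#' @param min_body_area smallest body component (px^2) kept; excludes stray
#'   bright foci that are not animals.
#' @param assignment_radius maximum distance (px) from a focus centroid to a
#'   body mask for nearest-body assignment.
#' @return a validated list of class `detection_config`.
#' @export
detection_config <- function(threshold_mode = c("background_relative", "absolute"),
                             gfp_threshold = 4,
                             smooth_sigma = 1,
                             min_object_area = 20,
                             gates = list(
                               vulva = list(area_min = 30, area_max = 250, peak_min = 13000),
                               adult_pharynx = list(area_min = 250, area_max = 900, peak_min = 7500),
                               larval_pharynx = list(area_min = 40, area_max = 220, peak_min = 7500)),
                             precedence = c("vulva", "adult_pharynx", "larval_pharynx"),
                             body_detection = FALSE,
                             body_threshold = 1.6,
                             min_body_area = 300,
                             assignment_radius = 12) {
  threshold_mode <- match.arg(threshold_mode)
  cfg <- list(threshold_mode = threshold_mode, gfp_threshold = gfp_threshold,
              smooth_sigma = smooth_sigma, min_object_area = min_object_area,
              gates = gates, precedence = precedence,
              body_detection = body_detection, body_threshold = body_threshold,
              min_body_area = min_body_area,
              assignment_radius = assignment_radius)
  class(cfg) <- "detection_config"
  validate_detection_config(cfg)
  cfg
}

validate_detection_config <- function(cfg) {
  if (cfg$gfp_threshold <= 0) stop_ws("gfp_threshold must be positive")
  if (cfg$min_object_area < 1) stop_ws("min_object_area must be >= 1")
  for (nm in names(cfg$gates)) {
    gt <- cfg$gates[[nm]]
    if (!all(c("area_min", "area_max", "peak_min") %in% names(gt)))
      stop_ws("gate '", nm, "' must define area_min, area_max, peak_min")
    if (gt$area_min >= gt$area_max)
      stop_ws("gate '", nm, "': area_min must be < area_max")
  }
  if (anyDuplicated(cfg$precedence))
    stop_ws("gate precedence contains duplicates")
  missing <- setdiff(names(cfg$gates), cfg$precedence)
  if (length(missing))
    stop_ws("gates without a precedence position (overlapping gates need a ",
            "total order): ", paste(missing, collapse = ", "))
  unknown <- setdiff(cfg$precedence, names(cfg$gates))
  if (length(unknown))
    stop_ws("precedence names classes with no gate: ",
            paste(unknown, collapse = ", "))
  invisible(cfg)
}

#' @export
print.detection_config <- function(x, ...) {
  cat("Detection configuration\n",
      "  threshold: ", x$gfp_threshold,
      if (x$threshold_mode == "background_relative") " x field median"
      else " (absolute)",
      ", smoothing sigma ", x$smooth_sigma, " px, min area ",
      x$min_object_area, " px^2\n", sep = "")
  for (nm in x$precedence) {
    gt <- x$gates[[nm]]
    cat(sprintf("  %-15s area [%g, %g] px^2, peak >= %g\n", nm,
                gt$area_min, gt$area_max, gt$peak_min))
  }
  cat("  body detection:", if (x$body_detection) "on" else "off", "\n")
  invisible(x)
}

# separable Gaussian blur with edge replication (compiled kernel)
gaussian_blur <- function(m, sigma) blur_sep_cpp(m, sigma)

segmentation_threshold <- function(raster, cfg) {
  switch(cfg$threshold_mode,
         absolute = cfg$gfp_threshold,
         background_relative = cfg$gfp_threshold * median(raster))
}

# label a thresholded raster and measure per-component features on the
# original intensities; components below min_area are dropped
measure_components <- function(raster, mask, min_area) {
  lab <- EBImage::bwlabel(mask)
  idx <- which(lab > 0)
  empty <- data.frame(x = numeric(0), y = numeric(0), area = numeric(0),
                      peak_intensity = numeric(0), mean_intensity = numeric(0),
                      eccentricity = numeric(0))
  if (!length(idx)) return(empty)
  l <- lab[idx]
  vals <- raster[idx]
  rows <- ((idx - 1) %% nrow(raster)) + 1
  cols <- ((idx - 1) %/% nrow(raster)) + 1
  area <- tabulate(l)
  keep <- which(area >= min_area)
  if (!length(keep)) return(empty)
  peak <- vapply(split(vals, l), max, numeric(1))
  meanv <- vapply(split(vals, l), mean, numeric(1))
  cx <- vapply(split(cols, l), mean, numeric(1))
  cy <- vapply(split(rows, l), mean, numeric(1))
  ecc <- vapply(seq_along(area), function(j) {
    sel <- l == j
    dx <- cols[sel] - cx[j]; dy <- rows[sel] - cy[j]
    mu20 <- mean(dx^2); mu02 <- mean(dy^2); mu11 <- mean(dx * dy)
    tr <- mu20 + mu02
    det <- mu20 * mu02 - mu11^2
    disc <- sqrt(max(tr^2 / 4 - det, 0))
    l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
    if (l1 <= 0) 0 else sqrt(max(1 - l2 / l1, 0))
  }, numeric(1))
  data.frame(x = cx, y = cy, area = area, peak_intensity = peak,
             mean_intensity = meanv, eccentricity = ecc)[keep, , drop = FALSE]
}

#' Segment GFP objects in one field
#'
#' Smooths the raster, thresholds it, labels connected components and measures
#' features (centroid, area, peak/mean intensity, eccentricity) from the
#' original, unsmoothed intensities.
#'
#' @param raster 2-D numeric matrix of GFP intensities.
#' @param config a [detection_config()].
#' @return data frame of unlabeled objects, one row per component of area at
#'   least `min_object_area`.
#' @export
segment_gfp <- function(raster, config = detection_config()) {
  if (!is.matrix(raster) || length(raster) == 0)
    stop_ws("raster must be a non-empty numeric matrix")
  if (any(!is.finite(raster)))
    stop_ws("raster contains non-finite pixels")
  raster <- matrix(as.numeric(raster), nrow(raster), ncol(raster))
  thr <- segmentation_threshold(raster, config)
  sm <- if (config$smooth_sigma > 0)
    gaussian_blur(raster, config$smooth_sigma) else raster
  measure_components(raster, sm > thr, config$min_object_area)
}

gate_matches <- function(objects, gate) {
  objects$area >= gate$area_min & objects$area <= gate$area_max &
    objects$peak_intensity >= gate$peak_min
}

#' Classify segmented objects into the three counted classes
#'
#' Applies the class gates in precedence order; each object receives the label
#' of the first gate it satisfies, or `rejected`.
#'
#' @param objects data frame from [segment_gfp()].
#' @param config a [detection_config()].
#' @return `objects` with a `label` column.
#' @export
classify_objects <- function(objects, config = detection_config()) {
  validate_detection_config(config)
  label <- rep("rejected", nrow(objects))
  unset <- rep(TRUE, nrow(objects))
  for (nm in config$precedence) {
    hit <- unset & gate_matches(objects, config$gates[[nm]])
    label[hit] <- nm
    unset <- unset & !hit
  }
  objects$label <- label
  objects
}

#' Detect and classify all GFP objects in a well
#'
#' Runs [segment_gfp()] and [classify_objects()] on each of the four fields
#' and combines the results.
#'
#' @param well a `well_image`.
#' @param config a [detection_config()].
#' @return data frame with columns plate, well, field, label, x, y, area,
#'   peak, mean, eccentricity.
#' @export
detect_well <- function(well, config = detection_config()) {
  out <- lapply(seq_along(well$fields), function(k) {
    obj <- classify_objects(segment_gfp(well$fields[[k]]$gfp, config), config)
    if (!nrow(obj)) return(NULL)
    data.frame(plate = well$plate_id, well = well$well_id, field = k,
               label = obj$label, x = obj$x, y = obj$y, area = obj$area,
               peak = obj$peak_intensity, mean = obj$mean_intensity,
               eccentricity = obj$eccentricity)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(plate = character(0), well = character(0),
                      field = integer(0), label = character(0),
                      x = numeric(0), y = numeric(0), area = numeric(0),
                      peak = numeric(0), mean = numeric(0),
                      eccentricity = numeric(0))
  out
}

#' Segment autofluorescent worm bodies in one field
#'
#' Bodies are the dim, elongated autofluorescent silhouettes; segmenting them
#' at a low threshold yields one mask per animal (bright organs are contained
#' within their body mask). Used for focus-to-worm assignment.
#'
#' @param raster GFP field matrix.
#' @param config a [detection_config()] with `body_detection = TRUE`.
#' @return list with `labels` (integer label matrix) and `bodies` (data frame
#'   body, x, y, area).
#' @export
segment_bodies <- function(raster, config = detection_config(body_detection = TRUE)) {
  if (!isTRUE(config$body_detection))
    stop_ws("body detection is disabled in this configuration")
  raster <- matrix(as.numeric(raster), nrow(raster), ncol(raster))
  thr <- config$body_threshold * median(raster)
  sm <- if (config$smooth_sigma > 0)
    gaussian_blur(raster, config$smooth_sigma) else raster
  lab <- EBImage::bwlabel(sm > thr)
  area <- tabulate(lab[lab > 0])
  keep <- which(area >= config$min_body_area)
  # relabel kept bodies 1..n, zero out the rest
  map <- integer(length(area))
  map[keep] <- seq_along(keep)
  lab[lab > 0] <- map[lab[lab > 0]]
  bodies <- if (length(keep)) {
    idx <- which(lab > 0)
    l <- lab[idx]
    rows <- ((idx - 1) %% nrow(lab)) + 1
    cols <- ((idx - 1) %/% nrow(lab)) + 1
    data.frame(body = seq_along(keep),
               x = vapply(split(cols, l), mean, numeric(1)),
               y = vapply(split(rows, l), mean, numeric(1)),
               area = area[keep])
  } else data.frame(body = integer(0), x = numeric(0), y = numeric(0),
                    area = numeric(0))
  list(labels = lab, bodies = bodies)
}

# body label at/near a point: containment first, else nearest body pixel
# within `radius`
body_at <- function(labels, x, y, radius) {
  nr <- nrow(labels); nc <- ncol(labels)
  r0 <- min(max(round(y), 1), nr); c0 <- min(max(round(x), 1), nc)
  if (labels[r0, c0] > 0) return(labels[r0, c0])
  r <- ceiling(radius)
  rows <- max(1, r0 - r):min(nr, r0 + r)
  cols <- max(1, c0 - r):min(nc, c0 + r)
  win <- labels[rows, cols, drop = FALSE]
  idx <- which(win > 0)
  if (!length(idx)) return(0L)
  wr <- ((idx - 1) %% nrow(win)) + 1
  wc <- ((idx - 1) %/% nrow(win)) + 1
  d2 <- (rows[wr] - y)^2 + (cols[wc] - x)^2
  j <- which.min(d2)
  if (sqrt(d2[j]) > radius) return(0L)
  win[idx[j]]
}

#' Assign vulval foci to worm bodies and flag Muv animals
#'
#' Each vulva-labeled focus is assigned to the body mask containing its
#' centroid, or to the nearest body within `assignment_radius`; unassigned
#' foci stay in the well total but belong to no worm. A body is called adult
#' if it contains an adult-pharynx object; an adult body with two or more
#' assigned foci is flagged Muv (multivulva).
#'
#' @param objects labeled objects for one well (from [detect_well()]).
#' @param well the `well_image` (bodies are segmented per field from GFP).
#' @param config a [detection_config()] with `body_detection = TRUE`.
#' @return list with `worms` (field, body, is_adult, n_foci, muv),
#'   `n_unassigned` focus count, `muv_fraction` (share of adult bodies that
#'   are Muv; `NA` if no adult bodies) and `adult_bodies`.
#' @export
assign_foci_to_bodies <- function(objects, well, config = detection_config(body_detection = TRUE)) {
  if (!isTRUE(config$body_detection))
    stop_ws("body detection is disabled in this configuration")
  worms <- list(); n_unassigned <- 0L
  for (k in seq_along(well$fields)) {
    seg <- segment_bodies(well$fields[[k]]$gfp, config)
    if (!nrow(seg$bodies)) next
    obj_k <- objects[objects$field == k, , drop = FALSE]
    n_foci <- integer(nrow(seg$bodies))
    has_adult_ph <- logical(nrow(seg$bodies))
    for (j in seq_len(nrow(obj_k))) {
      b <- body_at(seg$labels, obj_k$x[j], obj_k$y[j], config$assignment_radius)
      if (obj_k$label[j] == "vulva") {
        if (b > 0) n_foci[b] <- n_foci[b] + 1L else n_unassigned <- n_unassigned + 1L
      } else if (obj_k$label[j] == "adult_pharynx" && b > 0) {
        has_adult_ph[b] <- TRUE
      }
    }
    worms[[k]] <- data.frame(field = k, body = seg$bodies$body,
                             is_adult = has_adult_ph, n_foci = n_foci,
                             muv = has_adult_ph & n_foci >= 2L)
  }
  worms <- if (length(worms)) do.call(rbind, worms) else
    data.frame(field = integer(0), body = integer(0), is_adult = logical(0),
               n_foci = integer(0), muv = logical(0))
  n_adult <- sum(worms$is_adult)
  list(worms = worms, n_unassigned = n_unassigned,
       muv_fraction = if (n_adult > 0) sum(worms$muv) / n_adult else NA_real_,
       adult_bodies = n_adult)
}
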