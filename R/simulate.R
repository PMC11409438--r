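#' Rendering geometry for synthetic worms
#'
#' Constants controlling how simulated animals and confounders are drawn.
#' Lengths and widths are in pixels at the default scale of 2.5 um/px; all
#' intensities are arbitrary units on a 16-bit scale. Adults and larvae carry a
#' dim autofluorescent capsule body, a bright two-lobed pharyngeal GFP blob at
#' one body end whose size scales with life stage, and (adults only) zero or
#' more compact, very bright vulval GFP foci at mid-body. The amplitude ladder
#' (vulval focus > pharynx > body > background) and the size ranges are chosen
#' so that, in noise-free renders, the pixel-area and peak-intensity
#' distributions of the three countable object classes are disjoint and sit
#' well inside the default detection gates (see [detection_config()]).
#'
#' @param adult_length,adult_width,larva_length,larva_width ranges (px) for
#'   body capsule dimensions, sampled uniformly per worm.
#' @param body_amp_adult,body_amp_larva peak autofluorescence amplitude of the
#'   body above background.
#' @param body_edge_sigma softness (px) of the capsule edge falloff.
#' @param pharynx_amp_adult,pharynx_amp_larva pharyngeal GFP amplitude.
#' @param pharynx_sigma_adult,pharynx_sigma_larva range of the Gaussian lobe
#'   scale (px) of the pharynx, sampled per worm.
#' @param pharynx_lobe_ratio relative amplitude of the second (posterior) lobe.
#' @param pharynx_lobe_sep separation of the two lobes in units of lobe sigma.
#' @param pharynx_end_offset distance (px) of the first lobe from the body tip.
#' @param vulva_amp vulval focus amplitude (>= 2x pharynx amplitude).
#' @param vulva_sigma range of the vulval focus Gaussian sigma (px).
#' @param vulva_spacing minimum spacing (px) between foci on one worm.
#' @param speckle_amp,speckle_sigma ranges for confounder foci, which overlap
#'   the vulval gate in both area and peak by design.
#' @param placement_margin minimum surface-to-surface gap (px) between bodies.
#' @param bright_min_sep minimum distance (px) between bright-object centres of
#'   different worms, guaranteeing their masks never merge.
#' @param max_place_attempts placement attempts per worm before a hard
#'   placement-failure error.
#' @return a named list of class `worm_geometry`.
#' @export
worm_geometry <- function(adult_length = c(120, 170), adult_width = c(11, 15),
                          larva_length = c(50, 90), larva_width = c(5, 8),
                          body_amp_adult = 900, body_amp_larva = 700,
                          body_edge_sigma = 2.5,
                          pharynx_amp_adult = 7000, pharynx_amp_larva = 5500,
                          pharynx_sigma_adult = c(5.0, 6.2),
                          pharynx_sigma_larva = c(2.8, 3.2),
                          pharynx_lobe_ratio = 0.8, pharynx_lobe_sep = 1.6,
                          pharynx_end_offset = 6,
                          vulva_amp = 16000, vulva_sigma = c(1.6, 1.95),
                          vulva_spacing = 15,
                          speckle_amp = c(13500, 26000),
                          speckle_sigma = c(1.7, 2.4),
                          placement_margin = 10, bright_min_sep = 34,
                          max_place_attempts = 2000) {
  g <- as.list(environment())
  class(g) <- "worm_geometry"
  g
}

#' Simulation parameters for one well
#'
#' Defines the stochastic composition of a simulated well: how many animals it
#' holds, their stage mix, the per-adult vulval focus count, confounder rate,
#' and imaging noise. With a fixed `seed`, rendering is fully deterministic
#' (byte-identical TIFF output).
#'
#' @param n_worms fixed worm count, or `NULL` to draw from a normal
#'   distribution with `n_worms_mean`/`n_worms_sd` clipped to `n_worms_range`
#'   (defaults follow the assay's per-well dispensing statistics: mean 25.5,
#'   SD 7.4, range 5-66).
#' @param n_worms_mean,n_worms_sd,n_worms_range worm-count distribution.
#' @param adult_fraction probability that a worm is an adult.
#' @param stage_mode `"binomial"` draws each worm's stage independently;
#'   `"fixed"` assigns exactly `round(adult_fraction * n_worms)` adults.
#' @param vulva_rate_adult expected vulval foci per adult (about 1 in wild
#'   type, about 0 under full pathway suppression, > 2 in Muv genotypes).
#' @param vulva_mode `"poisson"` draws per-adult counts as Poisson(rate)
#'   truncated at `max_vulvae`; `"fixed"` gives every adult exactly
#'   `round(vulva_rate_adult)` foci; `"mixture"` gives a `muv_fraction` of
#'   adults `muv_count` foci and the rest one focus (a lin-1-like genotype).
#' @param muv_fraction,muv_count mixture-mode parameters.
#' @param max_vulvae cap on per-adult focus count (geometry limits apply too).
#' @param speckle_rate expected confounder foci per field (Poisson).
#' @param noise_sd additive Gaussian pixel noise SD, intensity units. The
#'   default equals 10 percent of the vulval focus amplitude.
#' @param background_level constant background intensity.
#' @param seed integer; fully determines the render.
#' @param field_size side length (px) of each of the four square fields.
#' @param pixel_size microns per pixel (metadata only).
#' @param geometry a [worm_geometry()] list.
#' @return a validated list of class `well_sim_params`.
#' @export
well_sim_params <- function(n_worms = NULL,
                            n_worms_mean = 25.5, n_worms_sd = 7.4,
                            n_worms_range = c(5, 66),
                            adult_fraction = 0.8,
                            stage_mode = c("binomial", "fixed"),
                            vulva_rate_adult = 1.0,
                            vulva_mode = c("poisson", "fixed", "mixture"),
                            muv_fraction = 0, muv_count = 4, max_vulvae = 6,
                            speckle_rate = 0.5,
                            noise_sd = 1600,
                            background_level = 500,
                            seed = 1L,
                            field_size = 600L, pixel_size = 2.5,
                            geometry = worm_geometry()) {
  stage_mode <- match.arg(stage_mode)
  vulva_mode <- match.arg(vulva_mode)
  p <- list(n_worms = n_worms, n_worms_mean = n_worms_mean,
            n_worms_sd = n_worms_sd, n_worms_range = n_worms_range,
            adult_fraction = adult_fraction, stage_mode = stage_mode,
            vulva_rate_adult = vulva_rate_adult, vulva_mode = vulva_mode,
            muv_fraction = muv_fraction, muv_count = muv_count,
            max_vulvae = max_vulvae, speckle_rate = speckle_rate,
            noise_sd = noise_sd, background_level = background_level,
            seed = as.integer(seed), field_size = as.integer(field_size),
            pixel_size = pixel_size, geometry = geometry)
  class(p) <- "well_sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  if (!is.null(p$n_worms) && !is_count(p$n_worms))
    stop_ws("n_worms must be NULL or a non-negative integer")
  if (p$adult_fraction < 0 || p$adult_fraction > 1)
    stop_ws("adult_fraction must be in [0, 1]")
  if (p$muv_fraction < 0 || p$muv_fraction > 1)
    stop_ws("muv_fraction must be in [0, 1]")
  for (f in c("vulva_rate_adult", "speckle_rate", "noise_sd"))
    if (p[[f]] < 0) stop_ws(f, " must be >= 0")
  if (p$field_size <= 0) stop_ws("field_size must be positive")
  if (p$background_level < 0 || p$background_level > 65535)
    stop_ws("background_level must be on the 16-bit scale")
  invisible(p)
}

#' @export
print.well_sim_params <- function(x, ...) {
  nw <- if (is.null(x$n_worms))
    sprintf("~N(%.1f, %.1f) in [%d, %d]", x$n_worms_mean, x$n_worms_sd,
            x$n_worms_range[1], x$n_worms_range[2])
  else as.character(x$n_worms)
  cat("Well simulation parameters\n",
      "  worms: ", nw, " (adult fraction ", x$adult_fraction, ", ",
      x$stage_mode, ")\n",
      "  vulvae/adult: ", x$vulva_rate_adult, " (", x$vulva_mode, ")\n",
      "  speckles/field: ", x$speckle_rate, ", noise SD: ", x$noise_sd,
      ", background: ", x$background_level, "\n",
      "  fields: 4 x ", x$field_size, "x", x$field_size, " px @ ",
      x$pixel_size, " um/px, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

# distance from grid points (px, py) to the segment (x0,y0)-(x1,y1)
dist_to_segment <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0; dy <- y1 - y0
  L2 <- dx * dx + dy * dy
  if (L2 == 0) return(sqrt((px - x0)^2 + (py - y0)^2))
  t <- ((px - x0) * dx + (py - y0) * dy) / L2
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - x0 - t * dx)^2 + (py - y0 - t * dy)^2)
}

# minimum distance between two segments (exact for non-intersecting segments;
# 0 if they intersect)
seg_seg_dist <- function(a, b) {
  d1 <- (a[3] - a[1]) * (b[2] - a[2]) - (a[4] - a[2]) * (b[1] - a[1])
  d2 <- (a[3] - a[1]) * (b[4] - a[2]) - (a[4] - a[2]) * (b[3] - a[1])
  d3 <- (b[3] - b[1]) * (a[2] - b[2]) - (b[4] - b[2]) * (a[1] - b[1])
  d4 <- (b[3] - b[1]) * (a[4] - b[2]) - (b[4] - b[2]) * (a[3] - b[1])
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(0)
  min(dist_to_segment(b[1], b[2], a[1], a[2], a[3], a[4]),
      dist_to_segment(b[3], b[4], a[1], a[2], a[3], a[4]),
      dist_to_segment(a[1], a[2], b[1], b[2], b[3], b[4]),
      dist_to_segment(a[3], a[4], b[1], b[2], b[3], b[4]))
}

# add a Gaussian blob to a field matrix (row = y, col = x); compiled kernel
add_gaussian <- function(canvas, x, y, amp, sigma)
  add_gaussian_cpp(canvas, x, y, amp, sigma)

# add a soft-edged capsule (full amplitude inside, Gaussian falloff
# outside); compiled kernel
add_capsule <- function(canvas, x0, y0, x1, y1, halfwidth, amp, edge_sigma)
  add_capsule_cpp(canvas, x0, y0, x1, y1, halfwidth, amp, edge_sigma)

# isolated-object footprint: pixels where the object's own contribution
# exceeds `net_level` (nominal ground-truth area, ignores underlying body)
gaussian_area_above <- function(amp, sigma, net_level) {
  if (amp <= net_level) return(0)
  pi * 2 * sigma^2 * log(amp / net_level)
}

two_lobe_area_above <- function(amp, sigma, ratio, sep_px, net_level) {
  # numeric union footprint of the two lobes on a local grid
  r <- ceiling(4 * sigma) + ceiling(sep_px)
  xs <- seq(-r, r, by = 1)
  g <- outer(xs, xs, function(y, x)
    amp * exp(-(x^2 + y^2) / (2 * sigma^2)) +
    ratio * amp * exp(-((x - sep_px)^2 + y^2) / (2 * sigma^2)))
  sum(g > net_level)
}

# draw per-adult vulval focus counts under the configured mode
draw_vulva_counts <- function(n_adults, p, caps) {
  if (n_adults == 0) return(integer(0))
  k <- switch(p$vulva_mode,
    poisson = rpois(n_adults, p$vulva_rate_adult),
    fixed   = rep.int(round(p$vulva_rate_adult), n_adults),
    mixture = {
      n_muv <- round(p$muv_fraction * n_adults)
      base <- rep.int(1L, n_adults)
      if (n_muv > 0) base[seq_len(n_muv)] <- as.integer(p$muv_count)
      # randomize which adults are Muv (length-safe shuffle)
      base[sample.int(n_adults)]
    })
  pmin(pmin(k, p$max_vulvae), caps)
}

#' Render one synthetic well
#'
#' Draws a well composition from `params`, places non-overlapping worms in the
#' four fields, renders the GFP and brightfield channels, and returns both the
#' pixel data and the exact ground truth. The GFP intensity ordering is
#' vulval focus peak > pharynx peak > body autofluorescence > background.
#' Identical `params` (including `seed`) give identical output.
#'
#' @param params a [well_sim_params()] object.
#' @param plate_id,well_id identifiers stored in the output.
#' @return a list with elements `image` (class `well_image`: `plate_id`,
#'   `well_id`, `pixel_size`, and `fields`, a list of 4 lists with integer
#'   matrices `gfp` and `bf`) and `truth` (class `ground_truth`: `well_id`,
#'   `worms` data frame, `true_counts` named vector of n_adults/n_larvae/
#'   n_vulvae/n_speckles, and `object_table` with one row per bright object:
#'   field, class, x, y, area, peak).
#' @export
render_well <- function(params, plate_id = "P1", well_id = "A01") {
  validate_sim_params(params)
  with_seed(params$seed, render_well_impl(params, plate_id, well_id))
}

render_well_impl <- function(p, plate_id, well_id) {
  g <- p$geometry
  size <- p$field_size

  n_worms <- p$n_worms
  if (is.null(n_worms)) {
    n_worms <- round(rnorm(1, p$n_worms_mean, p$n_worms_sd))
    n_worms <- min(max(n_worms, p$n_worms_range[1]), p$n_worms_range[2])
  }

  if (n_worms > 0) {
    is_adult <- switch(p$stage_mode,
      binomial = stats::runif(n_worms) < p$adult_fraction,
      fixed = {
        n_ad <- round(p$adult_fraction * n_worms)
        st <- rep(c(TRUE, FALSE), c(n_ad, n_worms - n_ad))
        st[sample.int(n_worms)]
      })
  } else is_adult <- logical(0)

  # per-worm dimensions
  len <- wid <- ph_sigma <- numeric(n_worms)
  for (i in seq_len(n_worms)) {
    if (is_adult[i]) {
      len[i] <- runif1(g$adult_length); wid[i] <- runif1(g$adult_width)
      ph_sigma[i] <- runif1(g$pharynx_sigma_adult)
    } else {
      len[i] <- runif1(g$larva_length); wid[i] <- runif1(g$larva_width)
      ph_sigma[i] <- runif1(g$pharynx_sigma_larva)
    }
  }

  # vulva counts (adults only); geometric cap keeps foci clear of the pharynx
  geo_cap <- ifelse(len > 0, pmax(floor(0.4 * len / g$vulva_spacing) + 1, 1), 1)
  n_vul <- integer(n_worms)
  if (any(is_adult))
    n_vul[is_adult] <- draw_vulva_counts(sum(is_adult), p, geo_cap[is_adult])

  # placement: random field, random pose, rejection on capsule overlap and
  # bright-centre proximity
  segs <- lapply(1:4, function(k) list())       # per field: capsule segments
  bright <- lapply(1:4, function(k) matrix(numeric(0), ncol = 2))
  placed <- vector("list", n_worms)
  for (i in seq_len(n_worms)) {
    hw <- wid[i] / 2
    edge_pad <- hw + 3 * g$body_edge_sigma + 2
    seg_half <- len[i] / 2 - hw
    ok <- FALSE
    for (att in seq_len(g$max_place_attempts)) {
      fld <- sample.int(4, 1)
      if (size - 2 * edge_pad <= 2 * seg_half) break
      cx <- stats::runif(1, edge_pad + seg_half, size - edge_pad - seg_half)
      cy <- stats::runif(1, edge_pad + seg_half, size - edge_pad - seg_half)
      th <- stats::runif(1, 0, pi)
      x0 <- cx - seg_half * cos(th); y0 <- cy - seg_half * sin(th)
      x1 <- cx + seg_half * cos(th); y1 <- cy + seg_half * sin(th)
      if (min(x0, x1) < edge_pad || max(x0, x1) > size - edge_pad ||
          min(y0, y1) < edge_pad || max(y0, y1) > size - edge_pad) next
      cand <- c(x0, y0, x1, y1)
      clash <- FALSE
      for (s in segs[[fld]]) {
        if (seg_seg_dist(cand, s$seg) < hw + s$hw + g$placement_margin) {
          clash <- TRUE; break
        }
      }
      if (clash) next
      # bright centres of this worm: pharynx lobes at end 0, vulvae mid-body
      ux <- cos(th); uy <- sin(th)
      d1 <- g$pharynx_end_offset
      d2 <- d1 + g$pharynx_lobe_sep * ph_sigma[i]
      bx <- c(x0 + d1 * ux, x0 + d2 * ux)
      by <- c(y0 + d1 * uy, y0 + d2 * uy)
      if (n_vul[i] > 0) {
        offs <- (seq_len(n_vul[i]) - (n_vul[i] + 1) / 2) * g$vulva_spacing
        tmid <- len[i] / 2 + offs
        bx <- c(bx, x0 + tmid * ux); by <- c(by, y0 + tmid * uy)
      }
      if (nrow(bright[[fld]]) > 0) {
        dmin <- min(sqrt(outer(bx, bright[[fld]][, 1], "-")^2 +
                         outer(by, bright[[fld]][, 2], "-")^2))
        if (dmin < g$bright_min_sep) next
      }
      segs[[fld]] <- c(segs[[fld]], list(list(seg = cand, hw = hw)))
      bright[[fld]] <- rbind(bright[[fld]], cbind(bx, by))
      placed[[i]] <- list(field = fld, seg = cand, theta = th,
                          bx = bx, by = by)
      ok <- TRUE
      break
    }
    if (!ok)
      stop_ws("placement failure: could not place worm ", i, " of ", n_worms,
              " without overlap (field size ", size,
              "); reduce worm count or density")
  }

  # render channels
  bg <- p$background_level
  net_ref <- 1500   # ground-truth footprint reference: mask level - background
  gfp <- lapply(1:4, function(k) matrix(bg, size, size))
  bf <- lapply(1:4, function(k) matrix(30000, size, size))
  obj <- list()

  for (i in seq_len(n_worms)) {
    pl <- placed[[i]]
    fld <- pl$field
    s <- pl$seg
    hw <- wid[i] / 2
    body_amp <- if (is_adult[i]) g$body_amp_adult else g$body_amp_larva
    ph_amp <- if (is_adult[i]) g$pharynx_amp_adult else g$pharynx_amp_larva
    gfp[[fld]] <- add_capsule(gfp[[fld]], s[1], s[2], s[3], s[4], hw,
                              body_amp, g$body_edge_sigma)
    bf[[fld]] <- add_capsule(bf[[fld]], s[1], s[2], s[3], s[4], hw,
                             -18000, g$body_edge_sigma)
    # pharynx lobes (bright centres 1 and 2)
    gfp[[fld]] <- add_gaussian(gfp[[fld]], pl$bx[1], pl$by[1], ph_amp, ph_sigma[i])
    gfp[[fld]] <- add_gaussian(gfp[[fld]], pl$bx[2], pl$by[2],
                               g$pharynx_lobe_ratio * ph_amp, ph_sigma[i])
    ph_area <- two_lobe_area_above(ph_amp, ph_sigma[i], g$pharynx_lobe_ratio,
                                   g$pharynx_lobe_sep * ph_sigma[i], net_ref)
    obj[[length(obj) + 1]] <- data.frame(
      field = fld,
      class = if (is_adult[i]) "adult_pharynx" else "larval_pharynx",
      x = mean(pl$bx[1:2]), y = mean(pl$by[1:2]),
      area = ph_area, peak = ph_amp + bg, worm = i)
    if (n_vul[i] > 0) {
      for (k in seq_len(n_vul[i])) {
        vx <- pl$bx[2 + k]; vy <- pl$by[2 + k]
        vs <- runif1(g$vulva_sigma)
        gfp[[fld]] <- add_gaussian(gfp[[fld]], vx, vy, g$vulva_amp, vs)
        obj[[length(obj) + 1]] <- data.frame(
          field = fld, class = "vulva", x = vx, y = vy,
          area = gaussian_area_above(g$vulva_amp, vs, net_ref),
          peak = g$vulva_amp + bg, worm = i)
      }
    }
  }

  n_speckles <- 0L
  for (fld in 1:4) {
    ns <- rpois(1, p$speckle_rate)
    for (k in seq_len(ns)) {
      sx <- stats::runif(1, 10, size - 10); sy <- stats::runif(1, 10, size - 10)
      sa <- runif1(g$speckle_amp); ss <- runif1(g$speckle_sigma)
      gfp[[fld]] <- add_gaussian(gfp[[fld]], sx, sy, sa, ss)
      obj[[length(obj) + 1]] <- data.frame(
        field = fld, class = "speckle", x = sx, y = sy,
        area = gaussian_area_above(sa, ss, net_ref), peak = sa + bg,
        worm = NA_integer_)
    }
    n_speckles <- n_speckles + ns
  }

  finish <- function(m) finish_channel_cpp(m, p$noise_sd)
  fields <- lapply(1:4, function(k)
    list(gfp = finish(gfp[[k]]), bf = finish(bf[[k]])))

  object_table <- if (length(obj)) do.call(rbind, obj) else
    data.frame(field = integer(0), class = character(0), x = numeric(0),
               y = numeric(0), area = numeric(0), peak = numeric(0),
               worm = integer(0))

  worms <- data.frame(
    worm = seq_len(n_worms),
    stage = ifelse(is_adult, "adult", "larva"),
    body_length = len, body_width = wid,
    pharynx_area = if (n_worms) vapply(seq_len(n_worms), function(i)
      object_table$area[!is.na(object_table$worm) & object_table$worm == i &
                        object_table$class != "vulva"][1], numeric(1))
      else numeric(0),
    n_vulvae = n_vul,
    field = if (n_worms) vapply(placed, `[[`, numeric(1), "field") else integer(0),
    x = if (n_worms) vapply(placed, function(z) mean(z$seg[c(1, 3)]), numeric(1)) else numeric(0),
    y = if (n_worms) vapply(placed, function(z) mean(z$seg[c(2, 4)]), numeric(1)) else numeric(0),
    orientation = if (n_worms) vapply(placed, `[[`, numeric(1), "theta") else numeric(0))

  image <- structure(list(plate_id = plate_id, well_id = well_id,
                          pixel_size = p$pixel_size, fields = fields),
                     class = "well_image")
  truth <- structure(list(
    plate_id = plate_id, well_id = well_id, worms = worms,
    true_counts = c(n_adults = sum(is_adult), n_larvae = sum(!is_adult),
                    n_vulvae = sum(n_vul), n_speckles = as.integer(n_speckles)),
    object_table = object_table), class = "ground_truth")
  list(image = image, truth = truth)
}

#' @export
print.well_image <- function(x, ...) {
  cat("well_image ", x$plate_id, "/", x$well_id, ": 4 fields of ",
      nrow(x$fields[[1]]$gfp), "x", ncol(x$fields[[1]]$gfp),
      " px (gfp + bf), ", x$pixel_size, " um/px\n", sep = "")
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth ", x$plate_id, "/", x$well_id, ": ", sep = "")
  print(x$true_counts)
  invisible(x)
}

#' Render a whole plate to TIFF files with ground truth
#'
#' Renders every well of `plate_map` and writes one 16-bit grayscale TIFF per
#' (well, field, channel), named `<plate>_<well>_f<field>_<channel>.tif` with
#' channel `gfp` or `bf`, plus `ground_truth.csv` (per-well true counts),
#' `ground_truth_objects.csv` (per-object records) and `manifest.csv`.
#'
#' @param plate_map a plate map data frame (see [read_plate_map()]).
#' @param params either a single [well_sim_params()] applied to all wells
#'   (with per-well sub-seeds derived from its `seed`), a named list of
#'   parameter objects keyed `"<plate>:<well>"`, or a function
#'   `function(row)` returning the parameters for one plate-map row.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest data frame (file, plate, well, field,
#'   channel).
#' @export
render_plate <- function(plate_map, params, out_dir) {
  plate_map <- validate_plate_map(plate_map)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  get_params <- params_resolver(params)

  manifest <- list(); truth_rows <- list(); obj_rows <- list()
  for (i in seq_len(nrow(plate_map))) {
    row <- plate_map[i, ]
    pw <- get_params(row)
    res <- render_well(pw, plate_id = row$plate, well_id = row$well)
    files <- write_well_image(res$image, out_dir)
    manifest[[i]] <- data.frame(file = files$file, plate = row$plate,
                                well = row$well, field = files$field,
                                channel = files$channel)
    tc <- res$truth$true_counts
    truth_rows[[i]] <- data.frame(plate = row$plate, well = row$well,
                                  n_adults = tc[["n_adults"]],
                                  n_larvae = tc[["n_larvae"]],
                                  n_vulvae = tc[["n_vulvae"]],
                                  n_speckles = tc[["n_speckles"]])
    ot <- res$truth$object_table
    if (nrow(ot)) {
      obj_rows[[i]] <- cbind(data.frame(plate = row$plate, well = row$well),
                             ot[c("field", "class", "x", "y", "area", "peak")])
    }
  }
  truth <- do.call(rbind, truth_rows)
  objs <- if (length(obj_rows)) do.call(rbind, obj_rows) else
    data.frame(plate = character(0), well = character(0), field = integer(0),
               class = character(0), x = numeric(0), y = numeric(0),
               area = numeric(0), peak = numeric(0))
  write.csv(truth, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  write.csv(objs, file.path(out_dir, "ground_truth_objects.csv"),
            row.names = FALSE)
  manifest <- do.call(rbind, manifest)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# resolve the three accepted `params` shapes into function(row) -> params
params_resolver <- function(params) {
  if (inherits(params, "well_sim_params")) {
    base <- params
    function(row) {
      p <- base
      p$seed <- derive_seed(base$seed, row$plate, row$well)
      p
    }
  } else if (is.function(params)) {
    params
  } else if (is.list(params)) {
    function(row) {
      key <- paste0(row$plate, ":", row$well)
      p <- params[[key]]
      if (is.null(p)) stop_ws("no simulation parameters for well ", key)
      p
    }
  } else stop_ws("params must be well_sim_params, a named list, or a function")
}

well_file_name <- function(plate, well, field, channel)
  sprintf("%s_%s_f%d_%s.tif", plate, well, field, channel)

write_well_image <- function(image, out_dir) {
  out <- data.frame(file = character(0), field = integer(0),
                    channel = character(0))
  for (k in 1:4) {
    for (ch in c("gfp", "bf")) {
      fn <- well_file_name(image$plate_id, image$well_id, k, ch)
      tiff::writeTIFF(image$fields[[k]][[ch]] / 65535,
                      file.path(out_dir, fn), bits.per.sample = 16L,
                      compression = "none")
      out <- rbind(out, data.frame(file = fn, field = k, channel = ch))
    }
  }
  out
}

#' Read a simulated well image back from TIFF files
#'
#' @param dir directory holding the plate's TIFF files.
#' @param plate,well identifiers used in the file names.
#' @param pixel_size microns per pixel to record on the object.
#' @param channels channels to load; detection only consumes `gfp`.
#' @return a `well_image` object (integer intensity matrices).
#' @export
read_well_image <- function(dir, plate, well, pixel_size = 2.5,
                            channels = c("gfp", "bf")) {
  fields <- lapply(1:4, function(k) {
    chans <- lapply(setNames(channels, channels), function(ch) {
      path <- file.path(dir, well_file_name(plate, well, k, ch))
      if (!file.exists(path)) stop_ws("missing image file: ", path)
      m <- tiff::readTIFF(path)
      round(m * 65535)
    })
    chans
  })
  structure(list(plate_id = plate, well_id = well, pixel_size = pixel_size,
                 fields = fields), class = "well_image")
}
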