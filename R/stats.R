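#' Z-factor assay-quality statistic
#'
#' Computes the screening-window coefficient
#' \deqn{Z = 1 - \frac{3(\sigma_p + \sigma_n)}{|\mu_p - \mu_n|}}
#' from negative- and positive-control readouts (here, vulvae-per-adult
#' scores), using sample standard deviations (n-1 denominator). Z lies in
#' (-Inf, 1]; 1 indicates a perfect assay (zero spread, separated means),
#' values in [0.5, 1] an excellent screen-worthy assay, [0, 0.5) a marginal
#' one, and negative values an unusable assay.
#'
#' @param neg_scores numeric vector of negative-control values (>= 2).
#' @param pos_scores numeric vector of positive-control values (>= 2).
#' @param na_drop drop `NA` values (undefined wells) with a recorded count
#'   rather than failing.
#' @return object of class `zfactor_result`: `z`, `interpretation`, and
#'   `neg`/`pos` component statistics (n_wells, mean, sd, n_dropped).
#' @export
zfactor <- function(neg_scores, pos_scores, na_drop = TRUE) {
  comp <- function(x, group) {
    n_na <- sum(is.na(x))
    if (n_na > 0 && !na_drop) stop_ws(group, " scores contain NA")
    x <- x[!is.na(x)]
    if (length(x) < 2)
      stop_ws(group, " control group needs >= 2 defined values (got ",
              length(x), ")")
    list(group = group, n_wells = length(x), mean = mean(x), sd = sd(x),
         n_dropped = n_na)
  }
  neg <- comp(neg_scores, "negative")
  pos <- comp(pos_scores, "positive")
  sep <- abs(pos$mean - neg$mean)
  if (sep == 0)
    stop_ws("Z-factor undefined: control means are equal (", neg$mean, ")")
  z <- 1 - 3 * (pos$sd + neg$sd) / sep
  interpretation <- if (z >= 0.5) "excellent"
    else if (z >= 0) "marginal" else "unusable"
  structure(list(z = z, interpretation = interpretation, neg = neg, pos = pos),
            class = "zfactor_result")
}

#' @export
print.zfactor_result <- function(x, ...) {
  cat(sprintf("Z-factor: %.4f (%s)\n", x$z, x$interpretation))
  for (g in list(x$neg, x$pos))
    cat(sprintf("  %s: n = %d, mean = %.4f, sd = %.4f%s\n", g$group,
                g$n_wells, g$mean, g$sd,
                if (g$n_dropped > 0) sprintf(" (%d undefined dropped)",
                                             g$n_dropped) else ""))
  invisible(x)
}

#' Z-factor from a score table
#'
#' Convenience wrapper selecting control wells from a [score_plate()] table by
#' role or compound name.
#'
#' @param scores score data frame.
#' @param neg,pos compound names for the control groups; `NULL` selects by
#'   `role` (`negative_control` / `positive_control`).
#' @param metric score column to use.
#' @return a `zfactor_result`.
#' @export
zfactor_from_scores <- function(scores, neg = NULL, pos = NULL,
                                metric = "vulvae_per_adult") {
  if (!metric %in% names(scores)) stop_ws("unknown metric: ", metric)
  nsel <- if (is.null(neg)) scores$role == "negative_control"
          else scores$compound == neg
  psel <- if (is.null(pos)) scores$role == "positive_control"
          else scores$compound == pos
  zfactor(scores[[metric]][nsel], scores[[metric]][psel])
}

#' Aggregate well scores into a dose-response table
#'
#' Two-level aggregation matching how replicated experiments are summarised:
#' within each experiment, replicate wells of a (compound, concentration) cell
#' are averaged (undefined vulvae-per-adult values dropped, with the dropped
#' count reported); across experiments, the mean and SD of the experiment
#' means are taken.
#'
#' @param scores score data frame with `compound`, `conc_um`, `experiment`,
#'   `vulvae_per_adult` and `pct_larvae` columns.
#' @return data frame, one row per compound x concentration: mean_va, sd_va
#'   (`NA` with a single experiment), mean_pct_larvae, sd_pct_larvae, n_wells
#'   (wells with a defined score), n_dropped, n_experiments.
#' @export
aggregate_dose_response <- function(scores) {
  need <- c("compound", "conc_um", "experiment", "vulvae_per_adult",
            "pct_larvae")
  missing <- setdiff(need, names(scores))
  if (length(missing))
    stop_ws("score table lacks column(s): ", paste(missing, collapse = ", "))
  key <- interaction(scores$compound, scores$conc_um, drop = TRUE)
  cells <- lapply(split(scores, key), function(cell) {
    agg2 <- function(col) {
      ex_means <- vapply(split(cell[[col]], cell$experiment),
                         function(v) mean(v[!is.na(v)]), numeric(1))
      ex_means[is.nan(ex_means)] <- NA_real_
      ok <- ex_means[!is.na(ex_means)]
      list(mean = if (length(ok)) mean(ok) else NA_real_,
           sd = if (length(ok) >= 2) sd(ok) else NA_real_)
    }
    va <- agg2("vulvae_per_adult")
    pl <- agg2("pct_larvae")
    data.frame(compound = cell$compound[1], conc_um = cell$conc_um[1],
               mean_va = va$mean, sd_va = va$sd,
               mean_pct_larvae = pl$mean, sd_pct_larvae = pl$sd,
               n_wells = sum(!is.na(cell$vulvae_per_adult)),
               n_dropped = sum(is.na(cell$vulvae_per_adult)),
               n_experiments = length(unique(cell$experiment)))
  })
  out <- do.call(rbind, cells)
  out <- out[order(out$compound, out$conc_um), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare two scoring pipelines by ordinary least squares
#'
#' Fits `a ~ b` over conditions scored by both pipelines and reports slope,
#' intercept and the coefficient of determination R^2 = 1 - SS_res/SS_tot,
#' the statistic used to compare manual against automated scoring.
#'
#' @param scores_a,scores_b paired numeric vectors (same condition order).
#' @return object of class `scoring_regression`: slope, intercept, r_squared,
#'   n_points.
#' @export
compare_scorings <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stop_ws("score vectors must be paired (equal length)")
  ok <- is.finite(scores_a) & is.finite(scores_b)
  a <- scores_a[ok]; b <- scores_b[ok]
  if (length(a) < 3) stop_ws("need >= 3 finite paired points, got ", length(a))
  if (sd(b) == 0) stop_ws("predictor has zero variance")
  fit <- lm(a ~ b)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((a - mean(a))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, n_points = length(a)),
            class = "scoring_regression")
}

#' @export
print.scoring_regression <- function(x, ...) {
  cat(sprintf("OLS pipeline comparison: slope %.4f, intercept %.4f, R^2 %.4f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Export a dose-response matrix (drugs x concentrations)
#'
#' Pivots an [aggregate_dose_response()] table into a compound-by-concentration
#' matrix for one metric, always writing a CSV and optionally a PNG heatmap.
#' Missing cells stay empty in the CSV and are drawn in grey.
#'
#' @param dr dose-response data frame.
#' @param metric one of the numeric columns of `dr` (e.g. `"mean_va"`,
#'   `"mean_pct_larvae"`).
#' @param csv output CSV path.
#' @param png optional output PNG path.
#' @return invisibly, the matrix (compounds in rows, concentrations in
#'   columns).
#' @export
heatmap_export <- function(dr, metric = "mean_va", csv, png = NULL) {
  if (!nrow(dr)) stop_ws("dose-response table is empty")
  if (length(metric) != 1 || !nzchar(metric) || !metric %in% names(dr) ||
      !is.numeric(dr[[metric]]))
    stop_ws("unknown metric: '", paste(metric, collapse = ","), "'")
  compounds <- unique(dr$compound)
  concs <- sort(unique(dr$conc_um))
  m <- matrix(NA_real_, length(compounds), length(concs),
              dimnames = list(compounds, paste0(concs, "uM")))
  for (i in seq_len(nrow(dr)))
    m[dr$compound[i], paste0(dr$conc_um[i], "uM")] <- dr[[metric]][i]
  write.csv(data.frame(compound = rownames(m), m, check.names = FALSE),
            csv, row.names = FALSE, na = "")
  if (!is.null(png)) {
    grDevices::png(png, width = 200 + 60 * ncol(m), height = 150 + 22 * nrow(m))
    on.exit(grDevices::dev.off())
    pal <- grDevices::hcl.colors(64, "viridis")
    mm <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    graphics::par(mar = c(4, 8, 3, 1))
    graphics::image(x = seq_len(ncol(mm)), y = seq_len(nrow(mm)),
                    z = t(mm), col = pal, axes = FALSE,
                    xlab = "concentration", ylab = "", main = metric)
    graphics::axis(1, at = seq_len(ncol(mm)), labels = colnames(mm))
    graphics::axis(2, at = seq_len(nrow(mm)), labels = rownames(mm), las = 2)
  }
  invisible(m)
}
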