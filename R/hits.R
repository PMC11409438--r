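HIT_STATUSES <- c("excluded_artifact", "excluded_toxic", "primary_hit",
                  "non_hit")
COUNTER_CLASSES <- c("on_pathway_hit", "downstream_or_parallel",
                     "indeterminate_growth")

#' Screen decision thresholds
#'
#' Thresholds for primary hit selection and the genetic counter-screen. The
#' primary-screen criteria are applied in order, with strict inequalities
#' (boundary values never trigger): (i) a well is excluded as an artifact if
#' its vulva-class count exceeds `artifact_vulvae_multiplier` times the
#' positive-control adult count (fluorescent speckles from progeny, bacteria
#' or drugs inflate the vulva channel); (ii) excluded as toxic if it holds
#' fewer than `min_adult_fraction_of_pos` of the positive-control adult count
#' (severely reduced larval growth); (iii) remaining compounds scoring below
#' `primary_hit_va_threshold` vulvae/adult are primary hits.
#'
#' In the counter-screen against a constitutively multivulva lin-1 background:
#' wells with fewer than `counter_min_adult_fraction` of the untreated adult
#' count are indeterminate (growth-retarded); compounds whose Muv fraction,
#' relative to the untreated control, falls below
#' `counter_muv_suppression_threshold` suppress the Muv phenotype and are
#' classified as acting downstream of (or parallel to) the ELK1-family
#' transcription factor; the rest are on-pathway hits. The 0.5 suppression
#' default is a package convention (configurable, echoed in all outputs).
#'
#' @param artifact_vulvae_multiplier criterion (i) multiplier, default 2.
#' @param min_adult_fraction_of_pos criterion (ii) fraction, default 0.30.
#' @param primary_hit_va_threshold criterion (iii) vulvae/adult cutoff, 0.4.
#' @param counter_muv_suppression_threshold relative Muv fraction below which
#'   a compound counts as suppressing the lin-1 Muv phenotype.
#' @param counter_min_adult_fraction adult fraction (vs untreated lin-1
#'   control) below which the counter-screen is indeterminate.
#' @return a validated list of class `screen_config`.
#' @export
screen_config <- function(artifact_vulvae_multiplier = 2.0,
                          min_adult_fraction_of_pos = 0.30,
                          primary_hit_va_threshold = 0.4,
                          counter_muv_suppression_threshold = 0.5,
                          counter_min_adult_fraction = 0.30) {
  cfg <- list(artifact_vulvae_multiplier = artifact_vulvae_multiplier,
              min_adult_fraction_of_pos = min_adult_fraction_of_pos,
              primary_hit_va_threshold = primary_hit_va_threshold,
              counter_muv_suppression_threshold = counter_muv_suppression_threshold,
              counter_min_adult_fraction = counter_min_adult_fraction)
  for (nm in names(cfg)) if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
    stop_ws(nm, " must be > 0")
  for (nm in c("min_adult_fraction_of_pos",
               "counter_muv_suppression_threshold",
               "counter_min_adult_fraction"))
    if (cfg[[nm]] > 1) stop_ws(nm, " must be in (0, 1]")
  class(cfg) <- "screen_config"
  cfg
}

#' @export
print.screen_config <- function(x, ...) {
  cat("Screen decision thresholds\n",
      "  (i)   artifact: vulvae > ", x$artifact_vulvae_multiplier,
      " x positive-control adults\n",
      "  (ii)  toxic: adults < ", 100 * x$min_adult_fraction_of_pos,
      "% of positive-control adults\n",
      "  (iii) primary hit: vulvae/adult < ", x$primary_hit_va_threshold, "\n",
      "  counter-screen: Muv suppression < ",
      x$counter_muv_suppression_threshold, " of control, indeterminate below ",
      100 * x$counter_min_adult_fraction, "% adults\n", sep = "")
  invisible(x)
}

# per-plate mean adult count over positive-control wells
pos_control_adult_means <- function(scores) {
  pos <- scores[scores$role == "positive_control", , drop = FALSE]
  if (!nrow(pos))
    stop_ws("no positive-control wells: exclusion criteria are defined ",
            "relative to the positive control")
  means <- vapply(split(pos$n_adults, pos$plate), mean, numeric(1))
  plates <- unique(scores$plate)
  missing <- setdiff(plates, names(means))
  if (length(missing))
    stop_ws("plate(s) without positive-control wells: ",
            paste(missing, collapse = ", "))
  means
}

# apply exclusion criteria (i) and (ii) to each test well; returns scores with
# a `status` column: excluded_artifact / excluded_toxic / NA (passed)
apply_exclusions <- function(scores, config, pos_adults) {
  ref <- pos_adults[scores$plate]
  status <- rep(NA_character_, nrow(scores))
  status[scores$n_vulvae > config$artifact_vulvae_multiplier * ref] <-
    "excluded_artifact"
  toxic <- is.na(status) &
    scores$n_adults < config$min_adult_fraction_of_pos * ref
  status[toxic] <- "excluded_toxic"
  scores$status <- status
  scores
}

#' Primary hit selection
#'
#' Applies the single-datapoint screen rules to every test well: (i) artifact
#' exclusion, (ii) toxicity exclusion, (iii) the vulvae/adult hit threshold
#' (see [screen_config()]). Compounds with several test wells are judged on
#' the mean vulvae/adult of their non-excluded wells, and are excluded only if
#' every well is excluded.
#'
#' @param scores score table from [score_plate()] including control wells.
#' @param config a [screen_config()].
#' @return object of class `hit_calls`: `calls` (data frame compound, status,
#'   value, reason), `summary` (status counts, per-plate positive-control
#'   adult means, input count) and `thresholds`.
#' @export
call_primary_hits <- function(scores, config = screen_config()) {
  pos_adults <- pos_control_adult_means(scores)
  test <- scores[scores$role == "test", , drop = FALSE]
  test <- apply_exclusions(test, config, pos_adults)

  calls <- lapply(split(test, test$compound)[unique(test$compound)],
                  function(w) {
    kept <- w[is.na(w$status), , drop = FALSE]
    if (!nrow(kept)) {
      st <- w$status[1]
      reason <- if (st == "excluded_artifact")
        sprintf("criterion i: vulvae %d > %g x %.1f positive-control adults",
                w$n_vulvae[1], config$artifact_vulvae_multiplier,
                pos_adults[[w$plate[1]]])
      else
        sprintf("criterion ii: adults %d < %g%% of %.1f positive-control adults",
                w$n_adults[1], 100 * config$min_adult_fraction_of_pos,
                pos_adults[[w$plate[1]]])
      return(data.frame(compound = w$compound[1], status = st,
                        value = w$vulvae_per_adult[1], reason = reason))
    }
    va <- mean(kept$vulvae_per_adult, na.rm = TRUE)
    if (is.nan(va)) va <- NA_real_
    hit <- !is.na(va) && va < config$primary_hit_va_threshold
    data.frame(compound = w$compound[1],
               status = if (hit) "primary_hit" else "non_hit",
               value = va,
               reason = sprintf("criterion iii: vulvae/adult %s %g",
                                if (hit) "<" else ">=",
                                config$primary_hit_va_threshold))
  })
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(compound = character(0), status = character(0),
               value = numeric(0), reason = character(0))
  rownames(calls) <- NULL
  counts <- table(factor(calls$status, levels = HIT_STATUSES))
  structure(list(calls = calls,
                 summary = list(status_counts = as.list(counts),
                                n_compounds = nrow(calls),
                                pos_control_adult_mean = as.list(pos_adults)),
                 thresholds = unclass(config)),
            class = "hit_calls")
}

#' @export
print.hit_calls <- function(x, ...) {
  cat("Primary screen:", x$summary$n_compounds, "compounds\n")
  for (st in HIT_STATUSES)
    cat(sprintf("  %-18s %d\n", st, x$summary$status_counts[[st]]))
  invisible(x)
}

#' Validation-round filtering of primary hits
#'
#' Re-applies the screen's per-well exclusion criteria to validation wells
#' (several concentrations, replicated experiments), aggregates
#' vulvae/adult per compound and concentration as the mean over experiments,
#' and keeps a compound only if at least one concentration stays at or below
#' the hit threshold; compounds above threshold at every concentration, or
#' with no evaluable wells, are removed with the failing rule recorded.
#'
#' @param scores validation score table (controls included, test wells tagged
#'   with compound, conc_um, experiment).
#' @param config a [screen_config()].
#' @return data frame per compound: survives, best_conc, best_va, n_evaluable,
#'   reason.
#' @export
validate_hits <- function(scores, config = screen_config()) {
  pos_adults <- pos_control_adult_means(scores)
  test <- scores[scores$role == "test", , drop = FALSE]
  test <- apply_exclusions(test, config, pos_adults)
  out <- lapply(split(test, test$compound)[unique(test$compound)],
                function(w) {
    kept <- w[is.na(w$status) & !is.na(w$vulvae_per_adult), , drop = FALSE]
    if (!nrow(kept))
      return(data.frame(compound = w$compound[1], survives = FALSE,
                        best_conc = NA_real_, best_va = NA_real_,
                        n_evaluable = 0L, reason = "no evaluable wells"))
    dr <- vapply(split(kept, kept$conc_um), function(cc) {
      mean(vapply(split(cc$vulvae_per_adult, cc$experiment), mean, numeric(1)))
    }, numeric(1))
    best <- which.min(dr)
    ok <- dr[best] <= config$primary_hit_va_threshold
    data.frame(compound = w$compound[1], survives = ok,
               best_conc = as.numeric(names(dr)[best]), best_va = dr[[best]],
               n_evaluable = nrow(kept),
               reason = if (ok) "" else
                 sprintf("vulvae/adult > %g at all concentrations",
                         config$primary_hit_va_threshold))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Counter-screen classification against a lin-1 Muv background
#'
#' Classifies validated compounds by their effect in a constitutively
#' multivulva lin-1 mutant, in which the Muv phenotype arises downstream of
#' the drugged kinases. Rules, in order: (1) compounds whose lin-1 adult
#' fraction (vs untreated control) is below `counter_min_adult_fraction` are
#' `indeterminate_growth` (retarded larval growth precludes analysis); (2)
#' compounds whose Muv fraction relative to the untreated control falls below
#' `counter_muv_suppression_threshold` are `downstream_or_parallel` (they
#' still suppress ectopic vulvae without upstream kinase signaling); (3) the
#' rest are `on_pathway_hit` (vulval induction suppressed in the reporter
#' strain but not in lin-1).
#'
#' @param counter data frame per compound: `compound`, `lin1_muv_fraction`,
#'   `lin1_adult_fraction_of_control`, and optionally `reporter_va`.
#' @param control_muv_fraction Muv fraction of untreated lin-1 control wells
#'   (expected close to 1 in this genotype).
#' @param config a [screen_config()].
#' @return `counter` with columns `class` and `muv_ratio` added.
#' @export
counter_screen_classify <- function(counter, control_muv_fraction,
                                    config = screen_config()) {
  if (missing(control_muv_fraction) || is.null(control_muv_fraction) ||
      !is.finite(control_muv_fraction) || control_muv_fraction <= 0)
    stop_ws("untreated lin-1 control Muv fraction is required and must be > 0")
  need <- c("compound", "lin1_muv_fraction", "lin1_adult_fraction_of_control")
  missing_cols <- setdiff(need, names(counter))
  if (length(missing_cols))
    stop_ws("counter-screen table lacks column(s): ",
            paste(missing_cols, collapse = ", "))
  ratio <- counter$lin1_muv_fraction / control_muv_fraction
  cls <- ifelse(counter$lin1_adult_fraction_of_control <
                  config$counter_min_adult_fraction,
                "indeterminate_growth",
         ifelse(ratio < config$counter_muv_suppression_threshold,
                "downstream_or_parallel", "on_pathway_hit"))
  counter$muv_ratio <- ratio
  counter$class <- cls
  counter
}

#' Write hit calls and summary to disk
#'
#' Writes `hits.json` (per-compound records plus the thresholds used) and
#' `screen_summary.csv` (status counts).
#'
#' @param hits a `hit_calls` object.
#' @param out_dir output directory.
#' @export
write_hit_calls <- function(hits, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(calls = hits$calls, summary = hits$summary,
         thresholds = hits$thresholds),
    file.path(out_dir, "hits.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  counts <- data.frame(status = HIT_STATUSES,
                       n = vapply(HIT_STATUSES, function(s)
                         hits$summary$status_counts[[s]], numeric(1)))
  write.csv(counts, file.path(out_dir, "screen_summary.csv"),
            row.names = FALSE)
  invisible(file.path(out_dir, "hits.json"))
}
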