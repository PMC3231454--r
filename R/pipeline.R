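#' Study protocol configuration
#'
#' Bundles every choice the end-to-end workflow makes: file paths, analytes,
#' presentation modes, the candidate pretreatments (scatter + derivative
#' code + spectral window), the over-ripe exclusion rule, the spectral-only
#' split settings, (M)PLS settings, and the LOCAL optimization grids. The
#' defaults follow the standard protocol for grape internal quality: four
#' derivative codes by three windows, SNV + detrend, 4-group CV with at most
#' 16 factors, a LOCAL grid of k in \{25,...,150 incl. 110\} by l in
#' \{14, 15, 16\} (k capped at \{25, 50, 75\} for potassium, whose library
#' is a single season).
#'
#' @param spectra_path,reference_path dataset CSV paths (see
#'   [load_dataset()]).
#' @param analytes reference columns to model.
#' @param presentations presentation modes to model.
#' @param treatments derivative code strings.
#' @param scatter scatter-correction mode for all candidates.
#' @param windows list of `c(lo, hi)` spectral windows in nm.
#' @param season_filter season whose samples are structured by the CENTER
#'   split (validation comes only from this season).
#' @param validation_fraction fraction of the filtered season assigned to
#'   validation.
#' @param overripe_ssc_quantile if non-NULL, samples above this soluble
#'   solids quantile are excluded (logged) before splitting.
#' @param max_factors,cv_groups (M)PLS cross-validation settings.
#' @param mode `"mpls"` or `"pls"` for the global calibrations.
#' @param local_k,local_l LOCAL optimization grid.
#' @param local_k_potassium reduced k grid for potassium.
#' @param n_discard,min_library,weighting LOCAL settings
#'   (see [local_config()]).
#' @param local_criterion best-cell statistic, `"sepc"` or `"sep"`.
#' @param out_dir report output directory, or `NULL` for in-memory only.
#' @param seed root seed for the CV group shuffle.
#' @return a `StudyConfig` list.
#' @export
study_config <- function(spectra_path, reference_path,
                         analytes = c("ssc_brix", "reducing_sugar_gL", "ph",
                                      "titratable_acidity_gL", "tartaric_gL",
                                      "malic_gL", "potassium_mgL"),
                         presentations = "bunch",
                         treatments = c("1,5,5,1", "2,5,5,1",
                                        "1,10,5,1", "2,10,5,1"),
                         scatter = "snv_detrend",
                         windows = list(c(380, 1650), c(780, 1650),
                                        c(1100, 1650)),
                         season_filter = 2008,
                         validation_fraction = 0.27,
                         overripe_ssc_quantile = NULL,
                         max_factors = 16, cv_groups = 4, mode = "mpls",
                         local_k = c(25, 50, 75, 100, 110, 125, 150),
                         local_l = 14:16,
                         local_k_potassium = c(25, 50, 75),
                         n_discard = 4, min_library = 15,
                         weighting = "shenk", local_criterion = "sepc",
                         out_dir = NULL, seed = 1) {
  structure(list(spectra_path = spectra_path,
                 reference_path = reference_path, analytes = analytes,
                 presentations = presentations, treatments = treatments,
                 scatter = scatter, windows = windows,
                 season_filter = season_filter,
                 validation_fraction = validation_fraction,
                 overripe_ssc_quantile = overripe_ssc_quantile,
                 max_factors = max_factors, cv_groups = cv_groups,
                 mode = mode, local_k = local_k, local_l = local_l,
                 local_k_potassium = local_k_potassium,
                 n_discard = n_discard, min_library = min_library,
                 weighting = weighting, local_criterion = local_criterion,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "StudyConfig")
}

#' Run the full study protocol
#'
#' Executes, in order: dataset loading, replicate averaging, the optional
#' over-ripe exclusion, the CENTER-based spectral split of the
#' `season_filter` season (validation samples come from that season only;
#' all other seasons join the calibration set; potassium models use the
#' filtered season alone), then per analyte x presentation a scan of every
#' derivative treatment x window with grouped cross-validation, selection of
#' the best global model by SECV, its external validation, and — for the
#' first presentation mode — the LOCAL k-by-l optimization grid at the best
#' global pretreatment, tuned on the validation set. Note the protocol
#' asymmetry: the global model is chosen on cross-validation statistics
#' only, while LOCAL is tuned on the validation set, which favors LOCAL.
#'
#' @param cfg a [study_config()].
#' @return a report bundle: list with `calibration_table` (best global model
#'   per analyte x presentation, CV statistics), `validation_table`
#'   (global vs LOCAL validation statistics), `local_grids` (per-analyte
#'   k-by-l grids), `comparisons` (per-analyte [compare_models()] records),
#'   `split`, `excluded_overripe`, and `config`. When `cfg$out_dir` is set
#'   the three tables are also written as CSV plus a JSON manifest.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "StudyConfig"))
  ds <- load_dataset(cfg$spectra_path, cfg$reference_path)
  avg <- average_replicates(ds$spectra)
  ref <- ds$reference

  # over-ripe exclusion (reference-value filter, separate from CENTER)
  excluded_overripe <- character(0)
  if (!is.null(cfg$overripe_ssc_quantile)) {
    thr <- stats::quantile(ref$ssc_brix, cfg$overripe_ssc_quantile,
                           na.rm = TRUE)
    excluded_overripe <- ref$sample_id[!is.na(ref$ssc_brix) &
                                         ref$ssc_brix > thr]
    if (length(excluded_overripe)) {
      keep <- !(avg$meta$sample_id %in% excluded_overripe)
      avg <- subset_rows(avg, keep)
    }
  }

  # CENTER split on the filtered season, using the first candidate
  # pretreatment as the structuring space (one split shared by all models)
  p0 <- pretreatment_spec(cfg$scatter, cfg$treatments[1], cfg$windows[[1]])
  first_mode <- cfg$presentations[1]
  base <- subset_rows(avg, avg$meta$presentation == first_mode)
  in_season <- base$meta$season == cfg$season_filter
  season_set <- subset_rows(base, in_season)
  pre_season <- apply_pretreatment(season_set, p0)
  cm <- fit_center(pre_season)
  split <- split_by_center(pre_season, cm, cfg$validation_fraction)
  val_ids <- split$validation_ids
  cal_ids_all <- setdiff(base$meta$sample_id, val_ids)

  cal_tab <- list(); val_tab <- list(); grids <- list(); comps <- list()
  for (analyte in cfg$analytes) {
    potassium <- analyte == "potassium_mgL"
    for (mode_p in cfg$presentations) {
      sub <- subset_rows(avg, avg$meta$presentation == mode_p)
      if (potassium)
        sub <- subset_rows(sub, sub$meta$season == cfg$season_filter)
      yall <- ref[[analyte]][match(sub$meta$sample_id, ref$sample_id)]
      is_val <- sub$meta$sample_id %in% val_ids
      usable <- !is.na(yall)
      best <- NULL
      for (tr in cfg$treatments) for (win in cfg$windows) {
        pre <- apply_pretreatment(sub, pretreatment_spec(cfg$scatter, tr, win))
        cal_idx <- which(!is_val & usable)
        cv <- cross_validate(pre$x[cal_idx, , drop = FALSE], yall[cal_idx],
                             max_factors = cfg$max_factors,
                             n_groups = cfg$cv_groups, seed = cfg$seed,
                             mode = cfg$mode)
        if (is.null(best) || cv$secv < best$cv$secv)
          best <- list(cv = cv, treatment = tr, window = win, pre = pre,
                       cal_idx = cal_idx)
      }
      ycal <- yall[best$cal_idx]
      cal_tab[[length(cal_tab) + 1]] <- data.frame(
        analyte = analyte, presentation = mode_p,
        treatment = best$treatment,
        window = paste(best$window, collapse = "-"),
        n = length(best$cal_idx), mean = mean(ycal), sd = stats::sd(ycal),
        factors = best$cv$chosen_factors, sec = best$cv$sec,
        R2 = best$cv$R2_cal, secv = best$cv$secv, r2_cv = best$cv$r2_cv,
        rpd = rpd(stats::sd(ycal), best$cv$secv),
        cv_percent = cv_percent(best$cv$secv, mean(ycal)))

      # external validation of the best global model
      val_idx <- which(is_val & usable)
      if (length(val_idx) >= 2) {
        pv <- predict_pls(best$cv$model, best$pre$x[val_idx, , drop = FALSE],
                          best$cv$chosen_factors)
        gstat <- eval_stats(yall[val_idx], pv, context = "prediction",
                            sd_ref = stats::sd(ycal))
        val_tab[[length(val_tab) + 1]] <- data.frame(
          analyte = analyte, presentation = mode_p, method = toupper(cfg$mode),
          treatment = best$treatment,
          window = paste(best$window, collapse = "-"),
          factors = best$cv$chosen_factors, n = gstat$n, sep = gstat$sep,
          sepc = gstat$sepc, bias = gstat$bias, r2 = gstat$r2,
          slope = gstat$slope, k = NA_integer_)

        # LOCAL on the first presentation mode only
        if (mode_p == first_mode) {
          kg <- if (potassium) cfg$local_k_potassium else cfg$local_k
          kg <- kg[kg <= length(best$cal_idx)]
          lib <- subset_rows(best$pre, best$cal_idx)
          qry <- subset_rows(best$pre, val_idx)
          lc <- local_config(k = max(cfg$min_library, min(kg)),
                             l_max = max(cfg$local_l),
                             n_discard = cfg$n_discard,
                             min_library = cfg$min_library,
                             weighting = cfg$weighting, mode = cfg$mode)
          og <- optimize_local_grid(lib, ycal, qry, yall[val_idx],
                                    k_grid = kg, l_grid = cfg$local_l,
                                    cfg = lc, criterion = cfg$local_criterion)
          grids[[analyte]] <- og$grid
          lb <- og$best
          lstat <- eval_stats(yall[val_idx],
                              og$predictions[, which(og$grid$k == lb$k &
                                                       og$grid$l == lb$l)],
                              context = "prediction", sd_ref = stats::sd(ycal))
          val_tab[[length(val_tab) + 1]] <- data.frame(
            analyte = analyte, presentation = mode_p,
            method = paste0("LOCAL"), treatment = best$treatment,
            window = paste(best$window, collapse = "-"),
            factors = lb$l, n = lstat$n, sep = lstat$sep, sepc = lstat$sepc,
            bias = lstat$bias, r2 = lstat$r2, slope = lstat$slope,
            k = lb$k)
          comps[[analyte]] <- compare_models(gstat, lstat)
        }
      }
    }
  }

  out <- list(calibration_table = do.call(rbind, cal_tab),
              validation_table = do.call(rbind, val_tab),
              local_grids = grids, comparisons = comps, split = split,
              excluded_overripe = excluded_overripe,
              excluded_no_reference = ds$excluded, config = cfg)
  if (!is.null(cfg$out_dir)) {
    if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
    utils::write.csv(out$calibration_table,
                     file.path(cfg$out_dir, "calibration_stats.csv"),
                     row.names = FALSE)
    utils::write.csv(out$validation_table,
                     file.path(cfg$out_dir, "validation_stats.csv"),
                     row.names = FALSE)
    if (length(grids)) {
      gg <- do.call(rbind, Map(function(a, g) cbind(analyte = a, g),
                               names(grids), grids))
      utils::write.csv(gg, file.path(cfg$out_dir, "local_grid.csv"),
                       row.names = FALSE)
    }
    manifest <- unclass(cfg)
    manifest$windows <- lapply(manifest$windows, as.numeric)
    manifest$pipeline_order <- "window > scatter > derivative"
    manifest$note <- paste("global model chosen on CV statistics;",
                           "LOCAL tuned on the validation set (leakage",
                           "favors LOCAL, by protocol)")
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  out
}

#' Compare global and LOCAL validation statistics
#'
#' Per-statistic deltas, relative improvements ([improvement_percent()]:
#' error reduction for SEP/SEP(c), gain for r2) and winner flags. Both
#' statistics records must describe the same validation set.
#'
#' @param global_stats an `EvalStats` for the global (M)PLS model.
#' @param local_stats an `EvalStats` for the LOCAL predictions.
#' @return data.frame with one row per statistic: value for each model,
#'   delta, improvement percent, and the winning method.
#' @export
compare_models <- function(global_stats, local_stats) {
  if (global_stats$n != local_stats$n)
    stop("statistics describe different validation sets (n mismatch)")
  stat <- c("sep", "sepc", "r2")
  rows <- lapply(stat, function(s) {
    g <- global_stats[[s]]; l <- local_stats[[s]]
    imp <- if (s == "r2") improvement_percent(g, l, "r2_gain")
    else improvement_percent(g, l, "error_reduction")
    winner <- if (s == "r2") {
      if (l > g) "local" else if (g > l) "global" else "tie"
    } else {
      if (l < g) "local" else if (g < l) "global" else "tie"
    }
    data.frame(statistic = s, global = g, local = l, delta = l - g,
               improvement_percent = imp, winner = winner)
  })
  do.call(rbind, rows)
}
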