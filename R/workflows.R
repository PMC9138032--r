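# End-to-end workflow drivers: calibration (reduce range -> fit -> LOO CV ->
# conformity -> LoD/LoQ) and speciation (areas or chromatograms -> arm
# concentrations -> pools -> cohort statistics).  Every artifact embeds the
# config and seed verbatim, so re-running a config reproduces identical
# files.

#' Default workflow configuration
#'
#' @param seed integer seed recorded in every artifact.
#' @return nested named list understood by [run_calibration_workflow()] and
#'   [run_speciation_workflow()].
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    calibration = list(kind = "linear", max_conc = 6, alpha = 0.05,
                       reporting_decimals = 1L, rmse_denominator = "n"),
    chromatography = list(references = c(SDB = 11.8, MBB = 12.8),
                          tolerance = 0.2, baseline = "linear_endpoints",
                          min_height = 1),
    cohort = list(reference = "T0")
  )
}

.write_artifact <- function(x, path, config) {
  payload <- c(x, list(config = config))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the calibration workflow
#'
#' Executes range reduction (when `config$calibration$max_conc` is finite),
#' model fitting, leave-one-out cross-validation with the conformity
#' regression, and LoD/LoQ.  Writes `model.json`, `validation.json` and
#' `limits.json` under `out_dir`, each stamped with the config and seed.
#' A parabolic configuration skips the limits step and records the remedy
#' (reduce the range and refit linearly) instead of failing.
#'
#' @param standards a standards table or path to a standards CSV
#'   (`conc_um,area_au[,day,replicate]`).
#' @param config configuration list, see [default_run_config()].
#' @param out_dir artifact directory (created if needed); `NULL` skips
#'   writing.
#' @return list with `model`, `cv`, `limits` (or `NULL` + `limits_remedy`),
#'   `conforms` and `status` (0 = success, 2 = conformity failure).
#' @export
run_calibration_workflow <- function(standards, config = default_run_config(),
                                     out_dir = NULL) {
  if (is.character(standards)) standards <- utils::read.csv(standards)
  standards <- as_standards_table(standards)
  cal <- config$calibration
  if (!is.null(cal$max_conc) && is.finite(cal$max_conc)) {
    standards <- reduce_range(standards, cal$max_conc)
  }
  model <- fit_calibration(standards, kind = cal$kind,
                           rmse_denominator = cal$rmse_denominator %||% "n")
  cv <- cv_validate(standards, kind = cal$kind, mode = "cv",
                    alpha = cal$alpha %||% 0.05)
  limits <- NULL
  limits_remedy <- NULL
  if (cal$kind == "linear") {
    limits <- compute_lod_loq(model, cal$reporting_decimals %||% 1L)
  } else {
    limits_remedy <- tryCatch(compute_lod_loq(model),
                              error = conditionMessage)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    model_to_json(model, file.path(out_dir, "model.json"),
                  extra = list(config = config))
    .write_artifact(unclass(cv)[setdiff(names(unclass(cv)), "recalculated")],
                    file.path(out_dir, "validation.json"), config)
    .write_artifact(
      if (is.null(limits)) list(limits = NULL, remedy = limits_remedy)
      else unclass(limits),
      file.path(out_dir, "limits.json"), config)
  }
  list(model = model, cv = cv, limits = limits,
       limits_remedy = limits_remedy, conforms = cv$conforms,
       status = if (cv$conforms) 0L else 2L)
}

# Integrate the SDB peak of one chromatogram: detect, assign, return the
# SDB area (error if no SDB peak is found).
.sdb_area <- function(chrom, chrom_cfg) {
  pk <- detect_peaks(chrom, min_height = chrom_cfg$min_height %||% 1)
  pk <- assign_identity(pk, references = chrom_cfg$references,
                        tolerance = chrom_cfg$tolerance %||% 0.2)
  hit <- pk[pk$label == "SDB", , drop = FALSE]
  if (nrow(hit) == 0L) stopf("no SDB peak found")
  hit$area_lu_min[1]
}

#' Run the speciation workflow
#'
#' Consumes a per-sample area table with one row per injection,
#' `data.frame(patient_id, timepoint, arm, area_au)` with
#' `arm` in `free`/`acid`/`total` (or a list of chromatograms per
#' patient/timepoint/arm, which are integrated first), inverts areas
#' through the linear calibration, speciates each sample and runs the
#' cohort statistics.
#'
#' @param model a linear `calibration_model` or path to a model JSON.
#' @param areas injection-level area table as above; each patient x
#'   timepoint must carry all three arms.
#' @param config configuration list, see [default_run_config()].
#' @param out_dir artifact directory; `NULL` skips writing.
#' @return list with `samples` (per-sample speciation table), `cohort`
#'   (pool-level cohort table incl. totals), `stats` (cohort_stats output)
#'   and `status`.
#' @export
run_speciation_workflow <- function(model, areas,
                                    config = default_run_config(),
                                    out_dir = NULL) {
  if (is.character(model)) model <- model_from_json(model)
  stopifnot(inherits(model, "calibration_model"))
  need <- c("patient_id", "timepoint", "arm", "area_au")
  stopifnot(all(need %in% names(areas)))
  limits <- compute_lod_loq(model)
  keys <- unique(areas[, c("patient_id", "timepoint")])
  samples <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    pid <- keys$patient_id[i]; tp <- keys$timepoint[i]
    sub <- areas[areas$patient_id == pid & areas$timepoint == tp, ]
    arms <- lapply(c(free = "free", acid = "acid", total = "total"),
                   function(arm) {
      rows <- sub[sub$arm == arm, ]
      if (nrow(rows) == 0L) {
        stopf("sample %s/%s is missing the '%s' arm", pid, tp, arm)
      }
      quantify_arm(model, rows$area_au)
    })
    sp <- speciate(free = arms$free$conc_um, acid = arms$acid$conc_um,
                   total = arms$total$conc_um, loq = limits$loq)
    cbind(data.frame(patient_id = pid, timepoint = tp), sp)
  }))
  long <- do.call(rbind, lapply(
    c("free", "acid_labile", "bound_sulfane", "total"),
    function(sp) data.frame(patient_id = samples$patient_id,
                            timepoint = samples$timepoint,
                            species = sp, concentration = samples[[sp]])))
  stats_out <- cohort_stats(long, reference = config$cohort$reference %||% "T0")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(samples, file.path(out_dir, "speciation.csv"),
                     row.names = FALSE)
    .write_artifact(list(stats = stats_out),
                    file.path(out_dir, "cohort_stats.json"), config)
  }
  list(samples = samples, cohort = long, stats = stats_out, status = 0L)
}

#' Convert a simulated pool cohort into an injection-level area table
#'
#' Bridges the simulator and the speciation workflow: turns pool
#' concentrations into the three measured arms (free, acid = free +
#' acid-labile, total = acid + bound sulfane), maps arm concentrations to
#' SDB areas through a calibration model and replicates each sample into
#' `n_injections` injections with optional area noise.
#'
#' @param cohort pool cohort from [gen_serum_cohort()].
#' @param model calibration model used forward.
#' @param n_injections injections per sample (default 3).
#' @param area_noise_sd injection-to-injection area noise, AU.
#' @param seed integer seed.
#' @return injection-level `data.frame(patient_id, timepoint, arm,
#'   injection, area_au)`.
#' @export
cohort_to_area_table <- function(cohort, model, n_injections = 3L,
                                 area_noise_sd = 0, seed = NULL) {
  stopifnot(is_count(n_injections), area_noise_sd >= 0)
  wide <- stats::reshape(cohort, idvar = c("patient_id", "timepoint"),
                         timevar = "species", direction = "wide")
  names(wide) <- sub("^concentration\\.", "", names(wide))
  arms <- data.frame(patient_id = wide$patient_id,
                     timepoint = wide$timepoint,
                     free = wide$free,
                     acid = wide$free + wide$acid_labile,
                     total = wide$free + wide$acid_labile + wide$bound_sulfane)
  long <- do.call(rbind, lapply(c("free", "acid", "total"), function(arm) {
    do.call(rbind, lapply(seq_len(n_injections), function(j) {
      data.frame(patient_id = arms$patient_id, timepoint = arms$timepoint,
                 arm = arm, injection = j,
                 area_au = predict_area(model, pmax(arms[[arm]], 0),
                                        warn_out_of_range = FALSE))
    }))
  }))
  if (area_noise_sd > 0) {
    long$area_au <- long$area_au +
      with_seed(seed, stats::rnorm(nrow(long), 0, area_noise_sd))
  }
  long[order(long$patient_id, long$timepoint, long$arm, long$injection), ]
}
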