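# Three-pool hydrogen sulfide speciation and cohort statistics.
#
# The assay measures three treatment arms per serum sample: "free" H2S
# (direct derivatization), "acid" (acidification releases the acid-labile
# pool on top of the free pool) and "total" (acid + TCEP reduction adds the
# bound sulfane sulfur).  The pools follow by subtraction:
#   acid-labile  = acid  - free
#   bound sulfane = total - acid
# so free + acid-labile + bound sulfane = total identically.

#' Speciate one or more samples from arm concentrations
#'
#' @param free,acid,total arm concentrations, uM (vectorised, equal length).
#' @param loq limit of quantification, uM; arm values below it raise the
#'   `below_loq` flag (default 0 = no flagging).
#' @return `data.frame` of class `speciation_result` with columns `free`,
#'   `acid`, `total`, `acid_labile`, `bound_sulfane`, `below_loq`,
#'   `negative_difference`.  Negative differences are preserved, never
#'   clipped — the flag makes them auditable.
#' @examples
#' speciate(free = 1, acid = 3, total = 7)  # acid_labile 2, bound_sulfane 4
#' @export
speciate <- function(free, acid, total, loq = 0) {
  stopifnot(length(free) == length(acid), length(acid) == length(total),
            all(is.finite(c(free, acid, total))),
            all(c(free, acid, total) >= 0), is_number(loq), loq >= 0)
  acid_labile <- acid - free
  bound_sulfane <- total - acid
  out <- data.frame(
    free = free, acid = acid, total = total,
    acid_labile = acid_labile, bound_sulfane = bound_sulfane,
    below_loq = free < loq | acid < loq | total < loq,
    negative_difference = acid_labile < 0 | bound_sulfane < 0)
  class(out) <- c("speciation_result", "data.frame")
  out
}

#' Quantify one treatment arm from replicate injection areas
#'
#' Each sample is injected in (typically three) replicates; the arm
#' concentration is the mean of the per-injection inverted concentrations,
#' with the inverse-prediction standard deviation propagated at the mean
#' area using the number of injections.
#'
#' @param model a linear `calibration_model`.
#' @param areas peak areas, AU, one per injection.
#' @return list with `conc_um` (mean), `sd_um` (propagated), `in_range`
#'   (FALSE if any injection inverts outside the calibrated range or below
#'   LoQ — flagged, never dropped) and `per_injection` (the
#'   [invert_calibration()] table).
#' @export
quantify_arm <- function(model, areas) {
  stopifnot(inherits(model, "calibration_model"), length(areas) >= 1L)
  if (model$kind != "linear") stopf("quantification uses the linear model")
  per <- invert_calibration(model, areas, n_sample_reps = 1L)
  pooled <- invert_calibration(model, mean(areas),
                               n_sample_reps = length(areas))
  list(conc_um = mean(per$conc_um), sd_um = pooled$sd_um,
       in_range = all(per$in_range), per_injection = per)
}

# Greenhouse-Geisser epsilon from the subject x condition matrix.
.gg_epsilon <- function(wide) {
  S <- stats::cov(wide)
  k <- ncol(S)
  # eps = (sum of eigenvalues)^2 / ((k-1) * sum of squared eigenvalues)
  # of the double-centered covariance
  C <- diag(k) - matrix(1 / k, k, k)
  V <- C %*% S %*% C
  ev <- Re(eigen(V, only.values = TRUE)$values)
  sum(ev)^2 / ((k - 1) * sum(ev^2))
}

#' Repeated-measures cohort statistics with Dunnett contrasts
#'
#' Per species: a one-way repeated-measures ANOVA across timepoints with
#' patient as the block (univariate, sphericity assumed by default), then
#' Dunnett-adjusted comparisons of each non-reference timepoint against the
#' reference (default T0), and percent change of timepoint means relative
#' to the reference.
#'
#' @param cohort cohort table: `data.frame(patient_id, timepoint, species,
#'   concentration)`; every patient must have every timepoint for each
#'   species analysed.
#' @param reference reference timepoint (default `"T0"`).
#' @param sphericity `"none"` (assume sphericity) or `"greenhouse_geisser"`
#'   to correct the ANOVA df.
#' @return named list (one element per species) of lists with
#'   `percent_change` (named by timepoint; 0 at the reference),
#'   `rm_anova_p`, `dunnett_p` (named by non-reference timepoint) and
#'   `zero_variance`.  Zero-variance species report `NA` p-values with the
#'   flag set.
#' @export
cohort_stats <- function(cohort, reference = "T0",
                         sphericity = c("none", "greenhouse_geisser")) {
  sphericity <- match.arg(sphericity)
  need <- c("patient_id", "timepoint", "species", "concentration")
  stopifnot(all(need %in% names(cohort)))
  species <- unique(cohort$species)
  tps <- unique(cohort$timepoint)
  if (!reference %in% tps) stopf("reference timepoint '%s' absent", reference)
  out <- lapply(species, function(sp) {
    sub <- cohort[cohort$species == sp, ]
    # completeness check, naming the first missing cell
    tab <- table(sub$patient_id, sub$timepoint)
    if (any(tab == 0)) {
      miss <- which(tab == 0, arr.ind = TRUE)[1, ]
      stopf("species %s: patient %s is missing timepoint %s", sp,
            rownames(tab)[miss[1]], colnames(tab)[miss[2]])
    }
    if (length(unique(sub$patient_id)) < 2L) stopf("need >= 2 patients")
    sub$timepoint <- stats::relevel(factor(sub$timepoint), ref = reference)
    sub$patient_id <- factor(sub$patient_id)
    means <- tapply(sub$concentration, sub$timepoint, mean)
    pc <- stats::setNames(
      as.numeric(100 * (means - means[[reference]]) / means[[reference]]),
      names(means))
    others <- setdiff(levels(sub$timepoint), reference)
    if (stats::var(sub$concentration) == 0) {
      return(list(percent_change = pc, rm_anova_p = NA_real_,
                  dunnett_p = stats::setNames(rep(NA_real_, length(others)),
                                              others),
                  zero_variance = TRUE))
    }
    # a zero-residual blocked fit (noise-free simulations) triggers
    # "essentially perfect fit" warnings whose p-values we still report
    muffle_perfect <- function(expr) withCallingHandlers(expr,
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    fit <- stats::aov(concentration ~ timepoint + patient_id, data = sub)
    an <- muffle_perfect(stats::anova(fit))
    p_rm <- an["timepoint", "Pr(>F)"]
    if (sphericity == "greenhouse_geisser" && length(levels(sub$timepoint)) > 2) {
      wide <- tapply(sub$concentration,
                     list(sub$patient_id, sub$timepoint), mean)
      eps <- .gg_epsilon(wide)
      Fv <- an["timepoint", "F value"]
      df1 <- an["timepoint", "Df"] * eps
      df2 <- an["Residuals", "Df"] * eps
      p_rm <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    }
    dunnett <- tryCatch(muffle_perfect({
      gl <- multcomp::glht(fit, linfct = multcomp::mcp(timepoint = "Dunnett"))
      ps <- summary(gl)$test$pvalues
      lev <- sub(" - .*$", "", rownames(summary(gl)$linfct))
      stats::setNames(as.numeric(ps), lev)
    }), error = function(e) {
      stats::setNames(rep(NA_real_, length(others)), others)
    })
    list(percent_change = pc, rm_anova_p = unname(p_rm),
         dunnett_p = dunnett[others], zero_variance = FALSE)
  })
  stats::setNames(out, species)
}
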