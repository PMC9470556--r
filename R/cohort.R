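#' Cohort simulation settings
#'
#' Builds a [CohortSpec-class] describing the longitudinal study design:
#' 10 control and 13 tumor-injected animals imaged at 7, 11, 15, 19 and
#' 21 days post-injection. Death times are exponential; the default
#' hazards are calibrated so that about 20% of control and 39% of tumor
#' animals survive to day 21 (`ln(5)/21` and `ln(1/0.39)/21` per day).
#' Group effect sizes (tumor minus control mean shifts per imaging day)
#' default to a profile that rises as the graft establishes and fades as
#' both groups deteriorate: higher scattering intensity and higher
#' abnormality fraction in tumor animals, lower birefringence, DOPU first
#' lower then higher, and slightly (not significantly) reduced vessel
#' metrics.
#'
#' @param nControl,nTumor animals per group.
#' @param timepoints imaging days post-injection.
#' @param hazardControl,hazardTumor exponential death hazards per day.
#' @param baseline named control-group means (see
#'   [CohortSpec-class]).
#' @param withinSd named per-animal standard deviations.
#' @param effects data.frame of tumor-minus-control shifts by `dpi`.
#' @return a validated [CohortSpec-class].
#' @export
cohortSpec <- function(nControl = 10, nTumor = 13,
                       timepoints = c(7, 11, 15, 19, 21),
                       hazardControl = log(5) / 21,
                       hazardTumor = log(1 / 0.39) / 21,
                       baseline = NULL, withinSd = NULL, effects = NULL) {
  if (is.null(baseline)) {
    baseline <- c(mean_intensity_db = 25, mean_birefringence = 1.35e-3,
                  mean_dopu = 0.82, abnormality_pct = 8,
                  vessel_density_pct = 14, mean_vessel_length_mm = 0.35)
  }
  if (is.null(withinSd)) {
    withinSd <- c(mean_intensity_db = 1.2, mean_birefringence = 1.5e-4,
                  mean_dopu = 0.03, abnormality_pct = 4,
                  vessel_density_pct = 1.5, mean_vessel_length_mm = 0.08)
  }
  if (is.null(effects)) {
    effects <- data.frame(
      dpi = timepoints,
      mean_intensity_db = c(0.8, 2.2, 2.6, 2.2, 1.2),
      mean_birefringence = -c(1.0e-4, 4.0e-4, 4.0e-4, 2.5e-4, 2.0e-4),
      mean_dopu = c(-0.035, 0.045, 0.035, 0.015, 0.005),
      abnormality_pct = c(3, 12, 8, 3, 2),
      vessel_density_pct = c(-0.5, -0.8, -1.0, -1.0, -0.8),
      mean_vessel_length_mm = c(-0.01, -0.02, -0.03, -0.03, -0.02)
    )[seq_along(timepoints), , drop = FALSE]
    effects$dpi <- timepoints
  }
  new("CohortSpec", nControl = nControl, nTumor = nTumor,
      timepoints = sort(timepoints), hazardControl = hazardControl,
      hazardTumor = hazardTumor, baseline = baseline,
      withinSd = withinSd, effects = effects)
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d control + %d tumor animals\n",
              object@nControl, object@nTumor))
  cat(sprintf("  imaging at dpi %s\n",
              paste(object@timepoints, collapse = ", ")))
  cat(sprintf("  hazards/day: control %.4f, tumor %.4f\n",
              object@hazardControl, object@hazardTumor))
})

#' Simulate a longitudinal cohort
#'
#' Draws per-animal exponential death times (censored at the last imaging
#' day) and, for every animal alive at an imaging day, per-animal contrast
#' summaries from group-level normal distributions: control means from the
#' spec's baseline, tumor means shifted by the day's effect size. Dead
#' animals contribute no later measurement rows. DOPU is clamped to
#' `[0, 1]`, percentages to `[0, 100]`, birefringence and vessel metrics
#' to non-negative values.
#'
#' @param spec a [CohortSpec-class] from [cohortSpec()].
#' @param seed integer seed; the simulation is deterministic given the
#'   seed.
#' @return list with `measurements` (one row per animal and imaging day
#'   survived: `animal_id`, `group`, `dpi`, `alive`, and the six summary
#'   quantities) and `survival` (one row per animal: `animal_id`, `group`,
#'   `time_days`, `event`).
#' @export
simulateCohort <- function(spec = cohortSpec(), seed = 1L) {
  stopifnot(is(spec, "CohortSpec"))
  set.seed(seed)
  endDay <- max(spec@timepoints)
  qs <- names(spec@baseline)

  groups <- rep(c("control", "tumor"), c(spec@nControl, spec@nTumor))
  nAll <- length(groups)
  ids <- sprintf("%s%02d", ifelse(groups == "control", "C", "T"),
                 c(seq_len(spec@nControl), seq_len(spec@nTumor)))
  hazard <- ifelse(groups == "control", spec@hazardControl,
                   spec@hazardTumor)
  death <- if (all(hazard > 0)) stats::rexp(nAll, rate = hazard) else
    ifelse(hazard > 0, stats::rexp(nAll, rate = pmax(hazard, 1e-12)), Inf)

  survival <- data.frame(
    animal_id = ids, group = groups,
    time_days = pmin(death, endDay),
    event = as.integer(death <= endDay),
    stringsAsFactors = FALSE
  )

  rows <- list()
  for (i in seq_len(nAll)) {
    for (t in spec@timepoints) {
      if (death[i] <= t) next
      shift <- if (groups[i] == "tumor") {
        unlist(spec@effects[spec@effects$dpi == t, qs])
      } else {
        stats::setNames(numeric(length(qs)), qs)
      }
      val <- spec@baseline[qs] + shift[qs] + stats::rnorm(length(qs)) *
        spec@withinSd[qs]
      names(val) <- qs
      val["mean_dopu"] <- min(max(val["mean_dopu"], 0), 1)
      val["abnormality_pct"] <- min(max(val["abnormality_pct"], 0), 100)
      val["vessel_density_pct"] <-
        min(max(val["vessel_density_pct"], 0), 100)
      val["mean_birefringence"] <- max(val["mean_birefringence"], 0)
      val["mean_vessel_length_mm"] <- max(val["mean_vessel_length_mm"], 0)
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = ids[i], group = groups[i], dpi = t, alive = TRUE,
        as.list(val), stringsAsFactors = FALSE)
    }
  }
  measurements <- if (length(rows)) do.call(rbind, rows) else
    data.frame()
  rownames(measurements) <- NULL
  list(measurements = measurements, survival = survival, spec = spec)
}
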