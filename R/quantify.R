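#' Per-animal masked contrast summaries
#'
#' Reduces a contrast set and a muscle mask to the per-animal summary
#' statistics used in the longitudinal analysis: mean intensity, the
#' reliability-weighted mean birefringence, and mean DOPU over the masked
#' voxels of the central `bscanWindow` B-scans (the slow-axis slices
#' around the injection site).
#'
#' @param contrasts a [ContrastSet-class].
#' @param mask a [MaskVolume-class] or logical array on the same grid.
#' @param bscanWindow number of central B-scans to evaluate (default 30);
#'   clipped to the volume with a warning when larger.
#' @param animalId,group,dpi optional identifiers copied into the output.
#' @return one-row data.frame with `animal_id`, `group`, `dpi`,
#'   `mean_intensity_db`, `mean_birefringence`, `mean_dopu`, `n_voxels`.
#'   Means are `NA` (with a warning) when the mask is empty in the window.
#' @export
maskedMeans <- function(contrasts, mask, bscanWindow = 30L,
                        animalId = NA_character_, group = NA_character_,
                        dpi = NA_real_) {
  stopifnot(is(contrasts, "ContrastSet"))
  m <- if (is(mask, "MaskVolume")) maskArray(mask) else mask
  d <- dim(intensityDb(contrasts))
  stopifnot(identical(dim(m), d))
  ny <- d[3L]
  if (bscanWindow > ny) {
    warning("B-scan window larger than volume; clipping to ", ny)
    bscanWindow <- ny
  }
  start <- max(1L, floor((ny - bscanWindow) / 2) + 1L)
  ySel <- start:(start + bscanWindow - 1L)

  sel <- array(FALSE, dim = d)
  sel[, , ySel] <- TRUE
  use <- m & sel & validMask(contrasts)

  n <- sum(use)
  if (n == 0L) {
    warning("mask empty within the selected B-scan window")
    return(data.frame(animal_id = animalId, group = group, dpi = dpi,
                      mean_intensity_db = NA_real_,
                      mean_birefringence = NA_real_,
                      mean_dopu = NA_real_, n_voxels = 0L,
                      stringsAsFactors = FALSE))
  }
  rel <- reliabilityMap(contrasts)[use]
  dn <- birefringenceMap(contrasts)[use]
  mb <- if (sum(rel) > 0) sum(dn * rel) / sum(rel) else NA_real_
  data.frame(
    animal_id = animalId, group = group, dpi = dpi,
    mean_intensity_db = mean(intensityDb(contrasts)[use]),
    mean_birefringence = mb,
    mean_dopu = mean(dopuMap(contrasts)[use]),
    n_voxels = n,
    stringsAsFactors = FALSE
  )
}

#' Birefringence abnormality fraction
#'
#' Percentage of masked voxels whose birefringence falls below the
#' abnormality threshold (default dn = 0.0006, the value separating
#' healthy ordered muscle from abnormally low birefringence). Only voxels
#' with a positive reliability are counted when a reliability map is
#' supplied, so that noise-dominated pixels do not inflate the abnormal
#' area.
#'
#' @param birefringence birefringence array, or a [ContrastSet-class]
#'   (whose reliability channel is then used automatically).
#' @param mask a [MaskVolume-class] or logical array.
#' @param threshold abnormality threshold on dn (default 0.0006).
#' @param reliability optional reliability array; voxels with
#'   `reliability <= 0` are excluded from both numerator and denominator.
#' @return percentage in `[0, 100]`; `NA` with a warning for an empty
#'   mask.
#' @export
abnormalityFraction <- function(birefringence, mask, threshold = 0.0006,
                                reliability = NULL) {
  if (is(birefringence, "ContrastSet")) {
    if (is.null(reliability)) reliability <- reliabilityMap(birefringence)
    birefringence <- birefringenceMap(birefringence)
  }
  m <- if (is(mask, "MaskVolume")) maskArray(mask) else mask
  stopifnot(identical(dim(m), dim(birefringence)))
  use <- m
  if (!is.null(reliability)) use <- use & reliability > 0
  n <- sum(use)
  if (n == 0L) {
    warning("empty mask: abnormality fraction undefined")
    return(NA_real_)
  }
  100 * sum(birefringence[use] < threshold) / n
}

#' Mann-Whitney rank sum test
#'
#' Two-sided Mann-Whitney U test with midrank tie handling. For a pooled
#' sample size of at most `exactMax` the null distribution of U is built
#' by full enumeration over all assignments of the pooled midranks (so
#' the p-value is exact even under ties); for larger samples the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b numeric value vectors for the two groups (each nonempty).
#' @param exactMax largest pooled size for which full enumeration is used
#'   (default 12).
#' @return list with `U` (the U statistic of group `a`), `p` (two-sided),
#'   and `method` (`"exact"` or `"normal"`).
#' @examples
#' rankSumTest(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
rankSumTest <- function(a, b, exactMax = 12L) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)                      # midranks
  uObs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2

  if (n <= exactMax) {
    idx <- utils::combn(n, na)
    ra <- matrix(r[idx], nrow = na)
    uAll <- colSums(ra) - na * (na + 1) / 2
    p <- mean(abs(uAll - mu) >= abs(uObs - mu) - 1e-9)
    return(list(U = uObs, p = p, method = "exact"))
  }

  ties <- table(r)
  tieAdj <- sum(ties^3 - ties)
  v <- na * nb / 12 * ((n + 1) - tieAdj / (n * (n - 1)))
  if (v <= 0) return(list(U = uObs, p = 1, method = "normal"))
  z <- (abs(uObs - mu) - 0.5) / sqrt(v)   # continuity correction
  z <- max(z, 0)
  p <- min(1, 2 * stats::pnorm(-z))
  list(U = uObs, p = p, method = "normal")
}

#' Box-whisker summary of a cohort quantity
#'
#' Per-group box-plot statistics of one summary quantity at one imaging
#' day: median, quartiles (linear interpolation between order statistics,
#' `stats::quantile` type 7), whiskers and outliers. The default whisker
#' rule is Tukey's 1.5 IQR; `"minmax"` draws whiskers at the extremes
#' (then nothing is an outlier).
#'
#' @param table cohort measurement data.frame (see [simulateCohort()]).
#' @param quantity column name to summarize.
#' @param dpi imaging day to select.
#' @param whiskerRule `"tukey"` or `"minmax"`.
#' @return data.frame with one row per group: `group`, `n`, `median`,
#'   `q25`, `q75`, `lower`, `upper`, `n_outliers`; outlier values are in
#'   `attr(, "outliers")`. Zero rows when no data exist at that day.
#' @export
groupSummary <- function(table, quantity, dpi,
                         whiskerRule = c("tukey", "minmax")) {
  whiskerRule <- match.arg(whiskerRule)
  stopifnot(quantity %in% names(table))
  sub <- table[table$dpi == dpi & !is.na(table[[quantity]]), ]
  if (!nrow(sub)) {
    return(structure(data.frame(), outliers = list()))
  }
  groups <- sort(unique(sub$group))
  outliers <- list()
  rows <- lapply(groups, function(gr) {
    v <- sub[[quantity]][sub$group == gr]
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    if (whiskerRule == "tukey") {
      iqr <- qs[3] - qs[1]
      loFence <- qs[1] - 1.5 * iqr
      hiFence <- qs[3] + 1.5 * iqr
      inl <- v[v >= loFence & v <= hiFence]
      out <- v[v < loFence | v > hiFence]
      lower <- min(inl); upper <- max(inl)
    } else {
      lower <- min(v); upper <- max(v); out <- numeric(0)
    }
    outliers[[gr]] <<- out
    data.frame(group = gr, n = length(v), median = qs[2],
               q25 = qs[1], q75 = qs[3], lower = lower, upper = upper,
               n_outliers = length(out), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), outliers = outliers)
}

#' Group comparisons across imaging days
#'
#' Runs [rankSumTest()] for tumor vs control on each requested quantity
#' and imaging day, returning a tidy table. Mirrors the per-timepoint
#' rank-sum reporting of the longitudinal analysis; no multiple-testing
#' correction is applied by default (set `pAdjustMethod` to e.g. `"holm"`
#' to add one).
#'
#' @param table cohort measurement data.frame with `group`, `dpi` and the
#'   quantity columns.
#' @param quantities character vector of column names.
#' @param dpi days to test (default: all present).
#' @param pAdjustMethod method for [stats::p.adjust()], `"none"` by
#'   default.
#' @return data.frame with columns `quantity`, `dpi`, `n_control`,
#'   `n_tumor`, `mean_control`, `mean_tumor`, `U`, `p`.
#' @export
compareGroups <- function(table, quantities, dpi = NULL,
                          pAdjustMethod = "none") {
  if (is.null(dpi)) dpi <- sort(unique(table$dpi))
  rows <- list()
  for (q in quantities) {
    for (d in dpi) {
      sub <- table[table$dpi == d & !is.na(table[[q]]), ]
      va <- sub[[q]][sub$group == "control"]
      vb <- sub[[q]][sub$group == "tumor"]
      if (!length(va) || !length(vb)) next
      ts <- rankSumTest(va, vb)
      rows[[length(rows) + 1L]] <- data.frame(
        quantity = q, dpi = d, n_control = length(va),
        n_tumor = length(vb), mean_control = mean(va),
        mean_tumor = mean(vb), U = ts$U, p = ts$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out) && pAdjustMethod != "none") {
    out$p_adjusted <- stats::p.adjust(out$p, method = pAdjustMethod)
  }
  out
}
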