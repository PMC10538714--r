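#' @include AllClasses.R synth-cohort.R radbio.R
NULL

.subsetCohort <- function(cohort, territory, modality) {
  validateCohort(cohort)
  if (territory == "GLOBAL" && !("GLOBAL" %in% cohort$territory))
    cohort <- cohortWholeMyocardium(cohort)
  cohort[cohort$territory == territory & cohort$modality == modality &
           is.finite(cohort$mbf), , drop = FALSE]
}

#' Kruskal-Wallis omnibus test across timepoints
#'
#' Rank-based omnibus test (with tie correction, via
#' \code{stats::kruskal.test}) of MBF across the study visits for one
#' coronary territory and modality.
#'
#' @param cohort cohort data.frame (see [simulateCohort()]).
#' @param territory \code{"LAD"}, \code{"LCX"}, \code{"BOTH"} or
#'   \code{"GLOBAL"} (whole myocardium).
#' @param modality \code{"NH3"} or \code{"DCE"}.
#' @param variable column tested (default \code{"mbf"}; use
#'   \code{"rpp"}-style columns via \code{"heart_rate"} etc. or a
#'   precomputed column).
#' @return list with \code{H} (chi-squared statistic), \code{df},
#'   \code{p}, and \code{reason} (NA p with a reason when groups are
#'   insufficient).
#' @export
kruskalWallisTimepoints <- function(cohort, territory, modality,
                                    variable = "mbf") {
  d <- .subsetCohort(cohort, territory, modality)
  d <- d[is.finite(d[[variable]]), , drop = FALSE]
  tab <- table(droplevels(d$timepoint))
  if (sum(tab >= 2L) < 2L)
    return(list(H = NA_real_, df = NA_real_, p = NA_real_,
                reason = "fewer than 2 timepoints with >= 2 observations"))
  kt <- stats::kruskal.test(d[[variable]], droplevels(d$timepoint))
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, reason = NA_character_)
}

#' Mann-Whitney test of a follow-up visit against baseline
#'
#' Two-sided rank-sum test of MBF at one follow-up visit versus baseline
#' for a territory and modality (unpaired, matching the study's analysis
#' even though the animals are the same). The exact null distribution is
#' used when both groups have n <= 8 and there are no ties; the normal
#' approximation otherwise.
#'
#' @inheritParams kruskalWallisTimepoints
#' @param timepoint the follow-up visit label.
#' @param baseline the baseline visit label (default \code{"baseline"}).
#' @return list with \code{U} (rank-sum statistic of the follow-up group),
#'   \code{p}, \code{exact} (logical) and \code{reason}.
#' @export
mannWhitneyVsBaseline <- function(cohort, territory, modality, timepoint,
                                  baseline = "baseline",
                                  variable = "mbf") {
  d <- .subsetCohort(cohort, territory, modality)
  x <- d[[variable]][d$timepoint == timepoint]
  y <- d[[variable]][d$timepoint == baseline]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y))
    return(list(U = NA_real_, p = NA_real_, exact = NA,
                reason = "empty group"))
  useExact <- length(x) <= 8L && length(y) <= 8L
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = useExact, correct = !useExact))
  list(U = unname(wt$statistic), p = wt$p.value,
       exact = useExact && !any(duplicated(c(x, y))),
       reason = NA_character_)
}

#' Pearson correlation of MBF with FDG SUV per territory
#'
#' Sample Pearson correlation between MBF and SUV over all
#' animal-by-visit records of one territory, with the two-sided p-value
#' from the t transform (via \code{stats::cor.test}).
#'
#' @inheritParams kruskalWallisTimepoints
#' @return list with \code{r}, \code{p}, \code{n} and \code{reason}.
#' @export
pearsonByTerritory <- function(cohort, territory, modality = "NH3") {
  d <- .subsetCohort(cohort, territory, modality)
  d <- d[is.finite(d$suv), , drop = FALSE]
  if (nrow(d) < 3L)
    return(list(r = NA_real_, p = NA_real_, n = nrow(d),
                reason = "fewer than 3 paired observations"))
  if (stats::sd(d$mbf) == 0 || stats::sd(d$suv) == 0)
    return(list(r = NA_real_, p = NA_real_, n = nrow(d),
                reason = "zero variance"))
  ct <- stats::cor.test(d$mbf, d$suv, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(d),
       reason = NA_character_)
}

#' Paired t-test between the PET and DCE flow estimates
#'
#' Paired two-sided t-test of per-record MBF differences (ammonia PET vs
#' dual-bolus DCE) within one territory; records missing either modality
#' (e.g. QC-excluded DCE points) are dropped pairwise.
#'
#' @inheritParams kruskalWallisTimepoints
#' @return list with \code{t}, \code{df}, \code{p}, \code{n} (complete
#'   pairs) and \code{reason}.
#' @export
pairedModalityTest <- function(cohort, territory) {
  nh3 <- .subsetCohort(cohort, territory, "NH3")
  dce <- .subsetCohort(cohort, territory, "DCE")
  m <- merge(nh3[, c("animal_id", "timepoint", "mbf")],
             dce[, c("animal_id", "timepoint", "mbf")],
             by = c("animal_id", "timepoint"),
             suffixes = c("_nh3", "_dce"))
  m <- m[is.finite(m$mbf_nh3) & is.finite(m$mbf_dce), , drop = FALSE]
  if (nrow(m) < 3L)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, n = nrow(m),
                reason = "fewer than 3 complete pairs"))
  diffs <- m$mbf_nh3 - m$mbf_dce
  if (stats::sd(diffs) == 0) {
    # identical columns: no evidence of a difference; constant nonzero
    # difference: degenerate (zero variance), flagged
    if (all(diffs == 0))
      return(list(t = 0, df = nrow(m) - 1L, p = 1, n = nrow(m),
                  reason = NA_character_))
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, n = nrow(m),
                reason = "constant nonzero difference (zero variance)"))
  }
  tt <- stats::t.test(m$mbf_nh3, m$mbf_dce, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = nrow(m), reason = NA_character_)
}

#' Assemble the full longitudinal statistics report
#'
#' Computes, per territory (LAD, LCX, BOTH and whole-myocardium GLOBAL)
#' and modality: the Kruskal-Wallis omnibus p across visits, the
#' Mann-Whitney p of every follow-up visit against baseline, the MBF-SUV
#' Pearson correlation, and the paired PET-vs-DCE test; plus the
#' rate-pressure-product omnibus test across visits. DCE records of
#' QC-excluded acquisitions are set missing before any DCE statistic.
#' Degenerate cells carry an NA with a reason rather than failing.
#'
#' @param cohort cohort data.frame.
#' @param qcExclusions optional data.frame with columns \code{animal_id},
#'   \code{timepoint}: DCE acquisitions excluded by QC.
#' @param holm apply a Holm correction within each family of follow-up
#'   contrasts (default FALSE, matching the study's uncorrected
#'   reporting).
#' @return list of class \code{"StatReport"}: \code{omnibus},
#'   \code{contrasts}, \code{pearson}, \code{pairedModality} (data.frames)
#'   \code{rpp} (list), \code{nExcluded}.
#' @export
buildStatReport <- function(cohort, qcExclusions = NULL, holm = FALSE) {
  validateCohort(cohort)
  nExcluded <- 0L
  if (!is.null(qcExclusions) && nrow(qcExclusions)) {
    bad <- paste(cohort$animal_id, cohort$timepoint) %in%
      paste(qcExclusions$animal_id, qcExclusions$timepoint) &
      cohort$modality == "DCE"
    nExcluded <- sum(bad)
    cohort$mbf[bad] <- NA_real_
  }
  terrs <- c(.TERRITORIES, "GLOBAL")
  mods <- intersect(c("NH3", "DCE"), unique(cohort$modality))
  tps <- levels(cohort$timepoint)
  followups <- tps[-1L]

  omnibus <- do.call(rbind, lapply(terrs, function(tr)
    do.call(rbind, lapply(mods, function(mo) {
      kw <- kruskalWallisTimepoints(cohort, tr, mo)
      data.frame(territory = tr, modality = mo, H = kw$H, p = kw$p,
                 reason = kw$reason, stringsAsFactors = FALSE)
    }))))

  contrasts <- do.call(rbind, lapply(terrs, function(tr)
    do.call(rbind, lapply(mods, function(mo) {
      ps <- lapply(followups, function(tp)
        mannWhitneyVsBaseline(cohort, tr, mo, tp))
      p <- vapply(ps, `[[`, numeric(1), "p")
      if (holm) p <- stats::p.adjust(p, "holm")
      data.frame(territory = tr, modality = mo, timepoint = followups,
                 U = vapply(ps, `[[`, numeric(1), "U"), p = p,
                 reason = vapply(ps, function(x)
                   x$reason %||% NA_character_, character(1)),
                 stringsAsFactors = FALSE)
    }))))

  pearson <- do.call(rbind, lapply(terrs, function(tr) {
    pc <- pearsonByTerritory(cohort, tr, "NH3")
    data.frame(territory = tr, r = pc$r, p = pc$p, n = pc$n,
               reason = pc$reason, stringsAsFactors = FALSE)
  }))

  paired <- do.call(rbind, lapply(terrs, function(tr) {
    pt <- pairedModalityTest(cohort, tr)
    data.frame(territory = tr, t = pt$t, p = pt$p, n = pt$n,
               reason = pt$reason, stringsAsFactors = FALSE)
  }))

  # RPP: one record per animal-visit
  visits <- cohort[!duplicated(paste(cohort$animal_id, cohort$timepoint)), ]
  rppVals <- ratePressureProduct(visits$heart_rate, visits$systolic_bp)
  rppKw <- if (sum(table(droplevels(visits$timepoint)) >= 2L) >= 2L) {
    kt <- stats::kruskal.test(rppVals, droplevels(visits$timepoint))
    list(H = unname(kt$statistic), p = kt$p.value, reason = NA_character_)
  } else list(H = NA_real_, p = NA_real_, reason = "insufficient groups")

  out <- list(omnibus = omnibus, contrasts = contrasts, pearson = pearson,
              pairedModality = paired, rpp = rppKw,
              nExcluded = nExcluded)
  class(out) <- "StatReport"
  out
}
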