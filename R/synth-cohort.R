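#' @include AllClasses.R
NULL

.TIMEPOINTS <- c("baseline", "1wk", "1mo", "3mo", "6mo", "12mo")

#' Configuration of the synthetic longitudinal cohort
#'
#' Bundles the study-design constants of the emulated experiment: five
#' animals imaged at baseline and five follow-up visits, resting MBF around
#' 0.9 ml/min/g that rises ~25-35\% after irradiation except at the 3-month
#' visit (multiplier 1), myocardial FDG SUV rising from 1.1 +/- 0.03 at
#' baseline to 2.6 +/- 0.19 at follow-up, a target record-level MBF-SUV
#' Pearson correlation of 0.5, constant-mean rate-pressure product, and the
#' extraction fraction / hematocrit constants linking the two modalities.
#'
#' @param nAnimals number of animals (default 5).
#' @param timepoints visit labels; the first is baseline.
#' @param baselineMbfMean,baselineMbfSd resting MBF mean and SD, ml/min/g.
#' @param followupMultipliers named per-timepoint multipliers of baseline
#'   MBF (3-month multiplier 1: the transient null effect).
#' @param suvBaselineMean,suvBaselineSd,suvFollowupMean,suvFollowupSd
#'   myocardial SUV calibration.
#' @param mbfSuvCorrelation target Pearson correlation between SUV and
#'   whole-myocardium MBF across animal-by-visit records, in (-1, 1).
#' @param rppMean,rppCv rate-pressure product mean (bpm x mmHg) and
#'   coefficient of variation; the mean is constant across visits.
#' @param hrMean mean heart rate, bpm.
#' @param extractionFraction contrast extraction fraction linking
#'   Ktrans = EF x MBF (default 0.5).
#' @param hematocrit assumed blood hematocrit (default 0.45).
#' @param dceNoiseCv unbiased lognormal measurement noise CV on the DCE
#'   modality rows (default 0.05); ground-truth MBF is shared between
#'   modalities.
#' @param territorySharedFraction fraction of the per-record MBF noise
#'   variance shared across the three territories of one visit
#'   (default 0.5).
#' @param seed default RNG seed for [simulateCohort()].
#' @return a validated list of class \code{"CohortSimConfig"}.
#' @export
cohortSimConfig <- function(nAnimals = 5,
                            timepoints = .TIMEPOINTS,
                            baselineMbfMean = 0.9, baselineMbfSd = 0.1,
                            followupMultipliers = c(baseline = 1,
                              "1wk" = 1.25, "1mo" = 1.25, "3mo" = 1,
                              "6mo" = 1.3, "12mo" = 1.35),
                            suvBaselineMean = 1.1, suvBaselineSd = 0.03,
                            suvFollowupMean = 2.6, suvFollowupSd = 0.19,
                            mbfSuvCorrelation = 0.5,
                            rppMean = 9600, rppCv = 0.1, hrMean = 80,
                            extractionFraction = 0.5, hematocrit = 0.45,
                            dceNoiseCv = 0.05,
                            territorySharedFraction = 0.5,
                            seed = NULL) {
  cfg <- list(nAnimals = nAnimals, timepoints = timepoints,
              baselineMbfMean = baselineMbfMean,
              baselineMbfSd = baselineMbfSd,
              followupMultipliers = followupMultipliers,
              suvBaselineMean = suvBaselineMean,
              suvBaselineSd = suvBaselineSd,
              suvFollowupMean = suvFollowupMean,
              suvFollowupSd = suvFollowupSd,
              mbfSuvCorrelation = mbfSuvCorrelation,
              rppMean = rppMean, rppCv = rppCv, hrMean = hrMean,
              extractionFraction = extractionFraction,
              hematocrit = hematocrit, dceNoiseCv = dceNoiseCv,
              territorySharedFraction = territorySharedFraction,
              seed = seed)
  if (nAnimals < 1) stop("'nAnimals' must be >= 1")
  if (length(timepoints) < 2L || anyDuplicated(timepoints))
    stop("'timepoints' must be >= 2 distinct visit labels")
  if (!setequal(names(followupMultipliers), timepoints))
    stop("'followupMultipliers' must be named by exactly the timepoints")
  if (any(followupMultipliers <= 0)) stop("multipliers must be > 0")
  sds <- c(baselineMbfSd, suvBaselineSd, suvFollowupSd, rppCv, dceNoiseCv)
  if (any(sds < 0)) stop("all SDs / CVs must be >= 0")
  if (abs(mbfSuvCorrelation) >= 1)
    stop("'mbfSuvCorrelation' must lie in (-1, 1)")
  if (territorySharedFraction < 0 || territorySharedFraction > 1)
    stop("'territorySharedFraction' must lie in [0, 1]")
  class(cfg) <- "CohortSimConfig"
  cfg
}

# Per-timepoint mean/SD profiles implied by a config.
.cohortProfiles <- function(config) {
  tp <- config$timepoints
  mult <- config$followupMultipliers[tp]
  m <- config$baselineMbfMean * mult
  isBase <- seq_along(tp) == 1L
  s <- ifelse(isBase, config$suvBaselineMean, config$suvFollowupMean)
  ssd <- ifelse(isBase, config$suvBaselineSd, config$suvFollowupSd)
  list(timepoints = tp, mbfMean = unname(m), suvMean = unname(s),
       suvSd = unname(ssd),
       mbfCv = if (config$baselineMbfMean > 0)
         config$baselineMbfSd / config$baselineMbfMean else 0)
}

# Solve for the latent noise correlation that makes the expected
# record-level Pearson correlation between SUV and whole-myocardium MBF
# equal the configured target. The systematic time profiles (MBF and SUV
# both elevated at follow-up) contribute a between-visit covariance on
# their own; the latent coupling makes up the difference. Uses a normal
# approximation of the lognormal MBF noise (CV ~ 0.11 at defaults, where
# the approximation error is negligible). Clamped to [-1, 1] with a
# warning when the target is unattainable under the configured profiles.
.calibrateLatentCorrelation <- function(config) {
  pr <- .cohortProfiles(config)
  h <- config$territorySharedFraction
  cv <- pr$mbfCv
  m <- pr$mbfMean; s <- pr$suvMean; ssd <- pr$suvSd
  covB <- mean(m * s) - mean(m) * mean(s)
  varBM <- mean(m^2) - mean(m)^2
  varBS <- mean(s^2) - mean(s)^2
  # whole-myocardium mean over 3 territories shrinks the idiosyncratic part
  noiseVarM <- mean(m^2) * cv^2 * (h + (1 - h) / 3)
  noiseVarS <- mean(ssd^2)
  varM <- varBM + noiseVarM
  varS <- varBS + noiseVarS
  denom <- mean(ssd * m) * cv * sqrt(h)
  if (denom <= 0 || varM <= 0 || varS <= 0) return(0)
  rho <- (config$mbfSuvCorrelation * sqrt(varM * varS) - covB) / denom
  if (abs(rho) > 1) {
    warning("target MBF-SUV correlation ", config$mbfSuvCorrelation,
            " unattainable under the configured time profiles; ",
            "latent correlation clamped to ", sign(rho))
    rho <- sign(rho)
  }
  rho
}

.lnFactor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulate the longitudinal cohort table
#'
#' Draws a long-format cohort table (animal x timepoint x territory x
#' modality) with the configured effect structure: per-record MBF is
#' baseline mean x visit multiplier x lognormal noise, with a latent
#' Gaussian factor per animal-visit shared between territories and with
#' the SUV draw, calibrated so the record-level MBF-SUV Pearson
#' correlation matches the configured target; SUV is per animal-visit;
#' DCE-modality MBF shares the NH3 ground truth up to unbiased lognormal
#' measurement noise; heart rate and systolic blood pressure are drawn
#' with visit-constant means so the rate-pressure product has no time
#' trend.
#'
#' @param config a [cohortSimConfig()] list.
#' @param seed RNG seed (default \code{config$seed}).
#' @return A \code{data.frame} with columns \code{animal_id},
#'   \code{timepoint} (factor in visit order), \code{territory},
#'   \code{modality} (\code{"NH3"} or \code{"DCE"}), \code{mbf},
#'   \code{suv}, \code{heart_rate}, \code{systolic_bp}.
#' @examples
#' coh <- simulateCohort(cohortSimConfig(seed = 1))
#' head(coh)
#' @export
simulateCohort <- function(config = cohortSimConfig(), seed = config$seed) {
  stopifnot(inherits(config, "CohortSimConfig"))
  if (!is.null(seed)) set.seed(seed)
  pr <- .cohortProfiles(config)
  rho <- .calibrateLatentCorrelation(config)
  h <- config$territorySharedFraction
  cv <- pr$mbfCv
  sdlog <- sqrt(log(1 + cv^2))
  terr <- .TERRITORIES
  sbpMean <- config$rppMean / config$hrMean
  hsCv <- config$rppCv / sqrt(2)

  rows <- vector("list", config$nAnimals * length(pr$timepoints))
  k <- 0L
  for (i in seq_len(config$nAnimals)) {
    for (j in seq_along(pr$timepoints)) {
      z <- stats::rnorm(1L)
      w <- stats::rnorm(length(terr))
      zg <- sqrt(h) * z + sqrt(1 - h) * w
      mbfTruth <- pr$mbfMean[j] * exp(sdlog * zg - sdlog^2 / 2)
      v <- stats::rnorm(1L)
      suv <- max(0, pr$suvMean[j] +
                   pr$suvSd[j] * (rho * z + sqrt(max(0, 1 - rho^2)) * v))
      hr <- config$hrMean * .lnFactor(1L, hsCv)
      sbp <- sbpMean * .lnFactor(1L, hsCv)
      dceNoise <- .lnFactor(length(terr), config$dceNoiseCv)
      k <- k + 1L
      rows[[k]] <- data.frame(
        animal_id = paste0("A", i),
        timepoint = pr$timepoints[j],
        territory = rep(terr, 2L),
        modality = rep(c("NH3", "DCE"), each = length(terr)),
        mbf = c(mbfTruth, mbfTruth * dceNoise),
        suv = suv, heart_rate = hr, systolic_bp = sbp,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$timepoint <- factor(out$timepoint, levels = pr$timepoints)
  rownames(out) <- NULL
  validateCohort(out)
  out
}

#' Validate a cohort table
#'
#' Checks the long-format cohort contract: required columns, non-negative
#' MBF and SUV (NAs allowed, e.g. QC-excluded DCE points), and no
#' duplicated (animal, timepoint, territory, modality) keys.
#'
#' @param cohort a data.frame.
#' @return the cohort, invisibly, or an error.
#' @export
validateCohort <- function(cohort) {
  req <- c("animal_id", "timepoint", "territory", "modality", "mbf",
           "suv", "heart_rate", "systolic_bp")
  missing <- setdiff(req, names(cohort))
  if (length(missing))
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "))
  if (any(cohort$mbf < 0, na.rm = TRUE)) stop("mbf must be >= 0")
  if (any(cohort$suv < 0, na.rm = TRUE)) stop("suv must be >= 0")
  key <- with(cohort, paste(animal_id, timepoint, territory, modality))
  if (anyDuplicated(key))
    stop("duplicate (animal, timepoint, territory, modality) keys")
  invisible(cohort)
}

#' Collapse a cohort to whole-myocardium records
#'
#' Averages MBF over the three coronary territories of each
#' animal-by-visit-by-modality cell (unweighted mean, NA if any territory
#' is missing); SUV, heart rate and blood pressure are per-visit and
#' carried through.
#'
#' @param cohort a cohort data.frame (see [simulateCohort()]).
#' @return a data.frame with one row per animal x timepoint x modality and
#'   territory \code{"GLOBAL"}.
#' @export
cohortWholeMyocardium <- function(cohort) {
  validateCohort(cohort)
  sp <- split(cohort,
              list(cohort$animal_id, cohort$timepoint, cohort$modality),
              drop = TRUE)
  rows <- lapply(sp, function(d) {
    data.frame(animal_id = d$animal_id[1L], timepoint = d$timepoint[1L],
               territory = "GLOBAL", modality = d$modality[1L],
               mbf = mean(d$mbf), suv = d$suv[1L],
               heart_rate = d$heart_rate[1L],
               systolic_bp = d$systolic_bp[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$animal_id, out$timepoint, out$modality), ]
}

#' Read / write a cohort table as CSV
#'
#' Long-format CSV with the cohort columns; timepoint levels are restored
#' in visit order on read.
#'
#' @param cohort a cohort data.frame.
#' @param path file path.
#' @param timepoints visit order for the timepoint factor.
#' @return \code{readCohort}: the cohort data.frame;
#'   \code{writeCohort}: the path, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  validateCohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path, timepoints = .TIMEPOINTS) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  lv <- intersect(timepoints, unique(out$timepoint))
  out$timepoint <- factor(out$timepoint,
                          levels = c(lv, setdiff(unique(out$timepoint), lv)))
  validateCohort(out)
  out
}
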