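#' Cohort specification for the synthetic study population
#'
#' Default values reproduce the study conditions of the emulated cohort:
#' 30 current hormonal-contraceptive (HC) users, 17 past users and 7
#' never-users; group N1 slope distributions Normal(-0.080, 0.033) for
#' current users and Normal(-0.052, 0.040) for non-users (microvolts/dB),
#' P2 slopes Normal(0.120, 0.068) vs Normal(0.084, 0.046), with N1 and P2
#' slope variation treated as independent so the N1P2 slope is their
#' difference by construction. Ages, menstrual-phase frequencies,
#' adverse-mood prevalence and the combined vs progestin-only split follow
#' the cohort's descriptive table; BDI-II subscale scores are drawn from
#' right-skewed negative-binomial distributions calibrated so roughly a
#' third of subjects exceed the clinical cut-off of 13.
#'
#' @param nCurrent,nPast,nNever group sizes.
#' @param n1SlopeUsers,n1SlopeNonusers c(mean, sd) of true N1 slopes
#'   (microvolts/dB; negative = amplitude grows more negative with loudness).
#' @param p2SlopeUsers,p2SlopeNonusers c(mean, sd) of true P2 slopes.
#' @param ageCurrent,agePast,ageNever c(mean, sd) of age (years).
#' @param bdiCognitive,bdiSomatic c(mu, size) of the negative-binomial
#'   subscale score distributions.
#' @param adverseMoodShift mean of the Poisson count added to the
#'   somatic-affective subscale of subjects reporting adverse mood effects
#'   (calibrated to a medium standardized effect).
#' @param adverseProb probability of reporting adverse mood effects, per
#'   group (current, past, never).
#' @param combinedFraction fraction of current users on combined (vs
#'   progestin-only) formulations.
#' @param noiseSigmaUv background pink-noise RMS per channel (microvolts).
#' @param blinkRateHz mean blink rate (Hz).
#' @param lineAmpUv 50 Hz line-noise amplitude (microvolts).
#' @param seed integer seed.
#' @return Object of class \code{cohortSpec}.
#' @export
cohortSpec <- function(nCurrent = 30, nPast = 17, nNever = 7,
                       n1SlopeUsers = c(-0.080, 0.033),
                       n1SlopeNonusers = c(-0.052, 0.040),
                       p2SlopeUsers = c(0.120, 0.068),
                       p2SlopeNonusers = c(0.084, 0.046),
                       ageCurrent = c(25.3, 3.9),
                       agePast = c(27.2, 5.2),
                       ageNever = c(23.4, 3.4),
                       bdiCognitive = c(4, 2),
                       bdiSomatic = c(6.5, 3),
                       adverseMoodShift = 3,
                       adverseProb = c(11 / 30, 14 / 17, 0),
                       combinedFraction = 17 / 30,
                       noiseSigmaUv = 10,
                       blinkRateHz = 0.25,
                       lineAmpUv = 5,
                       seed = 1L) {
  sds <- c(n1SlopeUsers[2], n1SlopeNonusers[2],
           p2SlopeUsers[2], p2SlopeNonusers[2])
  if (any(sds < 0)) stop("slope SDs must be >= 0")
  if (any(c(nCurrent, nPast + nNever) < 1))
    stop("each analysis group needs at least one subject")
  structure(as.list(environment()), class = "cohortSpec")
}

# truncated-normal draws by resampling out-of-range values
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws one \code{SubjectProfile} row per subject: group membership, HC
#' type, age, BDI-II subscale scores, menstrual phase, adverse-mood flag,
#' and the generative ERP parameters (true N1/P2 intercepts at 75 dB and
#' slopes, noise levels). Component intercepts are truncated so the N1
#' response stays negative and P2 positive across 55-95 dB for all
#' plausible slope draws.
#'
#' @param spec A \code{\link{cohortSpec}}.
#' @return A list with elements \code{profiles} (data.frame, one row per
#'   subject, including generative parameters) and \code{cohort} (the
#'   covariate table consumed by the statistics layer, including the true
#'   slopes for recovery tests).
#' @examples
#' cs <- cohortSpec(seed = 7)
#' cohort <- generateCohort(cs)$cohort
#' table(cohort$group)
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "cohortSpec"))
  n <- c(current_user = spec$nCurrent, past_user = spec$nPast,
         never_user = spec$nNever)
  nTot <- sum(n)
  group <- rep(names(n), n)
  isUser <- group == "current_user"

  withSeed(spec$seed, {
    n1 <- ifelse(isUser,
      stats::rnorm(nTot, spec$n1SlopeUsers[1], spec$n1SlopeUsers[2]),
      stats::rnorm(nTot, spec$n1SlopeNonusers[1], spec$n1SlopeNonusers[2]))
    p2 <- ifelse(isUser,
      stats::rnorm(nTot, spec$p2SlopeUsers[1], spec$p2SlopeUsers[2]),
      stats::rnorm(nTot, spec$p2SlopeNonusers[1], spec$p2SlopeNonusers[2]))
    n1Int <- rtruncnorm(nTot, -5, 0.8, upper = -4)
    p2Int <- rtruncnorm(nTot, 5, 0.8, lower = 4)
    ageMean <- c(current_user = spec$ageCurrent[1], past_user = spec$agePast[1],
                 never_user = spec$ageNever[1])[group]
    ageSd <- c(current_user = spec$ageCurrent[2], past_user = spec$agePast[2],
               never_user = spec$ageNever[2])[group]
    age <- round(rtruncnorm(nTot, ageMean, ageSd, lower = 18, upper = 40), 1)
    bdiCog <- stats::rnbinom(nTot, mu = spec$bdiCognitive[1],
                             size = spec$bdiCognitive[2])
    bdiSom <- stats::rnbinom(nTot, mu = spec$bdiSomatic[1],
                             size = spec$bdiSomatic[2])
    advP <- c(current_user = spec$adverseProb[1],
              past_user = spec$adverseProb[2],
              never_user = spec$adverseProb[3])[group]
    adverse <- stats::rbinom(nTot, 1, advP) == 1
    bdiSom <- bdiSom + ifelse(adverse,
                              stats::rpois(nTot, spec$adverseMoodShift), 0)
    phases <- c("follicular", "ovulatory", "luteal", "unknown")
    phaseProbs <- list(current_user = c(8, 6, 6, 10) / 30,
                       past_user = c(4, 4, 6, 3) / 17,
                       never_user = c(2, 1, 3, 1) / 7)
    phase <- vapply(group, function(g)
      sample(phases, 1, prob = phaseProbs[[g]]), character(1))
    nComb <- round(spec$nCurrent * spec$combinedFraction)
    hcType <- rep("none", nTot)
    hcType[isUser] <- sample(rep(c("combined", "progestin_only"),
                                 c(nComb, spec$nCurrent - nComb)))
    NULL
  })

  profiles <- data.frame(
    subject_id = sprintf("sub-%02d", seq_len(nTot)),
    group = group,
    hc_type = hcType,
    age = age,
    bdi_cognitive = bdiCog,
    bdi_somatic_affective = bdiSom,
    menstrual_phase = phase,
    adverse_mood = adverse,
    true_n1_intercept_uv = n1Int,
    true_n1_slope_uv_per_db = n1,
    true_p2_intercept_uv = p2Int,
    true_p2_slope_uv_per_db = p2,
    noise_sigma_uv = spec$noiseSigmaUv,
    blink_rate_hz = spec$blinkRateHz,
    line_amp_uv = spec$lineAmpUv,
    stringsAsFactors = FALSE
  )
  cohort <- cohortTableFromProfiles(profiles)
  list(profiles = profiles, cohort = cohort)
}

#' Build a covariate table from subject profiles
#'
#' Adds the derived BDI-II total and clinical-threshold indicator
#' (total >= 13) to the per-subject covariates; true slopes are carried
#' along for ground-truth recovery checks.
#'
#' @param profiles data.frame as returned by \code{\link{generateCohort}}.
#' @param bdiCutoff clinical BDI-II cut-off (default 13).
#' @return data.frame, one row per subject.
#' @export
cohortTableFromProfiles <- function(profiles, bdiCutoff = 13) {
  tot <- profiles$bdi_cognitive + profiles$bdi_somatic_affective
  data.frame(
    subject_id = profiles$subject_id,
    group = profiles$group,
    hc_type = profiles$hc_type,
    age = profiles$age,
    bdi_cognitive = profiles$bdi_cognitive,
    bdi_somatic_affective = profiles$bdi_somatic_affective,
    bdi_total = tot,
    above_bdi_threshold = tot >= bdiCutoff,
    menstrual_phase = profiles$menstrual_phase,
    adverse_mood = profiles$adverse_mood,
    true_n1_slope = profiles$true_n1_slope_uv_per_db,
    true_p2_slope = profiles$true_p2_slope_uv_per_db,
    true_n1p2_slope = profiles$true_p2_slope_uv_per_db -
      profiles$true_n1_slope_uv_per_db,
    stringsAsFactors = FALSE
  )
}
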