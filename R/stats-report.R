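#' Merge past and never users into a single non-user group
#'
#' The primary contrast compares all current hormonal-contraceptive users
#' (formulations pooled) with everyone else; past and never users are
#' merged because they do not differ on demographics or outcomes and the
#' never-user subgroup is small.
#'
#' @param cohort cohort data.frame with a \code{group} column containing
#'   \code{current_user} / \code{past_user} / \code{never_user}.
#' @return The cohort with an added two-level \code{group2} factor
#'   (\code{users}, \code{non_users}).
#' @export
mergeNonUsers <- function(cohort) {
  cohort$group2 <- factor(ifelse(cohort$group == "current_user",
                                 "users", "non_users"),
                          levels = c("users", "non_users"))
  cohort
}

reportRow <- function(analysis, outcome, test, statistic = NA, df = NA,
                      p = NA, effect = NA, note = "") {
  data.frame(analysis = analysis, outcome = outcome, test = test,
             statistic = as.numeric(statistic), df = as.character(df),
             p = as.numeric(p), effect = as.numeric(effect), note = note,
             stringsAsFactors = FALSE)
}

#' Run the full group-level analysis plan
#'
#' Executes, on a cohort covariate-plus-LDAEP table: the user/non-user
#' merge; per-slope normality screening, one-way ANOVA and Type II ANCOVA
#' (age + BDI-II cognitive and somatic-affective subscales as covariates);
#' Wilcoxon contrasts on BDI-II scores; t tests of slopes across the
#' clinical BDI-II threshold (full sample and within groups); menstrual
#' phase ANOVAs within users and non-users; combined vs progestin-only
#' contrasts within current users; and adverse-mood contrasts (slope t
#' tests, BDI Wilcoxon, Fisher on the threshold indicator). Analyses whose
#' subgroups are degenerate are skipped with an explicit notice row.
#'
#' @param cohort data.frame with columns \code{group}, the three slope
#'   columns, \code{age}, \code{bdi_cognitive}, \code{bdi_somatic_affective}
#'   (plus \code{bdi_total}, \code{above_bdi_threshold},
#'   \code{menstrual_phase}, \code{hc_type}, \code{adverse_mood} for the
#'   secondary analyses when present).
#' @param slopeCols names of the slope columns.
#' @param covariates ANCOVA covariates.
#' @return Object of class \code{ldaepReport}: a named list of data.frames
#'   (\code{normality}, \code{anova}, \code{ancova}, \code{emm},
#'   \code{bdi}, \code{bdi_threshold}, \code{phase}, \code{hc_type},
#'   \code{adverse_mood}, \code{notices}).
#' @export
runGroupAnalysis <- function(cohort,
                             slopeCols = c("n1_slope", "p2_slope",
                                           "n1p2_slope"),
                             covariates = c("age", "bdi_cognitive",
                                            "bdi_somatic_affective")) {
  required <- c("group", slopeCols, covariates)
  missingCols <- setdiff(required, names(cohort))
  if (length(missingCols))
    stop("cohort is missing required columns: ",
         paste(missingCols, collapse = ", "))
  cohort <- mergeNonUsers(cohort)
  notices <- character(0)
  out <- list()

  twoGroups <- length(unique(cohort$group2)) == 2 &&
    all(table(cohort$group2) >= 2)

  ## normality screen
  out$normality <- do.call(rbind, lapply(slopeCols, function(sc) {
    do.call(rbind, lapply(split(cohort[[sc]], cohort$group2), function(v) {
      if (length(v) >= 5 && stats::sd(v) > 0) {
        k <- ksNormality(v)
        reportRow("normality", sc, "lilliefors_ks", k$statistic, NA, k$p)
      } else NULL
    }))
  }))

  if (!twoGroups) {
    notices <- c(notices,
                 "between-group analyses skipped: fewer than 2 usable groups")
  } else {
    ## primary ANOVA per slope
    out$anova <- do.call(rbind, lapply(slopeCols, function(sc) {
      a <- oneWayAnova(cohort[[sc]], cohort$group2)
      reportRow("group_anova", sc, "one_way_anova", a$F,
                sprintf("(%d, %d)", a$df1, a$df2), a$p, a$partialEtaSq)
    }))
    ## ANCOVA per slope (skipped, with notice, when the cohort is too
    ## small to support the covariate model)
    if (nrow(cohort) > length(covariates) + 3) {
      anc <- lapply(slopeCols, function(sc)
        ancovaType2(cohort, sc, "group2", covariates))
      names(anc) <- slopeCols
      out$ancova <- do.call(rbind, lapply(slopeCols, function(sc) {
        g <- anc[[sc]]$terms[anc[[sc]]$terms$term == "group2", ]
        reportRow("group_ancova", sc, "type2_ancova", g$F,
                  sprintf("(%d, %d)", g$df, anc[[sc]]$residDf), g$p,
                  g$partialEtaSq)
      }))
      out$emm <- do.call(rbind, lapply(slopeCols, function(sc) {
        e <- anc[[sc]]$emm
        data.frame(outcome = sc, group = e$group, emmean = e$emmean,
                   se = e$se, stringsAsFactors = FALSE)
      }))
    } else {
      notices <- c(notices, "ancova skipped: too few observations")
    }
    ## BDI contrasts (Wilcoxon)
    bdiCols <- intersect(c("bdi_total", "bdi_cognitive",
                           "bdi_somatic_affective"), names(cohort))
    out$bdi <- do.call(rbind, lapply(bdiCols, function(bc) {
      w <- wilcoxonRankSum(cohort[[bc]][cohort$group2 == "users"],
                           cohort[[bc]][cohort$group2 == "non_users"])
      reportRow("bdi_group", bc, "wilcoxon_rank_sum", w$W, NA, w$p)
    }))
  }

  ## BDI-threshold stratified slope t tests
  if ("above_bdi_threshold" %in% names(cohort)) {
    strata <- list(full_sample = cohort,
                   users = cohort[cohort$group2 == "users", ],
                   non_users = cohort[cohort$group2 == "non_users", ])
    out$bdi_threshold <- do.call(rbind, lapply(names(strata), function(st) {
      d <- strata[[st]]
      hi <- d$above_bdi_threshold
      if (sum(hi) < 2 || sum(!hi) < 2) {
        notices <<- c(notices, paste0("bdi_threshold skipped in ", st,
                                      ": degenerate split"))
        return(NULL)
      }
      do.call(rbind, lapply(slopeCols, function(sc) {
        t <- twoSampleT(d[[sc]][hi], d[[sc]][!hi])
        reportRow(paste0("bdi_threshold_", st), sc, "t_test", t$t,
                  round(t$df, 1), t$p, t$d)
      }))
    }))
  }

  ## menstrual phase ANOVAs within users and non-users
  if ("menstrual_phase" %in% names(cohort)) {
    out$phase <- do.call(rbind, lapply(c("users", "non_users"),
                                       function(gr) {
      d <- cohort[cohort$group2 == gr &
                    cohort$menstrual_phase %in%
                    c("follicular", "ovulatory", "luteal"), ]
      ph <- factor(d$menstrual_phase)
      if (nlevels(droplevels(ph)) < 2 || any(table(droplevels(ph)) < 2)) {
        notices <<- c(notices, paste0("phase ANOVA skipped in ", gr,
                                      ": degenerate phase split"))
        return(NULL)
      }
      do.call(rbind, lapply(slopeCols, function(sc) {
        a <- oneWayAnova(d[[sc]], droplevels(ph))
        reportRow(paste0("phase_", gr), sc, "one_way_anova", a$F,
                  sprintf("(%d, %d)", a$df1, a$df2), a$p, a$partialEtaSq)
      }))
    }))
  }

  ## HC type within current users
  if ("hc_type" %in% names(cohort)) {
    d <- cohort[cohort$group == "current_user", ]
    if (sum(d$hc_type == "combined") >= 2 &&
        sum(d$hc_type == "progestin_only") >= 2) {
      out$hc_type <- do.call(rbind, lapply(slopeCols, function(sc) {
        t <- twoSampleT(d[[sc]][d$hc_type == "combined"],
                        d[[sc]][d$hc_type == "progestin_only"])
        reportRow("hc_type", sc, "t_test", t$t, round(t$df, 1), t$p, t$d)
      }))
    } else {
      notices <- c(notices, "hc_type contrast skipped: degenerate split")
    }
  }

  ## adverse mood effects within current users
  if (all(c("adverse_mood", "above_bdi_threshold") %in% names(cohort))) {
    d <- cohort[cohort$group == "current_user", ]
    if (sum(d$adverse_mood) >= 2 && sum(!d$adverse_mood) >= 2) {
      slopeRows <- do.call(rbind, lapply(slopeCols, function(sc) {
        t <- twoSampleT(d[[sc]][d$adverse_mood], d[[sc]][!d$adverse_mood])
        reportRow("adverse_mood", sc, "t_test", t$t, round(t$df, 1), t$p,
                  t$d)
      }))
      bdiCols <- intersect(c("bdi_total", "bdi_cognitive",
                             "bdi_somatic_affective"), names(d))
      bdiRows <- do.call(rbind, lapply(bdiCols, function(bc) {
        w <- wilcoxonRankSum(d[[bc]][d$adverse_mood],
                             d[[bc]][!d$adverse_mood])
        reportRow("adverse_mood", bc, "wilcoxon_rank_sum", w$W, NA, w$p)
      }))
      tab <- table(d$adverse_mood, d$above_bdi_threshold)
      fisherRow <- if (all(dim(tab) == c(2, 2))) {
        f <- contingencyTest(tab, "fisher")
        reportRow("adverse_mood", "above_bdi_threshold", "fisher_exact",
                  NA, NA, f$p)
      } else NULL
      out$adverse_mood <- rbind(slopeRows, bdiRows, fisherRow)
    } else {
      notices <- c(notices, "adverse_mood contrast skipped: degenerate split")
    }
  }

  out$notices <- notices
  class(out) <- "ldaepReport"
  out
}

#' @export
print.ldaepReport <- function(x, ...) {
  for (nm in setdiff(names(x), "notices")) {
    if (is.null(x[[nm]])) next
    cat("==", nm, "==\n")
    print(x[[nm]], digits = 4, row.names = FALSE)
    cat("\n")
  }
  if (length(x$notices)) {
    cat("notices:\n")
    for (n in x$notices) cat(" -", n, "\n")
  }
  invisible(x)
}

#' Write a group-analysis report to CSV files
#'
#' One tidy CSV per analysis table, plus a plain-text notice file.
#'
#' @param report an \code{ldaepReport}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in setdiff(names(report), "notices")) {
    if (is.null(report[[nm]])) next
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(report[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (length(report$notices)) {
    p <- file.path(dir, "notices.txt")
    writeLines(report$notices, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
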