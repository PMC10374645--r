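## Survival association of states and ecotypes: Mantel-Cox log-rank
## comparisons, Cox proportional-hazards fits (Breslow ties), one-vs-rest
## screens labeling units adverse (HR > 1) or favorable (HR < 1), and
## therapy-benefit screening by responder/non-responder stratification
## within units. Fits are delegated to the survival package.

#' @importFrom survival Surv survdiff coxph survfit
NULL

# Align a named per-sample vector with a SurvivalData object.
alignToSurvival <- function(x, surv) {
  common <- intersect(names(x), surv@sampleIDs)
  if (!length(common)) stop("no samples shared with the survival data")
  i <- match(common, surv@sampleIDs)
  list(x = x[common], time = surv@time[i], event = surv@event[i],
       response = if (is.null(surv@response)) NULL else surv@response[i])
}

#' Mantel-Cox log-rank test
#'
#' Observed-versus-expected event tabulation at each distinct event time
#' across two or more groups; the statistic is chi-square distributed with
#' \code{groups - 1} degrees of freedom under the null.
#'
#' @param surv a \linkS4class{SurvivalData}.
#' @param groups group labels, named by sample id.
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
logRankTest <- function(surv, groups) {
  al <- alignToSurvival(groups, surv)
  g <- factor(al$x)
  if (nlevels(g) < 2) stop("log-rank requires at least 2 non-empty groups")
  if (sum(al$event) < 1) stop("log-rank requires at least 1 event")
  sd <- survdiff(Surv(al$time, al$event) ~ g)
  df <- nlevels(g) - 1L
  stat <- unname(sd$chisq)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit for one covariate
#'
#' Newton-Raphson partial-likelihood maximization with Breslow tie
#' handling; returns the hazard ratio with Wald 95% confidence interval and
#' p-value. Monotone-likelihood (separation) and other non-convergence is
#' reported via \code{converged = FALSE}, in which case the estimate must
#' not be interpreted.
#'
#' @param surv a \linkS4class{SurvivalData}.
#' @param covariate numeric or binary covariate, named by sample id.
#' @return list with \code{logHR}, \code{HR}, \code{ciLow}, \code{ciHigh},
#'   \code{p}, \code{converged}.
#' @export
fitCox <- function(surv, covariate) {
  al <- alignToSurvival(covariate, surv)
  x <- as.numeric(al$x)
  if (length(unique(x)) < 2) stop("covariate does not vary")
  if (length(unique(x)) == 2) {
    ev <- tapply(al$event, x, sum)
    if (any(ev < 5))
      warning("fewer than 5 events in a covariate level; estimate unstable")
  }
  converged <- TRUE
  fit <- withCallingHandlers(
    coxph(Surv(al$time, al$event) ~ x, ties = "breslow"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|Loglik", w$message,
                ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  b <- unname(coef(fit))
  se <- sm$coefficients[1, "se(coef)"]
  if (!is.finite(b) || !is.finite(se)) converged <- FALSE
  list(logHR = b, HR = exp(b),
       ciLow = exp(b - 1.96 * se), ciHigh = exp(b + 1.96 * se),
       p = sm$coefficients[1, "Pr(>|z|)"], converged = converged)
}

#' One-vs-rest survival screen of states or ecotypes
#'
#' For each unit (a state or ecotype label), compares the samples in the
#' unit against all others with a Cox fit and a log-rank test. Direction is
#' adverse when HR > 1, favorable when HR < 1; significance uses the raw
#' Cox p at 0.05 by default (no multiplicity correction, with a
#' Benjamini-Hochberg option). Undersized units are skipped with a reason.
#'
#' @param units per-sample unit labels, named by sample id.
#' @param surv a \linkS4class{SurvivalData}.
#' @param minGroup minimum in-unit (and out-of-unit) sample count.
#' @param adjust "none" (default) or "BH".
#' @return data.frame with one row per unit: n, HR, ciLow, ciHigh, coxP,
#'   logRankP, adjustedP, direction, significant, reason.
#' @export
stateSurvivalScreen <- function(units, surv, minGroup = 10,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  al <- alignToSurvival(units, surv)
  labels <- sort(unique(al$x))
  rows <- lapply(labels, function(u) {
    inU <- al$x == u
    out <- data.frame(unit = u, n = sum(inU), HR = NA_real_,
                      ciLow = NA_real_, ciHigh = NA_real_, coxP = NA_real_,
                      logRankP = NA_real_, direction = NA_character_,
                      significant = FALSE, reason = "",
                      stringsAsFactors = FALSE)
    if (sum(inU) < minGroup) {
      out$reason <- sprintf("in-group size %d < %d", sum(inU), minGroup)
      return(out)
    }
    if (sum(!inU) < minGroup) {
      out$reason <- "no adequate comparison group"
      return(out)
    }
    sub <- SurvivalData(names(al$x), al$time, al$event)
    cx <- fitCox(sub, setNames(as.numeric(inU), names(al$x)))
    lr <- logRankTest(sub, setNames(ifelse(inU, "in", "out"), names(al$x)))
    out$HR <- cx$HR
    out$ciLow <- cx$ciLow
    out$ciHigh <- cx$ciHigh
    out$coxP <- cx$p
    out$logRankP <- lr$p
    out$direction <- if (cx$HR > 1) "adverse" else "favorable"
    if (!cx$converged) out$reason <- "Cox fit did not converge"
    out
  })
  tab <- do.call(rbind, rows)
  tab$adjustedP <- if (adjust == "BH") p.adjust(tab$coxP, "BH") else tab$coxP
  tested <- tab$reason == ""
  tab$significant <- tested & !is.na(tab$adjustedP) & tab$adjustedP < 0.05
  tab
}

# Restricted mean survival time: area under the Kaplan-Meier curve to tau.
rmstKM <- function(time, event, tau) {
  fit <- survfit(Surv(time, event) ~ 1)
  t <- c(0, fit$time[fit$time <= tau], tau)
  s <- c(1, fit$surv[fit$time <= tau])
  sum(diff(t) * s)
}

#' Therapy-benefit screen within states or ecotypes
#'
#' Within each unit, compares responders against non-responders by
#' log-rank; a unit is flagged as benefiting when the log-rank p is below
#' 0.05 and the responders' restricted mean survival (to the unit's last
#' follow-up) exceeds the non-responders' — the directional condition the
#' two-sided log-rank test lacks. Units with an empty response arm are
#' skipped with a reason.
#'
#' @param units per-sample unit labels, named by sample id.
#' @param surv a \linkS4class{SurvivalData} with response labels.
#' @param minArm minimum samples per response arm.
#' @return data.frame with one row per unit: nResponder, nNonResponder,
#'   logRankP, rmstResponder, rmstNonResponder, benefit, reason.
#' @export
therapyBenefit <- function(units, surv, minArm = 2) {
  if (is.null(surv@response))
    stop("survival data carry no response labels")
  al <- alignToSurvival(units, surv)
  ok <- !is.na(al$response)
  labels <- sort(unique(al$x[ok]))
  rows <- lapply(labels, function(u) {
    inU <- ok & al$x == u
    resp <- al$response[inU] == "responder"
    out <- data.frame(unit = u, nResponder = sum(resp),
                      nNonResponder = sum(!resp), logRankP = NA_real_,
                      rmstResponder = NA_real_, rmstNonResponder = NA_real_,
                      benefit = FALSE, reason = "", stringsAsFactors = FALSE)
    if (sum(resp) < minArm || sum(!resp) < minArm) {
      out$reason <- "a response arm is empty or too small"
      return(out)
    }
    tU <- al$time[inU]
    eU <- al$event[inU]
    if (sum(eU) < 1) {
      out$reason <- "no events in unit"
      return(out)
    }
    sub <- SurvivalData(names(al$x)[inU], tU, eU)
    lr <- logRankTest(sub, setNames(ifelse(resp, "R", "NR"),
                                    names(al$x)[inU]))
    tau <- max(tU)
    out$logRankP <- lr$p
    out$rmstResponder <- rmstKM(tU[resp], eU[resp], tau)
    out$rmstNonResponder <- rmstKM(tU[!resp], eU[!resp], tau)
    out$benefit <- lr$p < 0.05 && out$rmstResponder > out$rmstNonResponder
    out
  })
  do.call(rbind, rows)
}
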