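#' Kaplan-Meier curves and one-tailed log-rank test for score strata
#'
#' Product-limit survival estimates for the high- and low-score strata and a
#' log-rank comparison. The one-tailed p-value tests the direction
#' "high score implies worse survival": the two-sided p is halved when the
#' high stratum shows more events than expected, and is `1 - p/2` otherwise.
#'
#' @param scores data.frame from [score_patients()] (patient_id, stratum).
#' @param surv data.frame: patient_id, time, event.
#' @return list: `fit` (a [survival::survfit] object), `table` (time,
#'   n_risk, n_event, survival, stratum), `chisq`, `p_two_sided`,
#'   `p_one_sided`.
#' @export
km_logrank <- function(scores, surv) {
  dat <- merge(scores[, c("patient_id", "stratum")], surv, by = "patient_id")
  if (length(unique(dat$stratum)) < 2)
    stop("need two strata for a log-rank comparison", call. = FALSE)
  if (any(tapply(dat$event, dat$stratum, sum) < 1))
    stop("each stratum needs at least one event", call. = FALSE)
  dat$stratum <- factor(dat$stratum, levels = c("low", "high"))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ stratum, data = dat)
  p2 <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  hi <- which(grepl("high", names(sd_$n)))
  worse_high <- (sd_$obs[hi] - sd_$exp[hi]) > 0
  p1 <- if (isTRUE(worse_high)) p2 / 2 else 1 - p2 / 2
  fit <- survival::survfit(survival::Surv(time, event) ~ stratum, data = dat)
  sm <- summary(fit)
  tab <- data.frame(time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
                    survival = sm$surv,
                    stratum = sub("stratum=", "", as.character(sm$strata)))
  list(fit = fit, table = tab, chisq = unname(sd_$chisq),
       p_two_sided = p2, p_one_sided = unname(p1))
}

#' Cox proportional-hazards association of community scores with survival
#'
#' Fits `Surv(time, event) ~ score` (univariate) and, when covariates are
#' given, `Surv(time, event) ~ score + covariates` (multivariate) by partial
#' likelihood with the Efron approximation for ties. Wald tests are
#' reported two-sided and one-sided (direction: positive coefficient,
#' i.e. higher score implies higher hazard). The baseline can optionally be
#' stratified by a grouping column.
#'
#' @param scores data.frame with patient_id and a `score` column.
#' @param surv data.frame: patient_id, time, event, plus covariate columns.
#' @param covariates character vector of covariate column names in `surv`
#'   (ordinal covariates are used numerically as provided).
#' @param strata_by optional column name for a stratified baseline hazard.
#' @return data.frame: model ("univariate"/"multivariate"), term, coef,
#'   hr, se, p_wald (two-sided), p_one_sided, converged.
#' @export
cox_ph <- function(scores, surv, covariates = NULL, strata_by = NULL) {
  dat <- merge(scores[, c("patient_id", "score")], surv, by = "patient_id")
  for (cv in covariates)
    if (stats::sd(as.numeric(dat[[cv]])) == 0)
      stop("covariate ", cv, " has zero variance", call. = FALSE)
  fit_one <- function(terms, label) {
    fm <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                  paste(terms, collapse = " + ")))
    fit <- tryCatch(survival::coxph(fm, data = dat, ties = "efron"),
                    warning = function(w) {
                      f <- suppressWarnings(survival::coxph(fm, data = dat,
                                                            ties = "efron"))
                      attr(f, "nonconverged") <- conditionMessage(w)
                      f
                    })
    s <- summary(fit)$coefficients
    data.frame(model = label, term = rownames(s), coef = s[, "coef"],
               hr = s[, "exp(coef)"], se = s[, "se(coef)"],
               p_wald = s[, "Pr(>|z|)"],
               p_one_sided = ifelse(s[, "coef"] > 0, s[, "Pr(>|z|)"] / 2,
                                    1 - s[, "Pr(>|z|)"] / 2),
               converged = is.null(attr(fit, "nonconverged")),
               row.names = NULL)
  }
  strat <- if (!is.null(strata_by)) sprintf("strata(%s)", strata_by) else NULL
  out <- fit_one(c("score", strat), "univariate")
  if (length(covariates))
    out <- rbind(out, fit_one(c("score", covariates, strat), "multivariate"))
  out
}
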