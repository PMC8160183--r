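# Liability-threshold machinery: morbid risk, threshold, conditional means.
#
# A binary trait is modelled as the indicator that a latent standard-normal
# liability exceeds the threshold T set by the lifetime morbid risk K:
# T = Phi^{-1}(1 - K). Affected individuals then carry the conditional mean
# liability above the threshold, z+ = phi(T)/K, and unaffected individuals
# z- = -phi(T)/(1 - K), so that K z+ + (1 - K) z- = 0.

K_EPS <- 1e-6

#' Estimate lifetime morbid risk from ages at first registration
#'
#' Cumulative incidence by the last observed event age, from the product-limit
#' (Kaplan-Meier) estimator over age with events at `age_at_first_registration`
#' and censoring at `censor_age`. Death is treated as censoring (no
#' competing-risk correction). When no one is censored before the last event
#' this reduces to the simple affected proportion.
#'
#' @param cohort an `fgrs_cohort`.
#' @param trait trait code to estimate the risk for.
#' @param strata `NULL` for a single pooled estimate (the default), `"sex"`,
#'   `"birth_year"`, or both, for stratified estimates.
#' @param birth_band width in years of birth-year strata (used only when
#'   stratifying by birth year).
#' @param eps clamp: K is forced into `[eps, 1 - eps]`.
#' @return an `fgrs_prevalence` object: a data.table with columns `trait`,
#'   `stratum` and `K`.
#' @export
estimate_morbid_risk <- function(cohort, trait, strata = NULL, birth_band = 10L,
                                 eps = K_EPS) {
  stopifnot(inherits(cohort, "fgrs_cohort"))
  if (!is.null(strata) && !all(strata %in% c("sex", "birth_year")))
    stop_fgrs("fgrs_domain_error", "strata must be NULL, 'sex' and/or 'birth_year'")
  tr <- trait
  d <- cohort$diagnoses[trait == tr, .(person_id, onset = age_at_first_registration)]
  p <- merge(cohort$persons, d, by = "person_id", all.x = TRUE)
  p[, event := !is.na(onset)]
  p[, time := fifelse(event, onset, censor_age)]

  p[, stratum := "all"]
  if ("sex" %in% strata) p[, stratum := sex]
  if ("birth_year" %in% strata) {
    band <- band_of(p$birth_year, birth_band)
    p[, stratum := if ("sex" %in% strata) paste(sex, band, sep = ":") else band]
  }

  est_one <- function(time, event, label) {
    if (!any(event))
      stop_fgrs("fgrs_estimation_error",
                paste0("no '%s' events in stratum '%s'; merge strata or supply",
                       " K externally"), tr, label)
    sf <- survfit(Surv(time, event) ~ 1)
    s_last <- tail(sf$surv[sf$n.event > 0], 1)
    min(max(1 - s_last, eps), 1 - eps)
  }
  out <- p[, .(K = est_one(time, event, .BY$stratum)), by = stratum]
  structure(data.table(trait = tr, out), class = c("fgrs_prevalence", "data.table"))
}

band_of <- function(birth_year, band) {
  lo <- (birth_year %/% band) * band
  sprintf("%d-%d", lo, lo + band - 1L)
}

#' Liability threshold and conditional mean z-scores for a prevalence
#'
#' @param K lifetime morbid risk, in (0, 1).
#' @return an `fgrs_liability` list with `K`, threshold `T`
#'   (`qnorm(1 - K)`), `z_affected` (`dnorm(T)/K`, the mean liability of
#'   affected individuals) and `z_unaffected` (`-dnorm(T)/(1 - K)`).
#' @examples
#' liability_scores(0.5)  # T = 0, z_affected = 2*dnorm(0)
#' @export
liability_scores <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K <= 0 || K >= 1)
    stop_fgrs("fgrs_domain_error", "K must be a single number in (0, 1)")
  T <- qnorm(K, lower.tail = FALSE)
  structure(list(K = K, T = T,
                 z_affected = dnorm(T) / K,
                 z_unaffected = -dnorm(T) / (1 - K)),
            class = "fgrs_liability")
}

#' @export
print.fgrs_liability <- function(x, ...) {
  cat(sprintf("<fgrs_liability> K = %.6g, T = %.6g, z+ = %.6g, z- = %.6g\n",
              x$K, x$T, x$z_affected, x$z_unaffected))
  invisible(x)
}

#' Liability z-score for an affection status
#'
#' @param affected logical vector.
#' @param scores an `fgrs_liability` from [liability_scores()].
#' @return numeric vector: `z_affected` where affected, `z_unaffected`
#'   otherwise.
#' @export
status_z <- function(affected, scores) {
  stopifnot(inherits(scores, "fgrs_liability"), is.logical(affected),
            !anyNA(affected))
  ifelse(affected, scores$z_affected, scores$z_unaffected)
}

#' Standardized z-scores for a quantitative trait
#'
#' Continuous phenotypes (e.g. BMI, years of education) bypass the liability
#' threshold: the phenotype is standardized to mean 0, SD 1 within birth-year
#' (and optionally sex) strata and used directly as the relative-level
#' z-score. Persons without a recorded value contribute nothing.
#'
#' @param cohort an `fgrs_cohort`.
#' @param trait quantitative trait code.
#' @param by_sex also stratify by sex.
#' @param birth_band width in years of the birth-year strata (default 1,
#'   exact years).
#' @return data.table with columns `person_id`, `z`.
#' @export
quantitative_z <- function(cohort, trait, by_sex = FALSE, birth_band = 1L) {
  stopifnot(inherits(cohort, "fgrs_cohort"))
  tr <- trait
  q <- cohort$quantitative[trait == tr]
  if (!nrow(q))
    stop_fgrs("fgrs_estimation_error", "no quantitative records for trait '%s'", tr)
  q <- merge(q, cohort$persons[, .(person_id, sex, birth_year)], by = "person_id")
  q[, stratum := band_of(birth_year, birth_band)]
  if (by_sex) q[, stratum := paste(sex, stratum, sep = ":")]
  q[, z := {
    m <- mean(value)
    s <- sqrt(mean((value - m)^2))  # population-SD convention
    if (s == 0)
      stop_fgrs("fgrs_estimation_error",
                "zero variance for trait '%s' in stratum '%s'", tr, .BY$stratum)
    (value - m) / s
  }, by = stratum]
  q[, .(person_id, z)]
}

#' Write / read a prevalence table
#'
#' TSV with columns `trait`, `stratum`, `K`, so morbid risks can be supplied
#' externally instead of estimated from the cohort.
#'
#' @param prevalence an `fgrs_prevalence` (or data.frame with those columns).
#' @param path file path.
#' @return `write_prevalence()` the path invisibly; `read_prevalence()` an
#'   `fgrs_prevalence`.
#' @export
write_prevalence <- function(prevalence, path) {
  fwrite(as.data.table(prevalence)[, .(trait, stratum, K)], path, sep = "\t",
         quote = FALSE)
  invisible(path)
}

#' @rdname write_prevalence
#' @export
read_prevalence <- function(path) {
  x <- fread(path, sep = "\t", colClasses = list(character = c("trait", "stratum")))
  if (!all(c("trait", "stratum", "K") %in% names(x)))
    stop_fgrs("fgrs_format_error", "prevalence table needs trait, stratum, K")
  if (any(x$K <= 0 | x$K >= 1))
    stop_fgrs("fgrs_domain_error", "K must lie in (0, 1)")
  structure(x, class = c("fgrs_prevalence", "data.table"))
}
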