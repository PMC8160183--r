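# The FGRS aggregation itself: kinship-weighted quotient, empirical-Bayes
# shrinkage, and birth-year standardization.
#
# For a proband with relatives i (degree d_i, corrected liability z_i), the
# two components are the weighted z sum and the weighted number of relatives,
# both with kinship weights w_i = 0.5^{d_i}:
#     quotient = sum(w_i z_i) / sum(w_i),   n_eff = sum(w_i).
# The quotient is then multiplied by the reliability-ratio shrinkage factor
#     s = var_between / (var_between + var_within / n),
# built from the variance of z across all relatives (var_within), the
# sampling-corrected variance of the quotient across probands (var_between)
# and the proband's relative count n, and finally standardized within year
# of birth to mean 0, SD 1.
#
# The count n entering the reliability ratio is the Kish effective number of
# relatives, n = (sum w_i)^2 / sum(w_i^2): the sampling variance of a
# weighted mean of independent z's is var_within * sum(w^2)/(sum w)^2, so
# this is the independent-equivalent count the ratio calls for. Using the
# raw weighted count sum(w_i) instead overstates the sampling variance by
# the factor n/n_eff (an order of magnitude in extended pedigrees, where
# many small-weight distant relatives inflate sum(w) relative to the
# information they carry) and drives the estimated between-proband variance
# to zero.

#' Kinship-weighted quotient of relatives' z-scores
#'
#' @param z numeric vector of (corrected) relative z-scores.
#' @param w numeric vector of kinship weights, same length.
#' @return list with `quotient` (`sum(w*z)/sum(w)`; 0 for an empty list),
#'   `n_eff` (`sum(w)`) and `eff_n` (the Kish effective relative count
#'   `sum(w)^2 / sum(w^2)`; 0 for an empty list).
#' @examples
#' weighted_quotient(z = c(1, -0.2), w = c(0.5, 0.125))
#' @export
weighted_quotient <- function(z, w) {
  stopifnot(length(z) == length(w))
  if (!length(z)) return(list(quotient = 0, n_eff = 0, eff_n = 0))
  stopifnot(all(is.finite(z)), all(is.finite(w)), all(w > 0))
  list(quotient = sum(w * z) / sum(w), n_eff = sum(w),
       eff_n = sum(w)^2 / sum(w^2))
}

#' Estimate the shrinkage variance components
#'
#' `var_within` is the (sample) variance of the z-score across all relative
#' contributions; `var_between` is the variance of the quotient across
#' probands minus its expected sampling part, `mean(var_within / eff_n)`,
#' floored at zero, where `eff_n` is each proband's effective
#' (independent-equivalent) relative count.
#'
#' @param quotients numeric vector, one quotient per proband.
#' @param n_eff numeric vector of weighted relative counts, same length.
#' @param relative_z numeric vector of every relative contribution's z.
#' @param eff_n effective relative counts per proband (Kish,
#'   `sum(w)^2/sum(w^2)`); defaults to `n_eff`, appropriate when all
#'   contributing relatives share one weight.
#' @return an `fgrs_shrinkage` list with `var_within`, `var_between`.
#' @export
estimate_shrinkage_params <- function(quotients, n_eff, relative_z,
                                      eff_n = n_eff) {
  stopifnot(length(quotients) == length(n_eff), length(eff_n) == length(n_eff))
  use <- n_eff > 0
  if (sum(use) < 2L)
    stop_fgrs("fgrs_estimation_error",
              "need at least two probands with relatives to estimate shrinkage")
  var_within <- if (length(relative_z) >= 2L) var(relative_z) else 0
  var_between <-
    max(0, var(quotients[use]) - mean(var_within / eff_n[use]))
  shrinkage_params(var_within, var_between)
}

#' @rdname estimate_shrinkage_params
#' @param var_within,var_between explicit components (`var_within >= 0`,
#'   `var_between >= 0`), for constructing the object directly.
#' @export
shrinkage_params <- function(var_within, var_between) {
  stopifnot(is.finite(var_within), var_within >= 0,
            is.finite(var_between), var_between >= 0)
  structure(list(var_within = var_within, var_between = var_between),
            class = "fgrs_shrinkage")
}

#' Reliability-ratio shrinkage factor
#'
#' `s = var_between / (var_between + var_within / n)`, in `[0, 1]` and
#' non-decreasing in `n`; `s = 0` when `n = 0` (no information pulls the
#' score to the population mean) and `s = 1` for noise-free relatives
#' (`var_within = 0`, `n > 0`). The count `n` is the effective
#' (independent-equivalent) number of relatives; [compute_fgrs()] passes the
#' Kish count `sum(w)^2/sum(w^2)`.
#'
#' @param params an `fgrs_shrinkage`.
#' @param n_eff numeric vector of effective relative counts (>= 0).
#' @return numeric vector of shrinkage factors.
#' @export
shrinkage_factor <- function(params, n_eff) {
  stopifnot(inherits(params, "fgrs_shrinkage"), all(n_eff >= 0))
  if (params$var_within == 0) return(as.numeric(n_eff > 0))
  ifelse(n_eff > 0,
         params$var_between / (params$var_between + params$var_within / n_eff),
         0)
}

#' Compute family genetic risk scores for a cohort
#'
#' Runs the full per-trait pipeline: enumerate each person's 1st- to
#' `max_degree`-degree relatives, assign each relative the liability z-score
#' of their observed status (or their standardized quantitative phenotype),
#' apply the 1st-degree shared-environment corrections, form the
#' kinship-weighted quotient, shrink it, and standardize within birth year.
#' A person's own phenotype never enters their score. The pipeline is
#' deterministic given its inputs.
#'
#' @param cohort an `fgrs_cohort`.
#' @param traits character vector of trait codes; default: every trait in the
#'   diagnosis and quantitative tables.
#' @param pedigree optional prebuilt [build_pedigree()] result (built on the
#'   fly otherwise).
#' @param prevalence lifetime morbid risk(s) for binary traits: `NULL` to
#'   estimate by [estimate_morbid_risk()] (pooled), a single number, or a
#'   named numeric vector by trait.
#' @param factors 1st-degree correction factors: `NULL` to estimate both from
#'   the cohort (falling back, with a warning, to 1.0 when the cohort cannot
#'   support estimation), a single `fgrs_corrections`, or a named list of them
#'   by trait.
#' @param max_degree furthest degree of relatedness used (default 5).
#' @param shrinkage_params `NULL` to estimate per trait, or an
#'   `fgrs_shrinkage` to impose.
#' @param standardize standardize within birth year (default TRUE; set FALSE
#'   for tiny fixtures).
#' @param birth_band width in years of the standardization strata (default 1,
#'   exact birth years).
#' @return data.table with one row per person and trait: `person_id`, `trait`,
#'   `quotient`, `n_eff`, `shrinkage`, `fgrs_raw` (`quotient * shrinkage`) and
#'   `fgrs_std` (NA when `standardize = FALSE`).
#' @export
compute_fgrs <- function(cohort, traits = NULL, pedigree = NULL,
                         prevalence = NULL, factors = NULL, max_degree = 5L,
                         shrinkage_params = NULL, standardize = TRUE,
                         birth_band = 1L) {
  stopifnot(inherits(cohort, "fgrs_cohort"))
  if (is.null(traits))
    traits <- union(unique(cohort$diagnoses$trait),
                    unique(cohort$quantitative$trait))
  if (!length(traits))
    stop_fgrs("fgrs_domain_error", "no traits to compute FGRS for")
  if (is.null(pedigree)) pedigree <- build_pedigree(cohort, max_degree)
  pairs <- pedigree$pairs[degree <= max_degree]

  out <- rbindlist(lapply(traits, function(tr) {
    quant <- tr %in% cohort$quantitative$trait
    if (quant) {
      ztab <- quantitative_z(cohort, tr)
    } else {
      K <- resolve_prevalence(prevalence, cohort, tr)
      sc <- liability_scores(K)
      aff <- affected_set(cohort, tr)
      ztab <- data.table(person_id = cohort$persons$person_id,
                         z = status_z(cohort$persons$person_id %in% aff, sc))
    }
    fct <- resolve_factors(factors, cohort, tr)
    contrib <- pairs[ztab, on = c(relative_id = "person_id"), nomatch = NULL]
    contrib[, z := apply_correction(z, pair_class, fct)]
    setkey(contrib, proband_id, relative_id)  # fixed summation order
    agg <- contrib[, .(quotient = sum(weight * z) / sum(weight),
                       n_eff = sum(weight),
                       eff_n = sum(weight)^2 / sum(weight^2)),
                   by = proband_id]
    res <- merge(data.table(person_id = cohort$persons$person_id), agg,
                 by.x = "person_id", by.y = "proband_id", all.x = TRUE)
    res[is.na(quotient), `:=`(quotient = 0, n_eff = 0, eff_n = 0)]
    sp <- if (is.null(shrinkage_params))
      estimate_shrinkage_params(res$quotient, res$n_eff, contrib$z, res$eff_n)
    else shrinkage_params
    res[, shrinkage := shrinkage_factor(sp, eff_n)]
    res[, fgrs_raw := quotient * shrinkage]
    res[, `:=`(trait = tr, eff_n = NULL)]
    res
  }))
  setcolorder(out, c("person_id", "trait", "quotient", "n_eff", "shrinkage",
                     "fgrs_raw"))
  out[, fgrs_std := NA_real_]
  if (standardize)
    out <- standardize_by_birth_year(out, cohort$persons, birth_band)
  setkey(out, trait, person_id)
  out[]
}

resolve_prevalence <- function(prevalence, cohort, tr) {
  if (is.null(prevalence))
    return(estimate_morbid_risk(cohort, tr)$K[1])
  if (inherits(prevalence, "fgrs_prevalence")) {
    k <- prevalence[trait == tr & stratum == "all", K]
    if (!length(k))
      stop_fgrs("fgrs_domain_error", "no pooled prevalence supplied for '%s'", tr)
    return(k[1])
  }
  if (is.numeric(prevalence)) {
    if (length(prevalence) == 1L && is.null(names(prevalence)))
      return(prevalence)
    if (tr %in% names(prevalence)) return(unname(prevalence[[tr]]))
  }
  stop_fgrs("fgrs_domain_error", "no prevalence supplied for trait '%s'", tr)
}

resolve_factors <- function(factors, cohort, tr) {
  if (inherits(factors, "fgrs_corrections")) return(factors)
  if (is.list(factors) && tr %in% names(factors)) return(factors[[tr]])
  if (is.null(factors)) {
    est <- tryCatch(correction_factors(tr, cohort = cohort),
                    fgrs_estimation_error = function(e) e)
    if (inherits(est, "fgrs_corrections")) {
      # only trust slope ratios that are themselves well determined (delta
      # method); a noise-dominated ratio applied as a multiplier distorts the
      # scores more than no correction at all
      ratio_se <- function(num, den, ratio)
        abs(ratio) * sqrt((num$se / num$beta)^2 + (den$se / den$beta)^2)
      fi <- est$fit_info
      po_se <- ratio_se(fi$parent_offspring$not_lived_with,
                        fi$parent_offspring$lived_with, fi$parent_offspring$raw_ratio)
      sib_se <- ratio_se(fi$sibling$apart, fi$sibling$together,
                         fi$sibling$raw_ratio)
      if (is.finite(po_se) && is.finite(sib_se) && po_se < 0.25 && sib_se < 0.25)
        return(est)
      warning(sprintf(
        "correction-factor estimates for '%s' too noisy (SE %.2g / %.2g); using 1.0",
        tr, po_se, sib_se), call. = FALSE)
      return(correction_factors(tr))
    }
    warning(sprintf(
      "correction factors for '%s' not estimable (%s); using 1.0", tr,
      conditionMessage(est)), call. = FALSE)
    return(correction_factors(tr))
  }
  stop_fgrs("fgrs_domain_error", "no correction factors supplied for '%s'", tr)
}

#' Standardize FGRS within year of birth
#'
#' Within each birth-year stratum (optionally banded), `fgrs_std` is the raw
#' FGRS centred and scaled to mean 0, SD 1 (population-SD convention, divide
#' by n). Standardizing by birth year makes scores comparable across traits
#' and absorbs register-coverage differences across cohorts.
#'
#' @param results FGRS result table from [compute_fgrs()].
#' @param persons person table (for birth years).
#' @param birth_band stratum width in years (default 1).
#' @return the result table with `fgrs_std` filled in.
#' @export
standardize_by_birth_year <- function(results, persons, birth_band = 1L) {
  results <- as.data.table(results)
  by_of <- setNames(persons$birth_year, persons$person_id)
  results[, stratum := band_of(by_of[person_id], birth_band)]
  results[, fgrs_std := {
    if (.N < 2L)
      stop_fgrs("fgrs_estimation_error",
                "birth-year stratum '%s' has fewer than 2 persons (trait %s)",
                .BY$stratum, .BY$trait)
    m <- mean(fgrs_raw)
    s <- sqrt(mean((fgrs_raw - m)^2))
    if (s == 0)
      stop_fgrs("fgrs_estimation_error",
                "zero FGRS variance in birth-year stratum '%s' (trait %s)",
                .BY$stratum, .BY$trait)
    (fgrs_raw - m) / s
  }, by = .(trait, stratum)]
  results[, stratum := NULL]
  results[]
}

#' Write an FGRS result table as TSV
#'
#' Columns: `person_id`, `trait`, `quotient`, `n_eff`, `shrinkage`,
#' `fgrs_raw`, `fgrs_std`.
#'
#' @param results table from [compute_fgrs()].
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_fgrs <- function(results, path) {
  fwrite(as.data.table(results), path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_fgrs
#' @export
read_fgrs <- function(path) {
  fread(path, sep = "\t", na.strings = "",
        colClasses = list(character = c("person_id", "trait")))
}
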