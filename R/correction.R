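# Shared-environment correction factors for 1st-degree relatives.
#
# The extended adoption design: fathers who sired but never lived with their
# children transmit genes but not rearing environment, so the ratio of the
# logistic (log-odds) resemblance slope in not-lived-with versus lived-with
# father-offspring pairs estimates the genetic share of parent-offspring
# resemblance. Half-siblings reared apart versus together provide the same
# contrast for sibling pairs at identical genetic relatedness.

#' Father-offspring and half-sibling pair tables
#'
#' `father_offspring_pairs()` returns one row per child with a known father;
#' `half_sib_pairs()` one row per unordered half-sibling pair (exactly one
#' shared, known parent), with the pair ordered older/younger by birth year
#' (ties broken by person id).
#'
#' @param cohort an `fgrs_cohort`.
#' @return data.tables; see Details.
#' @keywords internal
father_offspring_pairs <- function(cohort) {
  p <- cohort$persons
  p[!is.na(father_id),
    .(offspring = person_id, parent = father_id, lived_with = lived_with_father)]
}

#' @rdname father_offspring_pairs
#' @keywords internal
half_sib_pairs <- function(cohort) {
  p <- cohort$persons[, .(person_id, father_id, mother_id, birth_year, household_id)]
  pair_by <- function(col) {
    x <- p[!is.na(get(col))]
    m <- merge(x, x, by = col, allow.cartesian = TRUE,
               suffixes = c("_a", "_b"))[person_id_a < person_id_b]
    m[, .(a = person_id_a, b = person_id_b,
          fa_a = if (col == "father_id") get(col) else father_id_a,
          fa_b = if (col == "father_id") get(col) else father_id_b,
          mo_a = if (col == "mother_id") get(col) else mother_id_a,
          mo_b = if (col == "mother_id") get(col) else mother_id_b,
          by_a = birth_year_a, by_b = birth_year_b,
          hh_a = household_id_a, hh_b = household_id_b)]
  }
  both <- unique(rbind(pair_by("father_id"), pair_by("mother_id")))
  share_f <- !is.na(both$fa_a) & !is.na(both$fa_b) & both$fa_a == both$fa_b
  share_m <- !is.na(both$mo_a) & !is.na(both$mo_b) & both$mo_a == both$mo_b
  hs <- both[xor(share_f, share_m)]
  if (!nrow(hs))
    return(data.table(older = character(), younger = character(),
                      reared_together = logical()))
  swap <- hs$by_b < hs$by_a | (hs$by_b == hs$by_a & hs$b < hs$a)
  hs[, .(older = fifelse(swap, b, a), younger = fifelse(swap, a, b),
         reared_together = !is.na(hh_a) & !is.na(hh_b) & hh_a == hh_b)]
}

# Log-odds resemblance slope: logistic regression of the outcome member's
# status on the predictor member's status. Requires variation in both.
fit_resemblance <- function(outcome, predictor, label) {
  if (length(outcome) == 0L)
    stop_fgrs("fgrs_estimation_error", "no pairs in group '%s'", label)
  if (length(unique(outcome)) < 2L || length(unique(predictor)) < 2L)
    stop_fgrs("fgrs_estimation_error",
              "no variation in affection status within group '%s'", label)
  fit <- glm(outcome ~ predictor, family = binomial())
  list(beta = unname(coef(fit)[2]), se = sqrt(diag(vcov(fit)))[2],
       n_pairs = length(outcome),
       n_exposed = sum(predictor), n_affected = sum(outcome))
}

ratio_factor <- function(fit_num, fit_den) {
  if (!is.finite(fit_den$beta) || fit_den$beta <= 0)
    stop_fgrs("fgrs_estimation_error",
              paste0("resemblance in the comparison group is not positive ",
                     "(beta = %.4g); correction factor undefined"), fit_den$beta)
  raw <- fit_num$beta / fit_den$beta
  list(factor = min(max(raw, 0), 1), raw_ratio = raw)
}

#' Estimate the parent-offspring shared-environment correction factor
#'
#' Fits, separately in lived-with and not-lived-with father-offspring pairs, a
#' logistic regression of offspring status on father status, and returns the
#' ratio of the not-lived-with to the lived-with log-odds slope, clamped to
#' `[0, 1]`. A factor of 1 means parent-offspring resemblance is fully
#' genetic; smaller values discount the shared-household part.
#'
#' @param cohort an `fgrs_cohort`.
#' @param trait trait code.
#' @return list with `factor` and `fit_info` (per-group pair counts, log-odds
#'   slopes and the unclamped ratio).
#' @export
estimate_parent_correction <- function(cohort, trait) {
  stopifnot(inherits(cohort, "fgrs_cohort"))
  aff <- affected_set(cohort, trait)
  fo <- father_offspring_pairs(cohort)
  if (!nrow(fo) || !any(fo$lived_with) || !any(!fo$lived_with))
    stop_fgrs("fgrs_estimation_error",
              "need both lived-with and not-lived-with father-offspring pairs")
  lw <- fo[lived_with == TRUE]
  nlw <- fo[lived_with == FALSE]
  fit_lw <- fit_resemblance(lw$offspring %in% aff, lw$parent %in% aff,
                            "lived-with fathers")
  fit_nlw <- fit_resemblance(nlw$offspring %in% aff, nlw$parent %in% aff,
                             "not-lived-with fathers")
  rf <- ratio_factor(fit_nlw, fit_lw)
  list(factor = rf$factor,
       fit_info = list(trait = trait, raw_ratio = rf$raw_ratio,
                       lived_with = fit_lw, not_lived_with = fit_nlw))
}

#' Estimate the sibling shared-environment correction factor
#'
#' Same construction as [estimate_parent_correction()], with the comparison
#' groups being half-sibling pairs reared together versus apart (identical
#' genetic relatedness, so the contrast isolates the shared-household part):
#' the younger sibling's status is regressed on the older's, and the factor is
#' the reared-apart / reared-together log-odds slope ratio clamped to
#' `[0, 1]`.
#'
#' @inheritParams estimate_parent_correction
#' @return list with `factor` and `fit_info`.
#' @export
estimate_sibling_correction <- function(cohort, trait) {
  stopifnot(inherits(cohort, "fgrs_cohort"))
  aff <- affected_set(cohort, trait)
  hs <- half_sib_pairs(cohort)
  if (!nrow(hs))
    stop_fgrs("fgrs_estimation_error", "cohort contains no half-sibling pairs")
  if (!any(hs$reared_together) || !any(!hs$reared_together))
    stop_fgrs("fgrs_estimation_error",
              "need half-sibling pairs both reared together and apart")
  tog <- hs[reared_together == TRUE]
  ap <- hs[reared_together == FALSE]
  fit_tog <- fit_resemblance(tog$younger %in% aff, tog$older %in% aff,
                             "half-sibs reared together")
  fit_ap <- fit_resemblance(ap$younger %in% aff, ap$older %in% aff,
                            "half-sibs reared apart")
  rf <- ratio_factor(fit_ap, fit_tog)
  list(factor = rf$factor,
       fit_info = list(trait = trait, raw_ratio = rf$raw_ratio,
                       together = fit_tog, apart = fit_ap))
}

affected_set <- function(cohort, tr) {
  cohort$diagnoses[trait == tr, person_id]
}

#' Bundle correction factors for a trait
#'
#' Either estimates both factors from the cohort or wraps user-supplied
#' values (e.g. published ranges, or 1.0 for no correction).
#'
#' @param trait trait code.
#' @param cohort optional `fgrs_cohort` to estimate from.
#' @param c_parent_offspring,c_sibling explicit factors in `[0, 1]`, used when
#'   `cohort` is `NULL`.
#' @return an `fgrs_corrections` list with `trait`, `c_parent_offspring`,
#'   `c_sibling` and `fit_info` (empty for user-supplied factors).
#' @export
correction_factors <- function(trait, cohort = NULL, c_parent_offspring = 1,
                               c_sibling = 1) {
  if (!is.null(cohort)) {
    po <- estimate_parent_correction(cohort, trait)
    sib <- estimate_sibling_correction(cohort, trait)
    return(structure(list(trait = trait, c_parent_offspring = po$factor,
                          c_sibling = sib$factor,
                          fit_info = list(parent_offspring = po$fit_info,
                                          sibling = sib$fit_info)),
                     class = "fgrs_corrections"))
  }
  stopifnot(c_parent_offspring >= 0, c_parent_offspring <= 1,
            c_sibling >= 0, c_sibling <= 1)
  structure(list(trait = trait, c_parent_offspring = c_parent_offspring,
                 c_sibling = c_sibling, fit_info = list()),
            class = "fgrs_corrections")
}

#' @export
print.fgrs_corrections <- function(x, ...) {
  cat(sprintf("<fgrs_corrections> %s: c_parent_offspring = %.4g, c_sibling = %.4g\n",
              x$trait, x$c_parent_offspring, x$c_sibling))
  invisible(x)
}

#' Apply 1st-degree shared-environment corrections to z-scores
#'
#' Parent-offspring contributions are multiplied by `c_parent_offspring`,
#' full-sibling contributions by `c_sibling`; every other pair class
#' (including half-siblings, which are 2nd degree) passes through unchanged.
#'
#' @param z numeric vector of liability z-scores.
#' @param pair_class character vector of pair classes, same length.
#' @param factors an `fgrs_corrections`.
#' @return corrected numeric vector.
#' @export
apply_correction <- function(z, pair_class, factors) {
  stopifnot(inherits(factors, "fgrs_corrections"), length(z) == length(pair_class))
  mult <- rep(1, length(z))
  mult[pair_class == "parent_offspring"] <- factors$c_parent_offspring
  mult[pair_class == "full_sibling"] <- factors$c_sibling
  z * mult
}

#' Write / read correction-factor tables
#'
#' TSV with columns `trait`, `c_parent_offspring`, `c_sibling`, so externally
#' estimated (e.g. published-range) factors can be injected.
#'
#' @param factors a single `fgrs_corrections` or a list of them.
#' @param path file path.
#' @return `write_corrections()` the path invisibly; `read_corrections()` a
#'   named list of `fgrs_corrections`.
#' @export
write_corrections <- function(factors, path) {
  if (inherits(factors, "fgrs_corrections")) factors <- list(factors)
  tab <- rbindlist(lapply(factors, function(f)
    data.table(trait = f$trait, c_parent_offspring = f$c_parent_offspring,
               c_sibling = f$c_sibling)))
  fwrite(tab, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_corrections
#' @export
read_corrections <- function(path) {
  x <- fread(path, sep = "\t", colClasses = list(character = "trait"))
  if (!all(c("trait", "c_parent_offspring", "c_sibling") %in% names(x)))
    stop_fgrs("fgrs_format_error",
              "corrections table needs trait, c_parent_offspring, c_sibling")
  out <- lapply(seq_len(nrow(x)), function(i)
    correction_factors(x$trait[i],
                       c_parent_offspring = x$c_parent_offspring[i],
                       c_sibling = x$c_sibling[i]))
  setNames(out, x$trait)
}
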