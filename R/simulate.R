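# Synthetic registry generator: multi-generation pedigrees under a
# multivariate additive-genetic + shared-household + residual liability
# model, with onset ages, censoring, not-lived-with fathers and half-siblings
# reared together or apart. Every other module is testable against the
# generative truth this module records.

#' Specify one simulated trait
#'
#' @param trait trait code.
#' @param kind `"binary"` (liability-threshold diagnosis with an onset age) or
#'   `"quantitative"` (the liability is recorded directly as the phenotype).
#' @param h2 additive-genetic proportion of liability variance, in `[0, 1]`.
#' @param c2 shared-household proportion, `h2 + c2 <= 1`.
#' @param prevalence lifetime prevalence K (binary traits only).
#' @param onset_mean,onset_sd parameters of the truncated-normal (on (0, 80])
#'   age-of-onset distribution (binary traits only; years).
#' @return a `trait_spec` list.
#' @export
trait_spec <- function(trait, kind = c("binary", "quantitative"), h2, c2 = 0,
                       prevalence = NULL, onset_mean = 30, onset_sd = 12) {
  kind <- match.arg(kind)
  stopifnot(h2 >= 0, h2 <= 1, c2 >= 0, c2 <= 1, h2 + c2 <= 1)
  if (kind == "binary") {
    if (is.null(prevalence) || prevalence <= 0 || prevalence >= 1)
      stop_fgrs("fgrs_config_error",
                "binary trait '%s' needs a prevalence in (0, 1)", trait)
    stopifnot(onset_sd > 0)
  }
  structure(list(trait = trait, kind = kind, h2 = h2, c2 = c2,
                 prevalence = prevalence, onset_mean = onset_mean,
                 onset_sd = onset_sd),
            class = "fgrs_trait_spec")
}

#' Full data-generating specification for a synthetic registry
#'
#' @param seed integer RNG seed; the same configuration and seed reproduce the
#'   cohort byte for byte.
#' @param n_founders number of founder individuals (generation 0).
#' @param n_generations total number of generations (>= 2).
#' @param birth_year_range integer `(first, last)` birth years; founders are
#'   born in the first decade of the range and children 22-34 years after
#'   their mother, capped at the range end.
#' @param traits list of [trait_spec()]s.
#' @param genetic_cor genetic correlation matrix across traits (positive
#'   semidefinite, unit diagonal); identity by default. Household and residual
#'   components are independent across traits.
#' @param p_not_lived_with_father probability that a union's father never
#'   lives with his children (he then shares no household environment with
#'   them).
#' @param p_half_sib_apart given a second union, probability that the
#'   re-partnering parent is the father — his half-siblings are reared apart
#'   (different mothers, different households); a re-partnering mother's
#'   half-siblings are reared together.
#' @param p_second_union probability that a couple's father or mother forms a
#'   second union with an unpartnered member of the generation, creating
#'   half-siblings.
#' @param mean_children_per_couple Poisson mean of children per union.
#' @param censor_year end of follow-up; `censor_age = censor_year -
#'   birth_year`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_founders = 2000L, n_generations = 4L,
                       birth_year_range = c(1932L, 1995L), traits,
                       genetic_cor = NULL, p_not_lived_with_father = 0.15,
                       p_half_sib_apart = 0.5, p_second_union = 0.2,
                       mean_children_per_couple = 2.4, censor_year = 2017L) {
  if (inherits(traits, "fgrs_trait_spec")) traits <- list(traits)
  stopifnot(length(traits) >= 1,
            all(vapply(traits, inherits, logical(1), "fgrs_trait_spec")))
  nt <- length(traits)
  if (is.null(genetic_cor)) genetic_cor <- diag(nt)
  genetic_cor <- as.matrix(genetic_cor)
  if (!isTRUE(all.equal(unname(diag(genetic_cor)), rep(1, nt))) ||
      !isTRUE(all.equal(genetic_cor, t(genetic_cor))))
    stop_fgrs("fgrs_config_error",
              "genetic_cor must be symmetric with unit diagonal")
  if (min(eigen(genetic_cor, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop_fgrs("fgrs_config_error", "genetic_cor is not positive semidefinite")
  for (p in c(p_not_lived_with_father, p_half_sib_apart, p_second_union))
    stopifnot(p >= 0, p <= 1)
  stopifnot(n_generations >= 2, n_founders >= 4, mean_children_per_couple > 0,
            length(birth_year_range) == 2,
            birth_year_range[1] <= birth_year_range[2],
            censor_year >= birth_year_range[2])
  codes <- vapply(traits, `[[`, character(1), "trait")
  if (anyDuplicated(codes))
    stop_fgrs("fgrs_config_error", "duplicated trait codes")
  structure(list(seed = as.integer(seed), n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 birth_year_range = as.integer(birth_year_range),
                 traits = traits, genetic_cor = genetic_cor,
                 p_not_lived_with_father = p_not_lived_with_father,
                 p_half_sib_apart = p_half_sib_apart,
                 p_second_union = p_second_union,
                 mean_children_per_couple = mean_children_per_couple,
                 censor_year = as.integer(censor_year)),
            class = "sim_config")
}

# symmetric matrix square root; tolerates PSD matrices with zero eigenvalues
mvn_draw <- function(n, Sigma) {
  ev <- eigen(Sigma, symmetric = TRUE)
  R <- ev$vectors %*% (t(ev$vectors) * sqrt(pmax(ev$values, 0)))
  matrix(rnorm(n * ncol(Sigma)), nrow = n) %*% R
}

rtruncnorm_0_80 <- function(n, mean, sd) {
  plo <- pnorm(0, mean, sd)
  phi <- pnorm(80, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Simulate a registry-style cohort with known generative truth
#'
#' Founders' additive-genetic values are drawn from a zero-mean multivariate
#' normal with covariance `sqrt(h2_i h2_j) * genetic_cor[i, j]`; each child's
#' value is the midparent mean plus an independent segregation deviation of
#' half the genetic variance, preserving the cross-trait structure. One
#' household effect per rearing unit (keyed by the mother) is shared by all
#' children reared in it and enters the liability of the mother and of
#' lived-with fathers, so that full siblings and reared-together half-siblings
#' share `c2`, lived-with parent-offspring pairs share `c2`, and
#' not-lived-with fathers and reared-apart half-siblings share nothing beyond
#' genes. Liabilities add an independent residual; binary traits are affected
#' above the empirical `1 - K` liability quantile, with a truncated-normal
#' onset age recorded as a diagnosis only when it falls before the censoring
#' age.
#'
#' @param config a [sim_config()].
#' @return list with `cohort` (a validated `fgrs_cohort`), `truth` (data.table
#'   per person and trait: additive value `A`, shared-household value `C`,
#'   `liability`, `affected`, `onset`) and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nt <- length(config$traits)
  h2 <- vapply(config$traits, `[[`, numeric(1), "h2")
  c2 <- vapply(config$traits, `[[`, numeric(1), "c2")
  codes <- vapply(config$traits, `[[`, character(1), "trait")
  Sg <- sqrt(h2) %o% sqrt(h2) * config$genetic_cor
  byr <- config$birth_year_range

  n0 <- config$n_founders
  gen <- data.table(person_id = sprintf("P%07d", seq_len(n0)),
                    sex = sample(rep(c("male", "female"), length.out = n0)),
                    birth_year = byr[1] +
                      sample.int(min(10L, byr[2] - byr[1] + 1L), n0,
                                 replace = TRUE) - 1L,
                    father_id = NA_character_, mother_id = NA_character_,
                    lived_with_father = TRUE, household_id = NA_character_)
  A <- mvn_draw(n0, Sg)
  Cbase <- matrix(rnorm(n0 * nt), n0) %*% diag(sqrt(c2), nt)
  persons_list <- list(gen)
  A_list <- list(A)
  Cbase_list <- list(Cbase)
  extra_list <- list(matrix(0, n0, nt))
  next_id <- n0 + 1L

  for (g in seq_len(config$n_generations - 1L)) {
    prev <- persons_list[[g]]
    prevA <- A_list[[g]]
    males <- sample(which(prev$sex == "male"))
    females <- sample(which(prev$sex == "female"))
    n_p <- floor(min(length(males), length(females)) * 0.85)
    if (n_p < 1L) break
    fa_idx <- males[seq_len(n_p)]
    mo_idx <- females[seq_len(n_p)]
    single_m <- males[-seq_len(n_p)]
    single_f <- females[-seq_len(n_p)]

    unions <- data.table(fa = fa_idx, mo = mo_idx)
    second <- which(runif(n_p) < config$p_second_union)
    if (length(second)) {
      father_remates <- runif(length(second)) < config$p_half_sib_apart
      fr <- second[father_remates]
      mr <- second[!father_remates]
      fr <- fr[seq_len(min(length(fr), length(single_f)))]
      mr <- mr[seq_len(min(length(mr), length(single_m)))]
      if (length(fr))
        unions <- rbind(unions, data.table(fa = fa_idx[match(fr, seq_len(n_p))],
                                           mo = single_f[seq_along(fr)]))
      if (length(mr))
        unions <- rbind(unions, data.table(fa = single_m[seq_along(mr)],
                                           mo = mo_idx[match(mr, seq_len(n_p))]))
    }
    n_u <- nrow(unions)
    unions[, lived_with := runif(n_u) >= config$p_not_lived_with_father]
    n_kids <- rpois(n_u, config$mean_children_per_couple)
    unions <- unions[n_kids > 0]
    n_kids <- n_kids[n_kids > 0]
    if (!nrow(unions)) break
    n_u <- nrow(unions)

    # one household effect per rearing unit (mother with children)
    mothers <- unique(unions$mo)
    H <- matrix(rnorm(length(mothers) * nt), length(mothers)) %*%
      diag(sqrt(c2), nt)
    rownames(H) <- as.character(mothers)
    extra <- extra_list[[g]]
    extra[mothers, ] <- extra[mothers, , drop = FALSE] +
      H[as.character(mothers), , drop = FALSE]
    lw_unions <- unions[lived_with == TRUE]
    if (nrow(lw_unions)) {
      add <- rowsum(H[as.character(lw_unions$mo), , drop = FALSE],
                    group = lw_unions$fa)
      idx <- as.integer(rownames(add))
      extra[idx, ] <- extra[idx, , drop = FALSE] + add
    }
    extra_list[[g]] <- extra

    if (sum(n_kids) == 0L) break
    u_rep <- rep(seq_len(n_u), n_kids)
    nk <- length(u_rep)
    fa_id <- prev$person_id[unions$fa[u_rep]]
    mo_id <- prev$person_id[unions$mo[u_rep]]
    kids <- data.table(
      person_id = sprintf("P%07d", seq.int(next_id, next_id + nk - 1L)),
      sex = sample(c("male", "female"), nk, replace = TRUE),
      birth_year = pmin(prev$birth_year[unions$mo[u_rep]] +
                          sample(22:34, nk, replace = TRUE), byr[2]),
      father_id = fa_id, mother_id = mo_id,
      lived_with_father = unions$lived_with[u_rep],
      household_id = paste0("HH", mo_id))
    next_id <- next_id + nk
    kidA <- (prevA[unions$fa[u_rep], , drop = FALSE] +
               prevA[unions$mo[u_rep], , drop = FALSE]) / 2 +
      mvn_draw(nk, Sg / 2)
    kidC <- H[as.character(unions$mo[u_rep]), , drop = FALSE]
    persons_list[[g + 1L]] <- kids
    A_list[[g + 1L]] <- kidA
    Cbase_list[[g + 1L]] <- kidC
    extra_list[[g + 1L]] <- matrix(0, nk, nt)
  }

  persons <- rbindlist(persons_list)
  A <- do.call(rbind, A_list)
  Cbase <- do.call(rbind, Cbase_list)
  extraC <- do.call(rbind, extra_list)
  n <- nrow(persons)
  E <- matrix(rnorm(n * nt), n) %*% diag(sqrt(pmax(1 - h2 - c2, 0)), nt)
  Ctot <- Cbase + extraC
  L <- A + Ctot + E
  persons[, censor_age := as.numeric(config$censor_year - birth_year)]

  diag_list <- list()
  quant_list <- list()
  truth_list <- list()
  for (t in seq_len(nt)) {
    spec <- config$traits[[t]]
    if (spec$kind == "binary") {
      thr <- quantile(L[, t], 1 - spec$prevalence, names = FALSE)
      affected <- L[, t] > thr
      onset <- rep(NA_real_, n)
      onset[affected] <- round(rtruncnorm_0_80(sum(affected), spec$onset_mean,
                                               spec$onset_sd), 2)
      seen <- affected & !is.na(onset) & onset <= persons$censor_age
      diag_list[[t]] <- data.table(person_id = persons$person_id[seen],
                                   trait = spec$trait,
                                   age_at_first_registration = onset[seen])
      truth_list[[t]] <- data.table(person_id = persons$person_id,
                                    trait = spec$trait, A = A[, t],
                                    C = Ctot[, t], liability = L[, t],
                                    affected = affected, onset = onset)
    } else {
      quant_list[[t]] <- data.table(person_id = persons$person_id,
                                    trait = spec$trait,
                                    value = round(L[, t], 6))
      truth_list[[t]] <- data.table(person_id = persons$person_id,
                                    trait = spec$trait, A = A[, t],
                                    C = Ctot[, t], liability = L[, t],
                                    affected = NA, onset = NA_real_)
    }
  }
  compact <- function(lst) {
    lst <- lst[!vapply(lst, is.null, logical(1))]
    if (length(lst)) rbindlist(lst) else NULL
  }
  cohort <- as_cohort(persons, compact(diag_list), compact(quant_list))
  list(cohort = cohort, truth = rbindlist(truth_list), config = config)
}

#' Shipped simulation scenarios
#'
#' Two registry-scale scenarios around a single liability-threshold trait
#' (lifetime prevalence 0.1, heritability 0.5): `"null"` has no shared
#' household environment (`c2 = 0`), `"household"` a substantial one
#' (`c2 = 0.2`). Both are sized to produce tens of thousands of
#' parent-offspring pairs and thousands of half-sibling pairs, and run in
#' well under two minutes.
#'
#' @param name `"null"` or `"household"`.
#' @param seed RNG seed.
#' @param n_founders founder count (default 16000).
#' @return a [sim_config()].
#' @export
scenario_config <- function(name = c("null", "household"), seed = 1L,
                            n_founders = 16000L) {
  name <- match.arg(name)
  c2 <- if (name == "household") 0.2 else 0
  sim_config(seed = seed, n_founders = n_founders, n_generations = 4L,
             traits = list(trait_spec("T1", "binary", h2 = 0.5, c2 = c2,
                                      prevalence = 0.1)),
             p_not_lived_with_father = 0.15, p_half_sib_apart = 0.5,
             p_second_union = 0.2, mean_children_per_couple = 2.4)
}

#' Hand-computed toy pedigrees with expected FGRS values
#'
#' Small fixed pedigrees whose quotients and raw FGRS were worked out step by
#' step from the closed-form liability scores and committed as constants, for
#' exact regression tests of [compute_fgrs()]. All use trait `"MD"` with
#' lifetime risk `K = 0.2`, correction factors `c_parent_offspring = 0.8`,
#' `c_sibling = 0.7`, and imposed shrinkage components `var_within = 1`,
#' `var_between = 0.25`.
#'
#' @return named list of fixtures; each has `cohort`, `proband`, `trait`,
#'   `K`, `factors`, `shrinkage` and `expected` (quotient, n_eff, fgrs_raw).
#' @export
make_toy_fixtures <- function() {
  fx <- list()
  factors <- correction_factors("MD", c_parent_offspring = 0.8, c_sibling = 0.7)
  shrink <- shrinkage_params(var_within = 1, var_between = 0.25)

  # six persons: proband, both parents, one full sib, one paternal half-sib
  # (reared apart), one paternal grandfather; father and half-sib affected.
  p6 <- data.frame(
    person_id = c("gp", "fat", "mot", "pro", "sib", "half"),
    sex = c("male", "male", "female", "male", "female", "male"),
    birth_year = c(1920L, 1945L, 1947L, 1970L, 1972L, 1975L),
    father_id = c(NA, "gp", NA, "fat", "fat", "fat"),
    mother_id = c(NA, NA, NA, "mot", "mot", NA),
    censor_age = c(90, 72, 70, 47, 45, 42),
    lived_with_father = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    household_id = c(NA, NA, NA, "h1", "h1", "h2"))
  d6 <- data.frame(person_id = c("fat", "half"), trait = "MD",
                   age_at_first_registration = c(40, 30))
  fx$six_person <- list(
    cohort = as_cohort(p6, d6), proband = "pro", trait = "MD", K = 0.2,
    factors = factors, shrinkage = shrink,
    expected = list(quotient = 0.27996192040780821, n_eff = 2,
                    fgrs_raw = 0.1493130242174977))

  # one affected father, nothing else: quotient = c_po * z_affected(K)
  p1 <- data.frame(person_id = c("f", "pro"), sex = c("male", "male"),
                   birth_year = c(1950L, 1980L), father_id = c(NA, "f"),
                   mother_id = NA_character_, censor_age = c(67, 37),
                   lived_with_father = TRUE)
  d1 <- data.frame(person_id = "f", trait = "MD",
                   age_at_first_registration = 40)
  fx$one_affected_parent <- list(
    cohort = as_cohort(p1, d1), proband = "pro", trait = "MD", K = 0.2,
    factors = factors, shrinkage = shrink,
    expected = list(quotient = 1.119847681631233, n_eff = 0.5,
                    fgrs_raw = 0.22396953632624661))

  # no relatives at all: full shrinkage to the population mean
  p0 <- data.frame(person_id = c("pro", "stranger"),
                   sex = c("male", "female"), birth_year = c(1980L, 1981L),
                   father_id = NA_character_, mother_id = NA_character_,
                   censor_age = c(37, 36), lived_with_father = TRUE)
  d0 <- data.frame(person_id = "stranger", trait = "MD",
                   age_at_first_registration = 25)
  fx$no_relatives <- list(
    cohort = as_cohort(p0, d0), proband = "pro", trait = "MD", K = 0.2,
    factors = factors, shrinkage = shrink,
    expected = list(quotient = 0, n_eff = 0, fgrs_raw = 0))

  fx
}
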