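test_that("weighted quotient is the kinship-weighted mean", {
  # one affected parent
  expect_equal(weighted_quotient(0.9, 0.5),
               list(quotient = 0.9, n_eff = 0.5, eff_n = 1))
  # parent plus first cousin, hand-computed: (0.5 - 0.025)/0.625 = 0.76
  wq <- weighted_quotient(c(1, -0.2), c(0.5, 0.125))
  expect_equal(wq$quotient, 0.76, tolerance = 1e-12)
  expect_equal(wq$n_eff, 0.625, tolerance = 1e-12)
  # empty relative list is legal
  expect_equal(weighted_quotient(numeric(0), numeric(0)),
               list(quotient = 0, n_eff = 0, eff_n = 0))
  # weighted-mean idempotence: all z equal
  for (seed in 1:5) {
    set.seed(seed)
    w <- runif(7, 0.03, 0.5)
    expect_equal(weighted_quotient(rep(0.37, 7), w)$quotient, 0.37,
                 tolerance = 1e-12)
  }
})

test_that("shrinkage factor has the reliability-ratio limits", {
  par <- shrinkage_params(var_within = 1, var_between = 0.25)
  expect_equal(shrinkage_factor(par, 0), 0)
  expect_gt(shrinkage_factor(par, 1e9), 1 - 1e-8)
  s <- shrinkage_factor(par, c(0.5, 1, 2, 4, 8, 100))
  expect_true(all(diff(s) > 0))
  expect_true(all(s >= 0 & s <= 1))
  # no between-proband variance: everything shrinks to the mean
  none <- shrinkage_params(var_within = 1, var_between = 0)
  expect_equal(shrinkage_factor(none, c(0, 1, 10)), c(0, 0, 0))
  # noise-free relatives need no shrinkage
  pure <- shrinkage_params(var_within = 0, var_between = 0.25)
  expect_equal(shrinkage_factor(pure, c(0, 1, 10)), c(0, 1, 1))
})

test_that("shrinkage component estimation clamps and errors as specified", {
  expect_error(estimate_shrinkage_params(1, 1, c(0.1, 0.2)),
               class = "fgrs_estimation_error")
  # all relatives share one z: no noise to shrink
  sp <- estimate_shrinkage_params(c(0.3, 0.3, 0.3), c(1, 2, 3),
                                  rep(0.3, 10))
  expect_equal(sp$var_within, 0)
  # quotient variance below sampling variance clamps var_between to zero
  sp <- estimate_shrinkage_params(c(0.01, -0.01, 0.02), c(1, 1, 1),
                                  rnorm(100, sd = 2))
  expect_equal(sp$var_between, 0)
})

test_that("toy fixtures reproduce their hand-computed values", {
  fx <- make_toy_fixtures()
  for (nm in names(fx)) {
    f <- fx[[nm]]
    res <- compute_fgrs(f$cohort, traits = f$trait, prevalence = f$K,
                        factors = f$factors, shrinkage_params = f$shrinkage,
                        standardize = FALSE)
    row <- res[res$person_id == f$proband, ]
    expect_equal(row$quotient, f$expected$quotient, tolerance = 1e-12,
                 label = paste(nm, "quotient"))
    expect_equal(row$n_eff, f$expected$n_eff, tolerance = 1e-12,
                 label = paste(nm, "n_eff"))
    expect_equal(row$fgrs_raw, f$expected$fgrs_raw, tolerance = 1e-12,
                 label = paste(nm, "fgrs_raw"))
  }
})

test_that("compute_fgrs matches the direct-formula oracle on random
           pedigrees", {
  factors <- correction_factors("MD", c_parent_offspring = 0.8,
                                c_sibling = 0.7)
  for (seed in 1:6) {
    cohort <- rand_tree_pedigree(sample(6:10, 1), seed = 100 + seed)
    res <- compute_fgrs(cohort, traits = "MD", prevalence = 0.2,
                        factors = factors, standardize = FALSE)
    orc <- oracle_fgrs(cohort, "MD", K = 0.2, c_po = 0.8, c_sib = 0.7)
    res <- res[order(res$person_id), ]
    expect_identical(res$quotient, orc$quotient, label = paste("q", seed))
    expect_identical(res$n_eff, orc$n_eff, label = paste("ne", seed))
    expect_identical(res$fgrs_raw, orc$fgrs_raw, label = paste("raw", seed))
  }
})

test_that("scores are invariant under relabelling of person ids", {
  cohort <- rand_tree_pedigree(12, seed = 77)
  factors <- correction_factors("MD")
  res1 <- compute_fgrs(cohort, traits = "MD", prevalence = 0.2,
                       factors = factors, standardize = FALSE)
  relabel <- function(x) ifelse(is.na(x), x, paste0("zz", x))
  p <- as.data.frame(cohort$persons)
  p$person_id <- relabel(p$person_id)
  p$father_id <- relabel(p$father_id)
  p$mother_id <- relabel(p$mother_id)
  d <- as.data.frame(cohort$diagnoses)
  d$person_id <- relabel(d$person_id)
  res2 <- compute_fgrs(as_cohort(p, d), traits = "MD", prevalence = 0.2,
                       factors = factors, standardize = FALSE)
  m <- merge(data.frame(person_id = relabel(res1$person_id),
                        raw1 = res1$fgrs_raw),
             data.frame(person_id = res2$person_id, raw2 = res2$fgrs_raw))
  expect_equal(m$raw1, m$raw2, tolerance = 1e-12)
})

test_that("an affected 1st-degree relative never lowers the quotient when
           no corrections apply", {
  factors <- correction_factors("MD")  # identity corrections
  shrink <- shrinkage_params(var_within = 0.3, var_between = 0.05)
  for (seed in 1:8) {
    cohort <- rand_tree_pedigree(8, seed = 200 + seed, p_affected = 0.25)
    p <- as.data.frame(cohort$persons)
    d <- as.data.frame(cohort$diagnoses)
    # pick a proband with both parents known, then graft in a new affected
    # full sibling
    cand <- p$person_id[!is.na(p$father_id) & !is.na(p$mother_id)]
    if (!length(cand)) next
    pro <- cand[1]
    before <- compute_fgrs(cohort, traits = "MD", prevalence = 0.2,
                           factors = factors, shrinkage_params = shrink,
                           standardize = FALSE)
    newsib <- data.frame(
      person_id = "newsib", sex = "female",
      birth_year = p$birth_year[p$person_id == pro],
      father_id = p$father_id[p$person_id == pro],
      mother_id = p$mother_id[p$person_id == pro],
      censor_age = 40, lived_with_father = TRUE,
      household_id = p$household_id[p$person_id == pro],
      stringsAsFactors = FALSE)
    d2 <- rbind(d, data.frame(person_id = "newsib", trait = "MD",
                              age_at_first_registration = 20))
    after <- compute_fgrs(as_cohort(rbind(p, newsib), d2), traits = "MD",
                          prevalence = 0.2, factors = factors,
                          shrinkage_params = shrink, standardize = FALSE)
    # the affected relative's z is the maximum any relative can carry, so
    # the weighted mean cannot drop
    expect_gte(after$quotient[after$person_id == pro],
               before$quotient[before$person_id == pro])
  }
  # and a proband with no relatives moves strictly up from zero
  fx <- make_toy_fixtures()$one_affected_parent
  res <- compute_fgrs(fx$cohort, traits = "MD", prevalence = fx$K,
                      factors = fx$factors, shrinkage_params = fx$shrinkage,
                      standardize = FALSE)
  expect_gt(res$fgrs_raw[res$person_id == "pro"], 0)
})

test_that("birth-year standardization yields mean 0, SD 1 per stratum and is
           location invariant", {
  persons <- data.frame(
    person_id = sprintf("p%d", 1:6), sex = "male",
    birth_year = c(1950L, 1950L, 1950L, 1960L, 1960L, 1960L),
    father_id = NA_character_, mother_id = NA_character_, censor_age = 60,
    lived_with_father = TRUE, stringsAsFactors = FALSE)
  res <- data.frame(person_id = persons$person_id, trait = "MD",
                    quotient = 0, n_eff = 0, shrinkage = 0,
                    fgrs_raw = c(1, 2, 3, 5, 6, 10), fgrs_std = NA_real_)
  std <- standardize_by_birth_year(res, persons)
  # single stratum {1,2,3}: population-SD z-scores
  expect_equal(std$fgrs_std[1:3], c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-10)
  for (yrs in list(1:3, 4:6)) {
    expect_equal(mean(std$fgrs_std[yrs]), 0, tolerance = 1e-10)
    expect_equal(sqrt(mean(std$fgrs_std[yrs]^2)), 1, tolerance = 1e-10)
  }
  # adding a constant within a stratum changes nothing
  res2 <- res
  res2$fgrs_raw[1:3] <- res2$fgrs_raw[1:3] + 100
  expect_equal(standardize_by_birth_year(res2, persons)$fgrs_std,
               std$fgrs_std, tolerance = 1e-12)
  # zero-variance stratum errors with its name
  res3 <- res
  res3$fgrs_raw[4:6] <- 7
  expect_error(standardize_by_birth_year(res3, persons), "1960",
               class = "fgrs_estimation_error")
})

test_that("probands without eligible relatives get a zero score", {
  fx <- make_toy_fixtures()$no_relatives
  res <- compute_fgrs(fx$cohort, traits = "MD", prevalence = 0.2,
                      factors = fx$factors, shrinkage_params = fx$shrinkage,
                      standardize = FALSE)
  expect_equal(res$fgrs_raw[res$person_id == "pro"], 0)
  expect_equal(res$n_eff[res$person_id == "pro"], 0)
  expect_equal(res$shrinkage[res$person_id == "pro"], 0)
})

test_that("quantitative traits feed standardized phenotypes through the same
           aggregation", {
  # father with a high BMI, mother average: proband quotient is the weighted
  # mean of the parents' standardized values
  persons <- data.frame(
    person_id = c("f", "m", "pro", "f2", "m2", "o2"),
    sex = c("male", "female", "male", "male", "female", "female"),
    birth_year = c(1950L, 1950L, 1980L, 1950L, 1950L, 1980L),
    father_id = c(NA, NA, "f", NA, NA, "f2"),
    mother_id = c(NA, NA, "m", NA, NA, "m2"),
    censor_age = 60, lived_with_father = TRUE, stringsAsFactors = FALSE)
  quant <- data.frame(person_id = c("f", "m", "f2", "m2"), trait = "BMI",
                      value = c(30, 20, 25, 25))
  cohort <- as_cohort(persons, NULL, quant)
  res <- compute_fgrs(cohort, traits = "BMI",
                      factors = correction_factors("BMI"),
                      shrinkage_params = shrinkage_params(1, 0.25),
                      standardize = FALSE)
  zv <- quantitative_z(cohort, "BMI")
  zmap <- setNames(zv$z, zv$person_id)
  expect_equal(res$quotient[res$person_id == "pro"],
               mean(zmap[c("f", "m")]), tolerance = 1e-12)
  # persons without a phenotype contribute nothing
  expect_equal(res$n_eff[res$person_id == "pro"], 1)
})
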