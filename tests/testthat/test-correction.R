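# Cohort of independent father-child pairs with statuses generated directly
# on the log-odds scale: child logit = base + g*father + h*father*lived_with.
# The log-odds slope ratio then converges to g/(g+h) exactly.
logodds_parent_cohort <- function(n_pairs, g, h, base = -1.5, p_father = 0.35,
                                  p_nlw = 0.4, seed = 1) {
  set.seed(seed)
  f_aff <- runif(n_pairs) < p_father
  lw <- runif(n_pairs) >= p_nlw
  eta <- base + g * f_aff + h * f_aff * lw
  c_aff <- runif(n_pairs) < plogis(eta)
  fid <- sprintf("f%05d", seq_len(n_pairs))
  cid <- sprintf("c%05d", seq_len(n_pairs))
  persons <- data.frame(
    person_id = c(fid, cid), sex = "male",
    birth_year = rep(c(1950L, 1980L), each = n_pairs),
    father_id = c(rep(NA_character_, n_pairs), fid),
    mother_id = NA_character_, censor_age = rep(c(67, 37), each = n_pairs),
    lived_with_father = c(rep(TRUE, n_pairs), lw), stringsAsFactors = FALSE)
  aff <- c(fid[f_aff], cid[c_aff])
  diagnoses <- data.frame(person_id = aff, trait = "MD",
                          age_at_first_registration = 25)
  as_cohort(persons, diagnoses)
}

# Independent maternal half-sib pairs (one shared mother, unknown fathers),
# reared together (same household) or apart, statuses on the log-odds scale.
logodds_sib_cohort <- function(n_pairs, g, h, base = -1.5, p_older = 0.35,
                               p_apart = 0.5, seed = 1) {
  set.seed(seed)
  o_aff <- runif(n_pairs) < p_older
  together <- runif(n_pairs) >= p_apart
  eta <- base + g * o_aff + h * o_aff * together
  y_aff <- runif(n_pairs) < plogis(eta)
  mid <- sprintf("m%05d", seq_len(n_pairs))
  oid <- sprintf("o%05d", seq_len(n_pairs))
  yid <- sprintf("y%05d", seq_len(n_pairs))
  persons <- data.frame(
    person_id = c(mid, oid, yid),
    sex = rep(c("female", "male", "male"), each = n_pairs),
    birth_year = rep(c(1950L, 1975L, 1980L), each = n_pairs),
    father_id = NA_character_,
    mother_id = c(rep(NA_character_, n_pairs), mid, mid),
    censor_age = rep(c(67, 42, 37), each = n_pairs),
    lived_with_father = TRUE,
    household_id = c(rep(NA_character_, n_pairs),
                     paste0("ho", seq_len(n_pairs)),
                     ifelse(together, paste0("ho", seq_len(n_pairs)),
                            paste0("hy", seq_len(n_pairs)))),
    stringsAsFactors = FALSE)
  aff <- c(oid[o_aff], yid[y_aff])
  diagnoses <- data.frame(person_id = aff, trait = "MD",
                          age_at_first_registration = 25)
  as_cohort(persons, diagnoses)
}

test_that("identical resemblance in both groups yields a factor of exactly 1", {
  # both father groups carry the same 2x2 table (positive association)
  build <- function() {
    counts <- c(ff_cc = 15, ff_cu = 5, fu_cc = 5, fu_cu = 15)
    make_group <- function(lw, tag) {
      f_aff <- rep(c(TRUE, TRUE, FALSE, FALSE), counts)
      c_aff <- rep(c(TRUE, FALSE, TRUE, FALSE), counts)
      n <- length(f_aff)
      fid <- sprintf("f%s%03d", tag, seq_len(n))
      cid <- sprintf("c%s%03d", tag, seq_len(n))
      list(persons = data.frame(
        person_id = c(fid, cid), sex = "male",
        birth_year = rep(c(1950L, 1980L), each = n),
        father_id = c(rep(NA_character_, n), fid),
        mother_id = NA_character_, censor_age = rep(c(67, 37), each = n),
        lived_with_father = c(rep(TRUE, n), rep(lw, n)),
        stringsAsFactors = FALSE),
        affected = c(fid[f_aff], cid[c_aff]))
    }
    g1 <- make_group(TRUE, "a"); g2 <- make_group(FALSE, "b")
    persons <- rbind(g1$persons, g2$persons)
    diagnoses <- data.frame(person_id = c(g1$affected, g2$affected),
                            trait = "MD", age_at_first_registration = 25)
    as_cohort(persons, diagnoses)
  }
  est <- estimate_parent_correction(build(), "MD")
  expect_equal(est$factor, 1, tolerance = 1e-10)
  expect_equal(est$fit_info$raw_ratio, 1, tolerance = 1e-10)
})

test_that("parent factor converges to the generative genetic share g/(g+h)", {
  g <- 1.0; h <- 0.6
  est <- estimate_parent_correction(
    logodds_parent_cohort(40000, g = g, h = h, seed = 11), "MD")
  expect_lt(abs(est$fit_info$raw_ratio - g / (g + h)), 0.08)
  expect_lt(est$factor, 1)
  # with no household effect the raw ratio hovers around 1
  est0 <- estimate_parent_correction(
    logodds_parent_cohort(40000, g = g, h = 0, seed = 12), "MD")
  expect_lt(abs(est0$fit_info$raw_ratio - 1), 0.12)
})

test_that("sibling factor recovers the genetic share from half-sib pairs", {
  g <- 1.0; h <- 0.6
  est <- estimate_sibling_correction(
    logodds_sib_cohort(40000, g = g, h = h, seed = 21), "MD")
  expect_lt(abs(est$fit_info$raw_ratio - g / (g + h)), 0.08)
  expect_lt(est$factor, 1)
  expect_gt(est$fit_info$together$n_pairs, 0)
  expect_gt(est$fit_info$apart$n_pairs, 0)
})

test_that("the sibling comparison is invariant to which sib is the outcome", {
  cohort <- logodds_sib_cohort(4000, g = 1, h = 0.6, seed = 31)
  est1 <- estimate_sibling_correction(cohort, "MD")
  # swap the birth order so the regression outcome flips; the 2x2 log odds
  # ratio is symmetric, so the factor is unchanged
  p <- as.data.frame(cohort$persons)
  p$birth_year[startsWith(p$person_id, "o")] <- 1980L
  p$birth_year[startsWith(p$person_id, "y")] <- 1975L
  est2 <- estimate_sibling_correction(as_cohort(p, cohort$diagnoses), "MD")
  expect_equal(est1$factor, est2$factor, tolerance = 1e-8)
})

test_that("degenerate designs raise estimation errors", {
  # no half-sib pairs at all
  expect_error(
    estimate_sibling_correction(
      as_cohort(data.frame(
        person_id = c("a", "b"), sex = c("male", "female"),
        birth_year = c(1950L, 1955L), father_id = NA_character_,
        mother_id = NA_character_, censor_age = 60,
        lived_with_father = TRUE, stringsAsFactors = FALSE),
        data.frame(person_id = "a", trait = "MD",
                   age_at_first_registration = 30)), "MD"),
    "half-sib", class = "fgrs_estimation_error")
  # no variation in a group
  cohort <- logodds_parent_cohort(50, g = 1, h = 0, seed = 41)
  d <- cohort$diagnoses[!cohort$diagnoses$person_id %in%
                          cohort$persons$person_id[
                            !cohort$persons$lived_with_father], ]
  p <- as.data.frame(cohort$persons)
  nlw_children <- p$person_id[!p$lived_with_father & !is.na(p$father_id)]
  d2 <- d[!d$person_id %in% nlw_children, ]
  expect_error(estimate_parent_correction(as_cohort(p, d2), "MD"),
               class = "fgrs_estimation_error")
})

test_that("corrections multiply only 1st-degree pair classes", {
  factors <- correction_factors("MD", c_parent_offspring = 0.8,
                                c_sibling = 0.7)
  z <- c(1, 1, 1, 1)
  cls <- c("parent_offspring", "full_sibling", "half_sibling", "other")
  expect_equal(apply_correction(z, cls, factors), c(0.8, 0.7, 1, 1))
  # factor 1 is the identity
  id <- correction_factors("MD")
  expect_equal(apply_correction(z, cls, id), z)
})

test_that("correction factors survive the export/import round trip", {
  f <- correction_factors("MD", c_parent_offspring = 0.82, c_sibling = 0.63)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_corrections(f, path)
  back <- read_corrections(path)
  expect_equal(back$MD$c_parent_offspring, 0.82)
  expect_equal(back$MD$c_sibling, 0.63)
})
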