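# Registry-style cohort tables: construction, validation, reading, writing.
#
# Dialect: UTF-8, tab-separated, header row, empty string = missing. IDs are
# opaque strings and are never parsed for meaning.

.person_cols <- c("person_id", "sex", "birth_year", "father_id", "mother_id",
                  "censor_age", "lived_with_father", "household_id")
.person_required <- setdiff(.person_cols, "household_id")
.diag_cols <- c("person_id", "trait", "age_at_first_registration")
.quant_cols <- c("person_id", "trait", "value")

#' Assemble and validate a cohort from in-memory tables
#'
#' A cohort bundles the three registry-style tables the package consumes: a
#' person table (pedigree links, sex, birth year, censoring age, cohabitation
#' flags), a binary-diagnosis table (person, trait code, age at first
#' registration) and an optional quantitative-trait table.
#'
#' @param persons data.frame with columns `person_id`, `sex` ("male"/"female"),
#'   `birth_year`, `father_id`, `mother_id` (NA when unknown), `censor_age`
#'   (age at death or end of follow-up, years), `lived_with_father` (logical;
#'   FALSE marks a child whose father sired but never lived with them) and
#'   optionally `household_id` (shared id defines "reared together").
#' @param diagnoses data.frame with columns `person_id`, `trait`,
#'   `age_at_first_registration`; at most one row per person and trait.
#' @param quantitative optional data.frame with columns `person_id`, `trait`,
#'   `value` for continuous phenotypes (e.g. BMI, years of education).
#' @return An object of class `fgrs_cohort`: a list of the three validated
#'   tables (as data.tables).
#' @examples
#' p <- data.frame(person_id = c("c", "f", "m"), sex = c("male", "male", "female"),
#'                 birth_year = c(1980L, 1950L, 1952L),
#'                 father_id = c("f", NA, NA), mother_id = c("m", NA, NA),
#'                 censor_age = c(37, 67, 65), lived_with_father = TRUE)
#' d <- data.frame(person_id = "f", trait = "MD", age_at_first_registration = 40)
#' as_cohort(p, d)
#' @export
as_cohort <- function(persons, diagnoses = NULL, quantitative = NULL) {
  persons <- as.data.table(persons)
  if (is.null(diagnoses)) {
    diagnoses <- data.table(person_id = character(), trait = character(),
                            age_at_first_registration = numeric())
  }
  diagnoses <- as.data.table(diagnoses)
  if (is.null(quantitative)) {
    quantitative <- data.table(person_id = character(), trait = character(),
                               value = numeric())
  }
  quantitative <- as.data.table(quantitative)

  miss <- setdiff(.person_required, names(persons))
  if (length(miss))
    stop_fgrs("fgrs_format_error", "person table lacks required column(s): %s",
              paste(miss, collapse = ", "))
  if (!"household_id" %in% names(persons))
    persons[, household_id := NA_character_]
  miss <- setdiff(.diag_cols, names(diagnoses))
  if (length(miss))
    stop_fgrs("fgrs_format_error", "diagnosis table lacks required column(s): %s",
              paste(miss, collapse = ", "))
  miss <- setdiff(.quant_cols, names(quantitative))
  if (length(miss))
    stop_fgrs("fgrs_format_error", "quantitative table lacks required column(s): %s",
              paste(miss, collapse = ", "))

  persons <- persons[, .(person_id = as.character(person_id),
                         sex = as.character(sex),
                         birth_year = as.integer(birth_year),
                         father_id = blank_na(father_id),
                         mother_id = blank_na(mother_id),
                         censor_age = as.numeric(censor_age),
                         lived_with_father = as.logical(lived_with_father),
                         household_id = blank_na(household_id))]
  diagnoses <- diagnoses[, .(person_id = as.character(person_id),
                             trait = as.character(trait),
                             age_at_first_registration =
                               as.numeric(age_at_first_registration))]
  quantitative <- quantitative[, .(person_id = as.character(person_id),
                                   trait = as.character(trait),
                                   value = as.numeric(value))]

  cohort <- structure(list(persons = persons, diagnoses = diagnoses,
                           quantitative = quantitative),
                      class = "fgrs_cohort")
  validate_cohort(cohort)
  cohort
}

blank_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

#' Validate the invariants of a cohort
#'
#' Checks id uniqueness, parent references (existence and sex), censoring ages,
#' pedigree acyclicity and the per-table uniqueness/range invariants of the
#' diagnosis and quantitative tables. Errors are classed `fgrs_format_error`
#' (shape problems) or `fgrs_integrity_error` (referential problems).
#'
#' @param cohort an `fgrs_cohort`.
#' @return the cohort, invisibly, if valid.
#' @export
validate_cohort <- function(cohort) {
  p <- cohort$persons
  if (anyDuplicated(p$person_id))
    stop_fgrs("fgrs_integrity_error", "duplicated person_id: %s",
              paste(unique(p$person_id[duplicated(p$person_id)]), collapse = ", "))
  if (any(is.na(p$person_id) | p$person_id == ""))
    stop_fgrs("fgrs_format_error", "missing person_id in person table")
  bad_sex <- !p$sex %in% c("male", "female")
  if (any(bad_sex))
    stop_fgrs("fgrs_format_error", "unknown sex for person(s): %s",
              paste(head(p$person_id[bad_sex], 5), collapse = ", "))
  if (any(is.na(p$birth_year)))
    stop_fgrs("fgrs_format_error", "missing birth_year for person(s): %s",
              paste(head(p$person_id[is.na(p$birth_year)], 5), collapse = ", "))
  if (any(is.na(p$censor_age) | p$censor_age < 0))
    stop_fgrs("fgrs_format_error", "censor_age missing or negative for person(s): %s",
              paste(head(p$person_id[is.na(p$censor_age) | p$censor_age < 0], 5),
                    collapse = ", "))
  if (any(is.na(p$lived_with_father)))
    stop_fgrs("fgrs_format_error", "lived_with_father must be TRUE/FALSE")

  for (side in c("father_id", "mother_id")) {
    ref <- p[[side]]
    dangling <- !is.na(ref) & !ref %in% p$person_id
    if (any(dangling))
      stop_fgrs("fgrs_integrity_error",
                "%s refers to missing person(s): %s", side,
                paste(unique(head(ref[dangling], 5)), collapse = ", "))
    self <- !is.na(ref) & ref == p$person_id
    if (any(self))
      stop_fgrs("fgrs_integrity_error", "person(s) listed as own parent: %s",
                paste(p$person_id[self], collapse = ", "))
  }
  sex_of <- setNames(p$sex, p$person_id)
  bad <- !is.na(p$father_id) & sex_of[p$father_id] != "male"
  if (any(bad))
    stop_fgrs("fgrs_integrity_error", "father_id points to non-male person(s): %s",
              paste(unique(head(p$father_id[bad], 5)), collapse = ", "))
  bad <- !is.na(p$mother_id) & sex_of[p$mother_id] != "female"
  if (any(bad))
    stop_fgrs("fgrs_integrity_error", "mother_id points to non-female person(s): %s",
              paste(unique(head(p$mother_id[bad], 5)), collapse = ", "))

  pedigree_depths(p)  # errors on cycles

  d <- cohort$diagnoses
  if (nrow(d)) {
    dangling <- !d$person_id %in% p$person_id
    if (any(dangling))
      stop_fgrs("fgrs_integrity_error", "diagnosis for unknown person(s): %s",
                paste(unique(head(d$person_id[dangling], 5)), collapse = ", "))
    if (anyDuplicated(d[, .(person_id, trait)]))
      stop_fgrs("fgrs_integrity_error",
                "more than one diagnosis record per (person, trait)")
    if (any(is.na(d$age_at_first_registration) | d$age_at_first_registration < 0))
      stop_fgrs("fgrs_format_error",
                "age_at_first_registration missing or negative")
    cens <- setNames(p$censor_age, p$person_id)
    late <- d$age_at_first_registration > cens[d$person_id] + 1e-9
    if (any(late))
      stop_fgrs("fgrs_integrity_error",
                "age_at_first_registration after censor_age for person(s): %s",
                paste(unique(head(d$person_id[late], 5)), collapse = ", "))
  }
  q <- cohort$quantitative
  if (nrow(q)) {
    dangling <- !q$person_id %in% p$person_id
    if (any(dangling))
      stop_fgrs("fgrs_integrity_error", "quantitative value for unknown person(s): %s",
                paste(unique(head(q$person_id[dangling], 5)), collapse = ", "))
    if (anyDuplicated(q[, .(person_id, trait)]))
      stop_fgrs("fgrs_integrity_error",
                "more than one quantitative record per (person, trait)")
    if (any(!is.finite(q$value)))
      stop_fgrs("fgrs_format_error", "non-finite quantitative value")
  }
  invisible(cohort)
}

# Generation depth of every person (founders = 0); errors on pedigree cycles.
pedigree_depths <- function(persons) {
  n <- nrow(persons)
  fi <- match(persons$father_id, persons$person_id)
  mi <- match(persons$mother_id, persons$person_id)
  depth <- rep(NA_integer_, n)
  depth[is.na(fi) & is.na(mi)] <- 0L
  repeat {
    pend <- which(is.na(depth))
    if (!length(pend)) break
    fd <- ifelse(is.na(fi[pend]), -1L, depth[fi[pend]])
    md <- ifelse(is.na(mi[pend]), -1L, depth[mi[pend]])
    ready <- !is.na(fd) & !is.na(md)
    if (!any(ready))
      stop_fgrs("fgrs_integrity_error",
                "pedigree cycle involving person(s): %s",
                paste(head(persons$person_id[pend], 5), collapse = ", "))
    depth[pend[ready]] <- pmax(fd[ready], md[ready]) + 1L
  }
  setNames(depth, persons$person_id)
}

#' Read a cohort from tab-separated registry-style files
#'
#' Files are UTF-8, tab-separated with a header row; the empty string encodes
#' a missing value. Column names must match the field names documented in
#' [as_cohort()]; unknown columns are dropped with a warning.
#'
#' @param person_path,diagnosis_path paths to the person and diagnosis tables.
#' @param quant_path optional path to the quantitative-trait table.
#' @return a validated [as_cohort()] object.
#' @export
read_cohort <- function(person_path, diagnosis_path, quant_path = NULL) {
  read_tsv_checked <- function(path, keep) {
    if (!file.exists(path))
      stop_fgrs("fgrs_format_error", "file not found: %s", path)
    hdr <- names(fread(path, sep = "\t", header = TRUE, nrows = 0L))
    char_cols <- intersect(intersect(
      c("person_id", "father_id", "mother_id", "household_id", "sex",
        "trait"), keep), hdr)
    x <- fread(path, sep = "\t", header = TRUE, na.strings = "",
               colClasses = if (length(char_cols))
                 list(character = char_cols))
    extra <- setdiff(names(x), keep)
    if (length(extra)) {
      warning(sprintf("ignoring unknown column(s) in %s: %s", basename(path),
                      paste(extra, collapse = ", ")), call. = FALSE)
      x[, (extra) := NULL]
    }
    miss <- setdiff(setdiff(keep, "household_id"), names(x))
    if (length(miss))
      stop_fgrs("fgrs_format_error", "%s lacks required column(s): %s",
                basename(path), paste(miss, collapse = ", "))
    x
  }
  persons <- read_tsv_checked(person_path, .person_cols)
  diagnoses <- read_tsv_checked(diagnosis_path, .diag_cols)
  quantitative <- if (!is.null(quant_path)) read_tsv_checked(quant_path, .quant_cols)
  as_cohort(persons, diagnoses, quantitative)
}

#' Write a cohort back to the three-table tab-separated format
#'
#' `read_cohort()` on the emitted files reproduces the cohort field for field.
#' An empty quantitative table is written as a header-only file so the file
#' set is uniform.
#'
#' @param cohort an `fgrs_cohort`.
#' @param out_dir output directory, created if absent.
#' @return named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "fgrs_cohort"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_fgrs("fgrs_io_error", "cannot create directory %s", out_dir)
  paths <- c(persons = file.path(out_dir, "persons.tsv"),
             diagnoses = file.path(out_dir, "diagnoses.tsv"),
             quantitative = file.path(out_dir, "quantitative.tsv"))
  ok <- tryCatch({
    fwrite(cohort$persons, paths[["persons"]], sep = "\t", na = "", quote = FALSE)
    fwrite(cohort$diagnoses, paths[["diagnoses"]], sep = "\t", na = "", quote = FALSE)
    fwrite(cohort$quantitative, paths[["quantitative"]], sep = "\t", na = "",
           quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_fgrs("fgrs_io_error", "failed writing cohort to %s: %s", out_dir,
              conditionMessage(ok))
  invisible(paths)
}

#' @export
print.fgrs_cohort <- function(x, ...) {
  cat(sprintf("<fgrs_cohort> %d persons, %d diagnoses (%d traits), %d quantitative records\n",
              nrow(x$persons), nrow(x$diagnoses),
              length(unique(x$diagnoses$trait)), nrow(x$quantitative)))
  invisible(x)
}
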