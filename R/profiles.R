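# Disorder-profile analyses on top of the FGRS: diagnostic hierarchies,
# group means with 95% CIs, ranking by score, and specificity criteria.

#' Diagnostic hierarchy rules
#'
#' An ordered list of (dominant, suppressed) trait pairs: a person carrying
#' both is coded as the dominant one only. The classic example is the DSM-5
#' mood hierarchy, where a person with both major depression and bipolar
#' disorder is coded as bipolar.
#'
#' @param dominant,suppressed character vectors of equal length.
#' @return an `fgrs_hierarchy` data.table; errors if the rules are cyclic.
#' @examples
#' hierarchy_rules("BD", "MD")  # MD suppressed in the presence of BD
#' @export
hierarchy_rules <- function(dominant, suppressed) {
  stopifnot(length(dominant) == length(suppressed))
  rules <- data.table(dominant = as.character(dominant),
                      suppressed = as.character(suppressed))
  if (any(rules$dominant == rules$suppressed))
    stop_fgrs("fgrs_config_error", "a trait cannot suppress itself")
  # Kahn's algorithm on dominant -> suppressed edges
  nodes <- unique(c(rules$dominant, rules$suppressed))
  edges <- as.data.frame(rules)
  while (length(nodes)) {
    no_incoming <- setdiff(nodes, edges$suppressed)
    if (!length(no_incoming))
      stop_fgrs("fgrs_config_error", "hierarchy rules contain a cycle")
    nodes <- setdiff(nodes, no_incoming)
    edges <- edges[!(edges$dominant %in% no_incoming), , drop = FALSE]
  }
  structure(rules, class = c("fgrs_hierarchy", "data.table"))
}

#' Apply a diagnostic hierarchy to a diagnosis table
#'
#' For each person and rule, if both the dominant and the suppressed trait are
#' present, the suppressed trait's record is removed. Idempotent.
#'
#' @param diagnoses a diagnosis table (as in an `fgrs_cohort`).
#' @param rules an [hierarchy_rules()] object.
#' @return the filtered diagnosis table.
#' @export
apply_hierarchy <- function(diagnoses, rules) {
  stopifnot(inherits(rules, "fgrs_hierarchy"))
  d <- as.data.table(diagnoses)
  for (r in seq_len(nrow(rules))) {
    has_dom <- d[trait == rules$dominant[r], person_id]
    d <- d[!(trait == rules$suppressed[r] & person_id %in% has_dom)]
  }
  d[]
}

#' Mean standardized FGRS per affected group
#'
#' For each proband group (persons carrying a given diagnosis) and each FGRS
#' trait, the mean standardized score with a normal-approximation 95% CI
#' (`mean +/- 1.96 * SD / sqrt(n)`; width 0 for a single person). A person
#' affected with several disorders belongs to several groups.
#'
#' @param results FGRS table from [compute_fgrs()] (standardized).
#' @param diagnoses diagnosis table defining the groups (apply any hierarchy
#'   first).
#' @param groups trait codes defining proband groups; default: all traits in
#'   `diagnoses`.
#' @param fgrs_traits FGRS columns to profile; default: all traits in
#'   `results`.
#' @return an `fgrs_profile` data.table with columns `group`, `fgrs_trait`,
#'   `mean`, `ci_low`, `ci_high`, `n`.
#' @export
group_mean_fgrs <- function(results, diagnoses, groups = NULL,
                            fgrs_traits = NULL) {
  results <- as.data.table(results)
  diagnoses <- as.data.table(diagnoses)
  if (is.null(groups)) groups <- sort(unique(diagnoses$trait))
  if (is.null(fgrs_traits)) fgrs_traits <- sort(unique(results$trait))
  if (any(is.na(results$fgrs_std)))
    stop_fgrs("fgrs_domain_error", "results must contain standardized FGRS")
  cells <- rbindlist(lapply(groups, function(g) {
    members <- unique(diagnoses[trait == g, person_id])
    if (!length(members))
      stop_fgrs("fgrs_estimation_error", "group '%s' is empty", g)
    sub <- results[trait %in% fgrs_traits & person_id %in% members]
    sub[, .(group = g, mean = mean(fgrs_std),
            se = if (.N > 1L) sd(fgrs_std) / sqrt(.N) else 0,
            n = .N), by = .(fgrs_trait = trait)]
  }))
  cells[, `:=`(ci_low = mean - 1.96 * se, ci_high = mean + 1.96 * se, se = NULL)]
  setcolorder(cells, c("group", "fgrs_trait", "mean", "ci_low", "ci_high", "n"))
  structure(cells, class = c("fgrs_profile", "data.table"))
}

#' Rank proband groups within each FGRS
#'
#' For each FGRS trait, orders the groups from highest to lowest mean score;
#' ties are broken alphabetically by group for determinism.
#'
#' @param table an `fgrs_profile` from [group_mean_fgrs()].
#' @return data.table with columns `fgrs_trait`, `rank`, `group`, `mean`.
#' @export
rank_by_fgrs <- function(table) {
  stopifnot(inherits(table, "fgrs_profile"))
  tab <- as.data.table(table)
  out <- tab[order(fgrs_trait, -mean, group),
             .(rank = seq_len(.N), group, mean), by = fgrs_trait]
  out[]
}

#' Specificity criteria for each FGRS
#'
#' For each disorder that appears both as a proband group and as an FGRS
#' trait: criterion (i) asks whether the FGRS is strictly highest in the
#' disorder it was built from; criterion (ii), evaluated only when (i) holds,
#' asks whether that own-disorder mean is substantially larger than the
#' second-largest — at least `ratio_threshold` times it. The ratio test needs
#' a positive own mean; a second-largest mean at or below zero counts as a
#' trivially substantial separation.
#'
#' @param table an `fgrs_profile`.
#' @param ratio_threshold minimum own/second ratio (default 2, the 2:1 rule).
#' @return data.table with columns `disorder`, `criterion_i`, `criterion_ii`.
#' @export
specificity_criteria <- function(table, ratio_threshold = 2.0) {
  stopifnot(inherits(table, "fgrs_profile"))
  tab <- as.data.table(table)
  disorders <- intersect(unique(tab$group), unique(tab$fgrs_trait))
  out <- rbindlist(lapply(sort(disorders), function(d) {
    col <- tab[fgrs_trait == d]
    own <- col[group == d, mean]
    others <- col[group != d, mean]
    crit_i <- length(others) == 0L || own > max(others)
    crit_ii <- FALSE
    if (crit_i && own > 0) {
      second <- if (length(others)) max(others) else -Inf
      crit_ii <- second <= 0 || own >= ratio_threshold * second
    }
    data.table(disorder = d, criterion_i = crit_i, criterion_ii = crit_ii)
  }))
  out[]
}

#' Write a profile table as TSV
#'
#' @param table an `fgrs_profile`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_profile <- function(table, path) {
  fwrite(as.data.table(table), path, sep = "\t", quote = FALSE)
  invisible(path)
}
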