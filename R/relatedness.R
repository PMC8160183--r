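# Pedigree construction and enumeration of 1st-5th-degree relatives.
#
# "Degree" here encodes expected additive-genetic sharing (0.5^degree), not
# generation distance: full siblings are degree 1 and half-siblings degree 2.
# Operationally the degree is the shortest genealogical connection through a
# common ancestor, with a one-step discount when the connection runs through a
# shared ancestral *couple* (the full-sibling shortcut). For outbred pedigrees
# this reproduces the classical degrees: parent/child and full sibs 1,
# grandparents, half-sibs and avuncular pairs 2, first cousins 3, and so on.
# In pedigrees with multiple connecting paths (inbreeding loops) the closest
# single relationship is used; paths are never summed.

#' Build a pedigree index from a cohort
#'
#' Precomputes the ancestor table and the full list of relative pairs within
#' `max_degree`, so that per-proband queries are lookups.
#'
#' @param cohort an `fgrs_cohort`.
#' @param max_degree integer, furthest degree of relatedness retained
#'   (default 5).
#' @return an object of class `fgrs_pedigree` holding the person table, the
#'   relative-pair table and the degree bound.
#' @export
build_pedigree <- function(cohort, max_degree = 5L) {
  stopifnot(inherits(cohort, "fgrs_cohort"))
  max_degree <- as.integer(max_degree)
  if (is.na(max_degree) || max_degree < 1L)
    stop_fgrs("fgrs_domain_error", "max_degree must be a positive integer")
  p <- cohort$persons
  anc <- ancestor_table(p, max_depth = max_degree)
  pairs <- relative_pair_table(anc, p, max_degree)
  structure(list(persons = p, pairs = pairs, max_degree = max_degree),
            class = "fgrs_pedigree")
}

# Long table (person, anc, depth, via): every ancestor of every person up to
# max_depth meioses, where `via` is the child of `anc` on the path (the person
# themselves at depth 1). Depth-0 self rows are included so that
# ancestor-descendant pairs fall out of the self-join.
ancestor_table <- function(persons, max_depth) {
  ids <- persons$person_id
  pl <- rbind(
    data.table(child = ids, parent = persons$father_id),
    data.table(child = ids, parent = persons$mother_id)
  )[!is.na(parent)]
  out <- vector("list", max_depth + 1L)
  out[[1]] <- data.table(person = ids, anc = ids, depth = 0L, via = NA_character_)
  cur <- data.table(person = pl$child, anc = pl$parent, depth = 1L, via = pl$child)
  d <- 1L
  while (nrow(cur) && d <= max_depth) {
    out[[d + 1L]] <- cur
    nxt <- merge(cur[, .(person, via_new = anc, anc)], pl,
                 by.x = "anc", by.y = "child", allow.cartesian = TRUE)
    cur <- nxt[, .(person, anc = parent, depth = d + 1L, via = via_new)]
    d <- d + 1L
  }
  unique(rbindlist(out[!vapply(out, is.null, logical(1))]))
}

relative_pair_table <- function(anc, persons, max_degree) {
  fa <- setNames(persons$father_id, persons$person_id)
  mo <- setNames(persons$mother_id, persons$person_id)

  jt <- merge(anc[, .(anc, p1 = person, di = depth, v1 = via)],
              anc[, .(anc, p2 = person, dj = depth, v2 = via)],
              by = "anc", allow.cartesian = TRUE)
  jt <- jt[p1 < p2 & di + dj <= max_degree + 1L]
  if (nrow(jt)) {
    full_sib_vias <- !is.na(jt$v1) & !is.na(jt$v2) & jt$v1 != jt$v2 &
      !is.na(fa[jt$v1]) & !is.na(fa[jt$v2]) & fa[jt$v1] == fa[jt$v2] &
      !is.na(mo[jt$v1]) & !is.na(mo[jt$v2]) & mo[jt$v1] == mo[jt$v2]
    jt[, deg := di + dj - as.integer(full_sib_vias)]
  } else jt[, deg := integer()]
  jt <- jt[deg <= max_degree & deg >= 1L]
  if (!nrow(jt))
    return(data.table(proband_id = character(), relative_id = character(),
                      degree = integer(), weight = numeric(),
                      pair_class = character(), reared_together = logical(),
                      key = c("proband_id", "relative_id")))
  pairs <- jt[, .(degree = min(deg)), by = .(p1, p2)]

  f1 <- fa[pairs$p1]; f2 <- fa[pairs$p2]
  m1 <- mo[pairs$p1]; m2 <- mo[pairs$p2]
  is_parent <- (!is.na(f1) & f1 == pairs$p2) | (!is.na(m1) & m1 == pairs$p2) |
               (!is.na(f2) & f2 == pairs$p1) | (!is.na(m2) & m2 == pairs$p1)
  share_f <- !is.na(f1) & !is.na(f2) & f1 == f2
  share_m <- !is.na(m1) & !is.na(m2) & m1 == m2
  pairs[, pair_class := fifelse(is_parent, "parent_offspring",
                        fifelse(share_f & share_m, "full_sibling",
                        fifelse(xor(share_f, share_m) & degree == 2L,
                                "half_sibling", "other")))]

  hh <- setNames(persons$household_id, persons$person_id)
  lwf <- setNames(persons$lived_with_father, persons$person_id)
  rt <- rep(TRUE, nrow(pairs))
  # father-offspring pairs carry the child's lived_with_father flag
  sel <- !is.na(f1) & f1 == pairs$p2
  rt[sel] <- lwf[pairs$p1][sel]
  sel <- !is.na(f2) & f2 == pairs$p1
  rt[sel] <- lwf[pairs$p2][sel]
  sel <- pairs$pair_class %in% c("full_sibling", "half_sibling")
  rt[sel] <- !is.na(hh[pairs$p1][sel]) & !is.na(hh[pairs$p2][sel]) &
    hh[pairs$p1][sel] == hh[pairs$p2][sel]
  pairs[, reared_together := rt]
  pairs[, weight := 0.5^degree]

  sym <- rbind(
    pairs[, .(proband_id = p1, relative_id = p2, degree, weight, pair_class,
              reared_together)],
    pairs[, .(proband_id = p2, relative_id = p1, degree, weight, pair_class,
              reared_together)]
  )
  setkey(sym, proband_id, relative_id)
  sym[]
}

#' Enumerate a proband's relatives
#'
#' Returns every genealogical relative within `max_degree`, each at its
#' closest degree; the proband never appears in their own list.
#'
#' @param pedigree an `fgrs_pedigree` from [build_pedigree()].
#' @param proband_id person id.
#' @param max_degree optional further restriction (must not exceed the bound
#'   the pedigree was built with).
#' @return data.table with columns `relative_id`, `degree`, `weight`
#'   (`0.5^degree`), `pair_class` and `reared_together`.
#' @export
enumerate_relatives <- function(pedigree, proband_id, max_degree = NULL) {
  stopifnot(inherits(pedigree, "fgrs_pedigree"))
  if (!proband_id %in% pedigree$persons$person_id)
    stop_fgrs("fgrs_key_error", "unknown proband id: %s", proband_id)
  pid <- proband_id
  out <- pedigree$pairs[list(pid), on = "proband_id", nomatch = NULL]
  if (!is.null(max_degree)) {
    if (max_degree > pedigree$max_degree)
      stop_fgrs("fgrs_domain_error",
                "pedigree was built with max_degree = %d", pedigree$max_degree)
    out <- out[degree <= max_degree]
  }
  out[, !"proband_id"]
}

#' Kinship weight for a degree of relatedness
#'
#' The expected additive-genetic sharing halves with each degree:
#' `0.5^degree` (0.5 for 1st degree, 0.03125 for 5th).
#'
#' @param degree integer vector of degrees in `1..max_degree`.
#' @param max_degree upper bound (default 5).
#' @return numeric vector of weights.
#' @export
kinship_weight <- function(degree, max_degree = 5L) {
  if (any(is.na(degree)) || any(degree != as.integer(degree)) ||
      any(degree < 1L) || any(degree > max_degree))
    stop_fgrs("fgrs_domain_error",
              "degree must be an integer in 1..%d", max_degree)
  0.5^degree
}

#' Classify a relative pair
#'
#' @param pedigree an `fgrs_pedigree`.
#' @param proband_id,relative_id person ids of a pair within the pedigree's
#'   degree bound.
#' @return list with `pair_class` (one of `parent_offspring`, `full_sibling`,
#'   `half_sibling`, `other`) and `reared_together`. Parent-offspring pairs
#'   take the child's `lived_with_father` flag (mothers count as always
#'   reared together); sibling-type pairs compare `household_id`; all other
#'   classes are reared together by convention.
#' @export
classify_pair <- function(pedigree, proband_id, relative_id) {
  stopifnot(inherits(pedigree, "fgrs_pedigree"))
  pid <- proband_id
  rid <- relative_id
  row <- pedigree$pairs[list(pid, rid), on = c("proband_id", "relative_id"),
                        nomatch = NULL]
  if (!nrow(row))
    stop_fgrs("fgrs_key_error",
              "pair (%s, %s) is not within degree %d", proband_id, relative_id,
              pedigree$max_degree)
  list(pair_class = row$pair_class[1], reared_together = row$reared_together[1])
}

#' Export the relative-pair list as a TSV (debugging aid)
#'
#' @param pedigree an `fgrs_pedigree`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_relatives <- function(pedigree, path) {
  stopifnot(inherits(pedigree, "fgrs_pedigree"))
  fwrite(pedigree$pairs, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' @export
print.fgrs_pedigree <- function(x, ...) {
  cat(sprintf("<fgrs_pedigree> %d persons, %d relative pairs within degree %d\n",
              nrow(x$persons), nrow(x$pairs) / 2L, x$max_degree))
  invisible(x)
}
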