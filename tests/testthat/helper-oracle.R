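# Independent oracles: recursive-kinship relative enumeration, a
# direct-formula FGRS re-implementation, a loop-free random pedigree
# generator, and high-precision normal-distribution quantities. These share
# no code with the package internals they are used to check.

# Random pedigree without loops: grows from one founder couple by either
# adding a child to an existing couple or marrying an existing person to a
# brand-new founder (so no two persons are ever connected by more than one
# genealogical path). Second marriages create half-siblings; each couple has
# its own household.
rand_tree_pedigree <- function(n, seed, p_affected = 0.3, trait = "MD") {
  set.seed(seed)
  ids <- character(0)
  sexes <- character(0); bys <- integer(0)
  fas <- character(0); mos <- character(0)
  lwf <- logical(0); hh <- character(0)
  add_person <- function(sex, by, fa = NA_character_, mo = NA_character_,
                         lw = TRUE, house = NA_character_) {
    id <- sprintf("I%03d", length(ids) + 1L)
    ids <<- c(ids, id); sexes <<- c(sexes, sex); bys <<- c(bys, by)
    fas <<- c(fas, fa); mos <<- c(mos, mo); lwf <<- c(lwf, lw)
    hh <<- c(hh, house)
    id
  }
  f0 <- add_person("male", 1934L); m0 <- add_person("female", 1936L)
  couples <- data.frame(f = f0, m = m0, hh = "HH1",
                        lw = TRUE, stringsAsFactors = FALSE)
  nhh <- 1L
  while (length(ids) < n) {
    if (runif(1) < 0.62 || length(ids) < 3) {
      ci <- sample.int(nrow(couples), 1)
      byp <- max(bys[match(c(couples$f[ci], couples$m[ci]), ids)])
      add_person(sample(c("male", "female"), 1),
                 min(byp + sample(20:30, 1), 1992L),
                 fa = couples$f[ci], mo = couples$m[ci],
                 lw = couples$lw[ci], house = couples$hh[ci])
    } else {
      pi <- sample.int(length(ids), 1)
      if (bys[pi] > 1970L) next
      spouse_sex <- if (sexes[pi] == "male") "female" else "male"
      sp <- add_person(spouse_sex, bys[pi] + sample(-3:3, 1))
      nhh <- nhh + 1L
      newc <- data.frame(f = if (sexes[pi] == "male") ids[pi] else sp,
                         m = if (sexes[pi] == "male") sp else ids[pi],
                         hh = sprintf("HH%d", nhh),
                         lw = runif(1) < 0.8, stringsAsFactors = FALSE)
      couples <- rbind(couples, newc)
    }
  }
  censor <- pmax(2017L - bys, 1)
  affected <- runif(length(ids)) < p_affected
  persons <- data.frame(person_id = ids, sex = sexes, birth_year = bys,
                        father_id = fas, mother_id = mos, censor_age = censor,
                        lived_with_father = lwf, household_id = hh,
                        stringsAsFactors = FALSE)
  diagnoses <- if (any(affected))
    data.frame(person_id = ids[affected], trait = trait,
               age_at_first_registration = pmin(censor[affected], 28),
               stringsAsFactors = FALSE)
  as_cohort(persons, diagnoses)
}

# Recursive kinship coefficient phi(a, b) with memoisation; the classical
# recursion on the later-born lineage member. 2*phi is the coefficient of
# relationship; on loop-free pedigrees -log2(2*phi) is the degree.
oracle_kinship <- function(persons) {
  fa <- stats::setNames(persons$father_id, persons$person_id)
  mo <- stats::setNames(persons$mother_id, persons$person_id)
  depth_memo <- new.env(parent = emptyenv())
  dep <- function(x) {
    if (is.na(x)) return(-1L)
    if (!is.null(depth_memo[[x]])) return(depth_memo[[x]])
    d <- max(dep(fa[[x]]), dep(mo[[x]])) + 1L
    depth_memo[[x]] <- d
    d
  }
  phi_memo <- new.env(parent = emptyenv())
  phi <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    key <- paste(sort(c(a, b)), collapse = "|")
    if (!is.null(phi_memo[[key]])) return(phi_memo[[key]])
    val <- if (a == b) {
      0.5 * (1 + phi(fa[[a]], mo[[a]]))
    } else {
      if (dep(a) < dep(b)) { tmp <- a; a <- b; b <- tmp }
      0.5 * (phi(fa[[a]], b) + phi(mo[[a]], b))
    }
    phi_memo[[key]] <- val
    val
  }
  phi
}

oracle_relatives <- function(persons, proband, max_degree = 5) {
  phi <- oracle_kinship(persons)
  others <- setdiff(persons$person_id, proband)
  out <- lapply(others, function(b) {
    r2 <- 2 * phi(proband, b)
    if (r2 <= 0) return(NULL)
    d <- -log2(r2)
    stopifnot(abs(d - round(d)) < 1e-9)  # loop-free pedigrees only
    if (round(d) > max_degree) return(NULL)
    data.frame(relative_id = b, degree = as.integer(round(d)))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(relative_id = character(),
                                      degree = integer())
  out[order(out$relative_id, method = "radix"), , drop = FALSE]
}

oracle_pair_class <- function(persons, a, b) {
  fa <- stats::setNames(persons$father_id, persons$person_id)
  mo <- stats::setNames(persons$mother_id, persons$person_id)
  hh <- stats::setNames(persons$household_id, persons$person_id)
  lw <- stats::setNames(persons$lived_with_father, persons$person_id)
  is_par <- function(p, c) (!is.na(fa[[c]]) && fa[[c]] == p) ||
    (!is.na(mo[[c]]) && mo[[c]] == p)
  share <- function(pa, pb) !is.na(pa) && !is.na(pb) && pa == pb
  if (is_par(a, b) || is_par(b, a)) {
    cls <- "parent_offspring"
    rt <- TRUE
    if (!is.na(fa[[b]]) && fa[[b]] == a) rt <- lw[[b]]
    if (!is.na(fa[[a]]) && fa[[a]] == b) rt <- lw[[a]]
  } else if (share(fa[[a]], fa[[b]]) && share(mo[[a]], mo[[b]])) {
    cls <- "full_sibling"
    rt <- share(hh[[a]], hh[[b]])
  } else if (xor(share(fa[[a]], fa[[b]]), share(mo[[a]], mo[[b]]))) {
    cls <- "half_sibling"
    rt <- share(hh[[a]], hh[[b]])
  } else {
    cls <- "other"
    rt <- TRUE
  }
  list(pair_class = cls, reared_together = rt)
}

# Direct-formula FGRS: per-proband loops over oracle-enumerated relatives,
# explicit sums in sorted order, the textbook variance decomposition and
# reliability ratio written out once more. No data.table machinery.
oracle_fgrs <- function(cohort, trait, K, c_po, c_sib, shrink = NULL,
                        max_degree = 5) {
  persons <- as.data.frame(cohort$persons)
  aff <- cohort$diagnoses$person_id[cohort$diagnoses$trait == trait]
  # same threshold expression as the package (the closed forms themselves are
  # checked against quadrature oracles separately); the aggregation is what
  # this oracle re-derives
  Tthr <- qnorm(K, lower.tail = FALSE)
  za <- dnorm(Tthr) / K
  zu <- -dnorm(Tthr) / (1 - K)
  ids <- sort(persons$person_id, method = "radix")
  q <- ne <- effn <- numeric(length(ids))
  zs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rel <- oracle_relatives(persons, ids[i], max_degree)
    if (!nrow(rel)) { q[i] <- 0; ne[i] <- 0; effn[i] <- 0; next }
    z <- ifelse(rel$relative_id %in% aff, za, zu)
    cls <- vapply(rel$relative_id, function(b)
      oracle_pair_class(persons, ids[i], b)$pair_class, character(1))
    z[cls == "parent_offspring"] <- z[cls == "parent_offspring"] * c_po
    z[cls == "full_sibling"] <- z[cls == "full_sibling"] * c_sib
    w <- 0.5^rel$degree
    q[i] <- sum(w * z) / sum(w)
    ne[i] <- sum(w)
    effn[i] <- sum(w)^2 / sum(w^2)
    zs[[i]] <- z
  }
  allz <- unlist(zs)
  if (is.null(shrink)) {
    vw <- if (length(allz) >= 2) var(allz) else 0
    use <- ne > 0
    vb <- max(0, var(q[use]) - mean(vw / effn[use]))
  } else {
    vw <- shrink$var_within
    vb <- shrink$var_between
  }
  s <- if (vw == 0) as.numeric(effn > 0) else
    ifelse(effn > 0, vb / (vb + vw / effn), 0)
  data.frame(person_id = ids, quotient = q, n_eff = ne, shrinkage = s,
             fgrs_raw = q * s, stringsAsFactors = FALSE)
}

# High-precision liability quantities: threshold by root finding on the
# normal CDF, truncated means by quadrature.
oracle_liability <- function(K) {
  Tthr <- uniroot(function(x) pnorm(x) - (1 - K), c(-40, 40),
                  tol = 1e-14)$root
  za <- integrate(function(x) x * dnorm(x), Tthr, Inf,
                  rel.tol = 1e-13, abs.tol = 1e-14)$value / K
  zu <- integrate(function(x) x * dnorm(x), -Inf, Tthr,
                  rel.tol = 1e-13, abs.tol = 1e-14)$value / (1 - K)
  list(T = Tthr, z_affected = za, z_unaffected = zu)
}

# P(X > a, Y > b) for standard bivariate normal with correlation r.
bvn_upper <- function(a, b, r) {
  stopifnot(abs(r) < 1)
  integrate(function(x)
    dnorm(x) * pnorm((b - r * x) / sqrt(1 - r^2), lower.tail = FALSE),
    a, Inf, rel.tol = 1e-11)$value
}
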