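## Marker power indices and trio parentage assignment: PIC, exclusion
## probabilities, probability of identity, LOD scoring, two-round exclusion +
## likelihood assignment, and hybrid classification.

.check_freqs <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("allele frequencies must be non-negative and sum to 1")
  p
}

#' Polymorphic information content
#'
#' Botstein's PIC for a codominant locus:
#' \deqn{PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2}
#' Strictly below the expected heterozygosity for any polymorphic locus.
#'
#' @param freqs numeric vector of allele frequencies (sums to 1).
#' @return PIC in `[0, 1]`.
#' @export
pic <- function(freqs) {
  p <- .check_freqs(freqs)
  s2 <- sum(p^2); s4 <- sum(p^4)
  # sum_{i<j} 2 p_i^2 p_j^2 == (sum p^2)^2 - sum p^4
  1 - s2 - (s2^2 - s4)
}

#' Probability of identity
#'
#' Probability that two random individuals share a genotype at the locus:
#' \deqn{I = \sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2}
#' Multilocus identity is the product over loci ([combined_identity()]).
#'
#' @inheritParams pic
#' @return I in `(0, 1]`.
#' @export
probability_of_identity <- function(freqs) {
  p <- .check_freqs(freqs)
  s2 <- sum(p^2); s4 <- sum(p^4)
  s4 + 4 * (s2^2 - s4) / 2
}

#' Combined multilocus probability of identity
#' @param freq_list list of allele-frequency vectors, one per locus.
#' @return product of per-locus identities.
#' @export
combined_identity <- function(freq_list) {
  prod(vapply(freq_list, probability_of_identity, numeric(1)))
}

#' Parentage exclusion probability
#'
#' Probability that a random non-parent is excluded at the locus, under
#' Hardy-Weinberg genotype proportions and Mendelian transmission, in three
#' configurations:
#' \describe{
#'   \item{P1}{first parent: a candidate single parent tested against the
#'     offspring alone (no other parent known).}
#'   \item{P2}{second parent: one true parent known; a candidate is tested for
#'     the remaining parental slot.}
#'   \item{PP}{parent pair: a candidate mother-father pair tested jointly.}
#' }
#' Computed by exact summation over offspring (and known-parent) genotype
#' distributions; equivalent to the Jamieson-Taylor closed forms.
#' `Q(PP) >= Q(P2) >= Q(P1)` always. Combine over loci with
#' [combined_exclusion()] (multiplicative on non-exclusion).
#'
#' @inheritParams pic
#' @param variant `"P1"`, `"P2"` or `"PP"`.
#' @return exclusion probability in `[0, 1)`.
#' @export
exclusion_probability <- function(freqs, variant = c("P2", "P1", "PP")) {
  variant <- match.arg(variant)
  p <- .check_freqs(freqs)
  A <- length(p)
  if (A < 2) return(0)
  carry <- 1 - (1 - p)^2          # P(random individual carries allele a)
  switch(variant,
    P1 = {
      # offspring HW genotype G; exclusion iff candidate shares no allele of G
      e <- sum(p^2 * (1 - p)^2)
      for (a in seq_len(A - 1)) for (b in (a + 1):A)
        e <- e + 2 * p[a] * p[b] * max(1 - p[a] - p[b], 0)^2
      e
    },
    P2 = {
      # known mother M (HW) transmits allele m; true father contributes a
      # random population allele f. A candidate father is compatible iff he
      # carries an offspring allele d whose complement (the other offspring
      # allele) is transmissible by M; d = f always qualifies, and d = m also
      # qualifies when the mother herself carries f.
      e <- 0
      for (x in seq_len(A)) for (y in x:A) {
        pM <- if (x == y) p[x]^2 else 2 * p[x] * p[y]
        mal <- if (x == y) x else c(x, y)
        wm <- if (x == y) 1 else c(0.5, 0.5)
        for (mi in seq_along(mal)) {
          m <- mal[mi]
          for (f in seq_len(A)) {
            D <- f
            if (m != f && f %in% c(x, y)) D <- c(D, m)
            pnc <- max(1 - sum(p[D]), 0)^2   # candidate carries none of D
            e <- e + pM * wm[mi] * p[f] * pnc
          }
        }
      }
      e
    },
    PP = {
      e <- sum(p^2 * (1 - carry^2))
      for (a in seq_len(A - 1)) for (b in (a + 1):A)
        e <- e + 2 * p[a] * p[b] *
          (1 - (2 * carry[a] * carry[b] - (2 * p[a] * p[b])^2))
      e
    })
}

#' Combined multilocus exclusion probability
#' @param freq_list list of allele-frequency vectors, one per locus.
#' @param variant passed to [exclusion_probability()].
#' @return 1 - prod(1 - Q_locus).
#' @export
combined_exclusion <- function(freq_list, variant = "P2") {
  1 - prod(1 - vapply(freq_list, exclusion_probability, numeric(1),
                      variant = variant))
}

#' Marker power summary for a panel
#'
#' @param table a [genotype_table()].
#' @param group population label(s) over which frequencies are computed
#'   (`NULL` pools all).
#' @return data.frame with one row per locus (`PIC`, `Q_P1`, `Q_P2`, `Q_PP`,
#'   `I`) plus a `combined` attribute with the multilocus quantities.
#' @export
marker_power <- function(table, group = NULL) {
  fr <- allele_freqs(table, group)
  rows <- data.frame(
    locus = names(fr),
    PIC = vapply(fr, pic, numeric(1)),
    Q_P1 = vapply(fr, exclusion_probability, numeric(1), variant = "P1"),
    Q_P2 = vapply(fr, exclusion_probability, numeric(1), variant = "P2"),
    Q_PP = vapply(fr, exclusion_probability, numeric(1), variant = "PP"),
    I = vapply(fr, probability_of_identity, numeric(1)),
    row.names = NULL)
  attr(rows, "combined") <- c(
    Q_P1 = combined_exclusion(fr, "P1"),
    Q_P2 = combined_exclusion(fr, "P2"),
    Q_PP = combined_exclusion(fr, "PP"),
    I = combined_identity(fr))
  rows
}

## ---- Trio likelihood --------------------------------------------------------

# Mendelian transmission probability of unordered offspring genotype (oa, ob)
# from parents (ma, mb) x (fa, fb)
.mendel_prob <- function(oa, ob, ma, mb, fa, fb) {
  pm <- c(ma, mb); pf <- c(fa, fb)
  tot <- 0
  for (x in pm) for (y in pf) {
    g <- sort(c(x, y))
    if (g[1] == oa && g[2] == ob) tot <- tot + 0.25
  }
  tot
}

# HW probability of unordered genotype (a, b) under freqs (named vector)
.hw_prob <- function(a, b, freqs) {
  pa <- unname(freqs[as.character(a)]); pb <- unname(freqs[as.character(b)])
  if (is.na(pa)) pa <- 0
  if (is.na(pb)) pb <- 0
  if (a == b) pa * pb else 2 * pa * pb
}

#' Trio LOD score
#'
#' Log-likelihood ratio that a mother-father pair produced the offspring,
#' against the offspring being a random draw from the population:
#' per locus \eqn{L = (1-e)\,T(o\mid m,f) + e\,P_{HW}(o)} over
#' \eqn{P_{HW}(o)}, summed as logs over scored loci. `e` is a per-locus
#' genotype-replacement error rate (Marshall-style). Mismatches are counted as
#' the scored loci where the trio is Mendelian-incompatible (`T = 0`), i.e.
#' at error rate zero; with `error_rate = 0` an incompatible trio has
#' `lod = -Inf`.
#'
#' @param table a [genotype_table()] containing the three individuals.
#' @param offspring,mother,father individual ids.
#' @param freqs allele frequency list as from [allele_freqs()] (the reference
#'   population for the denominator).
#' @param error_rate genotype-replacement error rate in `[0, 1)`; default 0.02.
#' @param loci loci to score; defaults to all non-null-flagged loci.
#' @return list with `lod`, `mismatches`, and per-locus log-ratios
#'   `per_locus`.
#' @export
trio_lod <- function(table, offspring, mother, father, freqs,
                     error_rate = 0.02, loci = NULL) {
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (is.null(loci)) loci <- table$loci[!table$flagged_null]
  io <- match(offspring, table$ids); im <- match(mother, table$ids)
  ifa <- match(father, table$ids)
  if (anyNA(c(io, im, ifa))) stop("unknown individual id")
  per <- stats::setNames(numeric(length(loci)), loci)
  mism <- 0L
  for (l in loci) {
    j <- match(l, table$loci)
    oa <- table$a1[io, j]; ob <- table$a2[io, j]
    ma <- table$a1[im, j]; mb <- table$a2[im, j]
    fa <- table$a1[ifa, j]; fb <- table$a2[ifa, j]
    if (anyNA(c(oa, ma, fa))) { per[l] <- 0; next }   # unscored at missing
    tmend <- .mendel_prob(oa, ob, ma, mb, fa, fb)
    phw <- .hw_prob(oa, ob, freqs[[l]])
    if (tmend == 0) mism <- mism + 1L
    num <- (1 - error_rate) * tmend + error_rate * phw
    per[l] <- if (num == 0 || phw == 0) -Inf else log(num / phw)
  }
  list(lod = sum(per), mismatches = mism, per_locus = per)
}

## ---- Assignment engine ------------------------------------------------------

# joint Mendelian compatibility of a trio at one locus, given carry flags:
# pair compatible iff mother can supply one offspring allele and father the
# other (in either order)
.pair_compat <- function(m_has_a, m_has_b, f_has_a, f_has_b) {
  (m_has_a & f_has_b) | (m_has_b & f_has_a)
}

# per-offspring candidate screen: for each adult and scored locus, does the
# adult carry either offspring allele (single-parent compatibility)?
.single_parent_mismatches <- function(table, io, cand_idx, loci_idx) {
  out <- integer(length(cand_idx))
  for (j in loci_idx) {
    oa <- table$a1[io, j]; ob <- table$a2[io, j]
    if (is.na(oa)) next
    ca1 <- table$a1[cand_idx, j]; ca2 <- table$a2[cand_idx, j]
    has <- (ca1 == oa | ca2 == oa | ca1 == ob | ca2 == ob)
    has[is.na(has)] <- TRUE       # missing adult call never counts as mismatch
    out <- out + !has
  }
  out
}

#' Trio parentage assignment with hybrid classification
#'
#' Two-round closed-system assignment. Round 1: for each offspring, all
#' mother x father trios are screened by Mendelian exclusion; the
#' highest-LOD trio with zero mismatches at the scoring loci is accepted, with
#' LOD ties left ambiguous (never broken arbitrarily). Round 2 rescores only
#' the offspring unresolved in round 1, allowing up to `max_mismatch`
#' (default 2) mismatching loci; LOD ties in round 2 are first re-examined at
#' the null-flagged loci (the only analyses those loci participate in) and
#' remain ambiguous if still tied. Candidate mothers are the registry's
#' females and candidate fathers its nesting and sneaker males.
#'
#' @param table a [genotype_table()] holding offspring and all candidate
#'   parents (closed system: every putative breeder genotyped).
#' @param registry a [breeder_registry()] for the adults.
#' @param offspring_ids ids to assign; defaults to individuals with
#'   `pop == "offspring"`.
#' @param freqs reference allele frequencies for LOD denominators; defaults to
#'   frequencies over the adults.
#' @param error_rate LOD error model rate (default 0.02).
#' @param max_mismatch mismatch budget of the rescue round (default 2).
#' @param consistency_check when `TRUE`, also run an exclusion-only engine
#'   (unique zero-mismatch pair, no LOD ranking) and report disagreements in
#'   the `consistent` column.
#' @return data.frame of class `pedigree_assignment`: columns `offspring_id`,
#'   `mother_id`, `father_id`, `lod`, `mismatches`, `round`, `origin_class`
#'   (`south`/`west`/`hybrid`/`unresolved`), and optionally `consistent`.
#' @export
assign_parentage <- function(table, registry, offspring_ids = NULL,
                             freqs = NULL, error_rate = 0.02,
                             max_mismatch = 2L, consistency_check = FALSE) {
  if (is.null(offspring_ids)) offspring_ids <- table$ids[table$pop == "offspring"]
  adults <- registry[registry$origin %in% c("south", "west"), , drop = FALSE]
  mothers <- adults$id[adults$tactic == "female"]
  fathers <- adults$id[adults$tactic %in% c("nesting_male", "sneaker_male")]
  mothers <- intersect(mothers, table$ids)
  fathers <- intersect(fathers, table$ids)
  if (is.null(freqs))
    freqs <- allele_freqs(subset_genotypes(table, ids = c(mothers, fathers)))
  score_j <- which(!table$flagged_null)
  null_j <- which(table$flagged_null)
  im_all <- match(mothers, table$ids)
  if_all <- match(fathers, table$ids)

  # per-locus carry flags computed lazily per offspring
  one_offspring <- function(off_id, budget) {
    io <- match(off_id, table$ids)
    mm_m <- .single_parent_mismatches(table, io, im_all, score_j)
    mm_f <- .single_parent_mismatches(table, io, if_all, score_j)
    cm <- which(mm_m <= budget); cf <- which(mm_f <= budget)
    if (!length(cm) || !length(cf))
      return(list(status = "none"))
    # joint mismatch counts over candidate pairs
    pairs_mm <- matrix(0L, length(cm), length(cf))
    for (j in score_j) {
      oa <- table$a1[io, j]; ob <- table$a2[io, j]
      if (is.na(oa)) next
      mi <- im_all[cm]; fi <- if_all[cf]
      mA <- table$a1[mi, j] == oa | table$a2[mi, j] == oa
      mB <- table$a1[mi, j] == ob | table$a2[mi, j] == ob
      fA <- table$a1[fi, j] == oa | table$a2[fi, j] == oa
      fB <- table$a1[fi, j] == ob | table$a2[fi, j] == ob
      mA[is.na(mA)] <- TRUE; mB[is.na(mB)] <- TRUE
      fA[is.na(fA)] <- TRUE; fB[is.na(fB)] <- TRUE
      compat <- outer(mA, fB, "&") | outer(mB, fA, "&")
      pairs_mm <- pairs_mm + !compat
    }
    ok <- which(pairs_mm <= budget, arr.ind = TRUE)
    if (!nrow(ok)) return(list(status = "none"))
    cand <- data.frame(mother = mothers[cm[ok[, 1]]],
                       father = fathers[cf[ok[, 2]]],
                       mism = pairs_mm[ok], lod = NA_real_)
    for (r in seq_len(nrow(cand))) {
      cand$lod[r] <- trio_lod(table, off_id, cand$mother[r], cand$father[r],
                              freqs, error_rate = error_rate,
                              loci = table$loci[score_j])$lod
    }
    best <- max(cand$lod)
    top <- which(cand$lod >= best - 1e-9)
    if (length(top) > 1L) {
      # tie-break on null-flagged loci (rescue round only)
      if (budget > 0 && length(null_j)) {
        tl <- vapply(top, function(r)
          trio_lod(table, off_id, cand$mother[r], cand$father[r], freqs,
                   error_rate = error_rate,
                   loci = table$loci[null_j])$lod, numeric(1))
        keep <- which(tl >= max(tl) - 1e-9)
        if (length(keep) == 1L) top <- top[keep]
      }
      if (length(top) > 1L) return(list(status = "ambiguous", n_tied = length(top)))
    }
    list(status = "assigned", mother = cand$mother[top], father = cand$father[top],
         lod = cand$lod[top], mism = cand$mism[top])
  }

  res <- data.frame(offspring_id = offspring_ids, mother_id = NA_character_,
                    father_id = NA_character_, lod = NA_real_,
                    mismatches = NA_integer_, round = NA_integer_,
                    origin_class = "unresolved", stringsAsFactors = FALSE)
  for (i in seq_along(offspring_ids)) {
    r1 <- one_offspring(offspring_ids[i], 0L)
    hit <- if (r1$status == "assigned") c(r1, round = 1L) else {
      r2 <- one_offspring(offspring_ids[i], as.integer(max_mismatch))
      if (r2$status == "assigned") c(r2, round = 2L) else NULL
    }
    if (!is.null(hit)) {
      res$mother_id[i] <- hit$mother
      res$father_id[i] <- hit$father
      res$lod[i] <- hit$lod
      res$mismatches[i] <- hit$mism
      res$round[i] <- hit$round
    }
  }
  res$origin_class <- classify_origin(res, registry)
  if (consistency_check) {
    res$consistent <- NA
    for (i in seq_along(offspring_ids)) {
      r1 <- one_offspring(offspring_ids[i], 0L)
      excl_only <- if (r1$status == "assigned") c(r1$mother, r1$father) else NULL
      lod_pick <- if (!is.na(res$mother_id[i]) && res$round[i] == 1L)
        c(res$mother_id[i], res$father_id[i]) else NULL
      res$consistent[i] <- identical(excl_only, lod_pick) ||
        (is.null(excl_only) && is.na(res$mother_id[i]))
    }
  }
  class(res) <- c("pedigree_assignment", "data.frame")
  res
}

#' Classify offspring origin from assigned parents
#'
#' `south` when both parents are of south origin, `west` when both are west,
#' `hybrid` when they differ, `unresolved` when either parent is unassigned.
#'
#' @param assignments data.frame with `mother_id`, `father_id` columns.
#' @param registry a [breeder_registry()].
#' @return character vector of origin classes.
#' @export
classify_origin <- function(assignments, registry) {
  om <- registry$origin[match(assignments$mother_id, registry$id)]
  of <- registry$origin[match(assignments$father_id, registry$id)]
  ifelse(is.na(om) | is.na(of), "unresolved",
         ifelse(om == of, om, "hybrid"))
}

#' Cumulative parentage-assignment success by marker ranking
#'
#' Ranks loci by descending second-parent exclusion probability Q(P2), then
#' for each panel prefix of size k simulates offspring from random
#' Hardy-Weinberg parents drawn out of a simulated closed breeder pool and
#' reports the fraction of offspring for which the true pair is the unique
#' fully Mendelian-compatible pair using the top-k loci. The curve is
#' monotone non-decreasing in k up to Monte-Carlo error.
#'
#' @param freqs allele frequency list (one vector per locus).
#' @param n_offspring simulated offspring per panel size (study setting:
#'   1,000).
#' @param n_mothers,n_fathers size of the simulated candidate pools.
#' @param seed RNG seed.
#' @return data.frame with `k`, `locus` (added at rank k) and `success`.
#' @export
simulate_assignment_success <- function(freqs, n_offspring = 1000L,
                                        n_mothers = 162L, n_fathers = 156L,
                                        seed = 1L) {
  stopifnot(n_offspring >= 1)
  q2 <- vapply(freqs, exclusion_probability, numeric(1), variant = "P2")
  ord <- order(q2, decreasing = TRUE)
  L <- length(freqs)
  set.seed(seed)
  draw_geno <- function(p, n) {
    al <- as.integer(names(p))
    cbind(sample(al, n, TRUE, p), sample(al, n, TRUE, p))
  }
  M <- lapply(freqs[ord], draw_geno, n = n_mothers)
  F_ <- lapply(freqs[ord], draw_geno, n = n_fathers)
  tm <- sample.int(n_mothers, n_offspring, TRUE)
  tf <- sample.int(n_fathers, n_offspring, TRUE)
  O <- lapply(seq_len(L), function(j) {
    a <- ifelse(stats::runif(n_offspring) < 0.5, M[[j]][tm, 1], M[[j]][tm, 2])
    b <- ifelse(stats::runif(n_offspring) < 0.5, F_[[j]][tf, 1], F_[[j]][tf, 2])
    cbind(a, b)
  })
  success <- numeric(L)
  for (k in seq_len(L)) {
    hit <- logical(n_offspring)
    for (i in seq_len(n_offspring)) {
      sm <- rep(TRUE, n_mothers); sf <- rep(TRUE, n_fathers)
      for (j in seq_len(k)) {      # single-parent screen
        oa <- O[[j]][i, 1]; ob <- O[[j]][i, 2]
        sm <- sm & (M[[j]][, 1] == oa | M[[j]][, 2] == oa |
                      M[[j]][, 1] == ob | M[[j]][, 2] == ob)
        sf <- sf & (F_[[j]][, 1] == oa | F_[[j]][, 2] == oa |
                      F_[[j]][, 1] == ob | F_[[j]][, 2] == ob)
      }
      im <- which(sm); fi <- which(sf)
      if (!length(im) || !length(fi)) next
      compat <- matrix(TRUE, length(im), length(fi))
      for (j in seq_len(k)) {
        oa <- O[[j]][i, 1]; ob <- O[[j]][i, 2]
        mA <- M[[j]][im, 1] == oa | M[[j]][im, 2] == oa
        mB <- M[[j]][im, 1] == ob | M[[j]][im, 2] == ob
        fA <- F_[[j]][fi, 1] == oa | F_[[j]][fi, 2] == oa
        fB <- F_[[j]][fi, 1] == ob | F_[[j]][fi, 2] == ob
        compat <- compat & (outer(mA, fB, "&") | outer(mB, fA, "&"))
        if (!any(compat)) break
      }
      w <- which(compat, arr.ind = TRUE)
      hit[i] <- nrow(w) == 1L && im[w[1, 1]] == tm[i] && fi[w[1, 2]] == tf[i]
    }
    success[k] <- mean(hit)
  }
  data.frame(k = seq_len(L), locus = names(freqs)[ord], success = success)
}
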