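## Diversity and differentiation statistics: allele frequencies, Nei-Chesser
## heterozygosities, rarefied allelic richness, Weir-Cockerham F-statistics,
## Markov-chain exact tests, null-allele frequency and FDR control.

#' Per-locus allele frequencies
#'
#' @param table a [genotype_table()].
#' @param group optional character vector of population labels; `NULL` pools
#'   all individuals.
#' @return named list, one element per locus: a named numeric vector of allele
#'   frequencies over non-missing calls (sums to 1), or `NULL` for a locus
#'   with no non-missing calls in the group.
#' @export
allele_freqs <- function(table, group = NULL) {
  sub <- if (is.null(group)) table else subset_genotypes(table, pop = group)
  if (!length(sub$ids)) stop("allele_freqs: empty group")
  out <- lapply(seq_along(sub$loci), function(j) {
    al <- c(sub$a1[, j], sub$a2[, j])
    al <- al[!is.na(al)]
    if (!length(al)) return(NULL)
    tab <- base::table(al)
    stats::setNames(as.numeric(tab) / length(al), names(tab))
  })
  names(out) <- sub$loci
  out
}

# per-locus count of individuals with non-missing calls
.n_typed <- function(table, group = NULL) {
  sub <- if (is.null(group)) table else subset_genotypes(table, pop = group)
  colSums(!is.na(sub$a1))
}

#' Observed and expected heterozygosity (Nei & Chesser)
#'
#' Observed heterozygosity is the fraction of heterozygous individuals among
#' non-missing calls. Expected heterozygosity is the small-sample-unbiased
#' gene diversity of Nei and Chesser (1983), which corrects both for the
#' sampling of individuals and for the observed heterozygote fraction:
#' \deqn{\hat H_E = \frac{n}{n-1}\Big(1 - \sum_i \hat p_i^2 - \frac{H_O}{2n}\Big)}
#' with n the number of typed individuals.
#'
#' @inheritParams allele_freqs
#' @return data.frame with columns `locus`, `n`, `Ho`, `He` (NA when n < 2)
#'   and an attribute `means` holding the across-locus means over non-flagged
#'   loci.
#' @export
observed_expected_het <- function(table, group = NULL) {
  sub <- if (is.null(group)) table else subset_genotypes(table, pop = group)
  res <- lapply(seq_along(sub$loci), function(j) {
    ok <- !is.na(sub$a1[, j])
    n <- sum(ok)
    if (n < 2) return(data.frame(locus = sub$loci[j], n = n,
                                 Ho = NA_real_, He = NA_real_))
    ho <- mean(sub$a1[ok, j] != sub$a2[ok, j])
    p <- base::table(c(sub$a1[ok, j], sub$a2[ok, j])) / (2 * n)
    he <- n / (n - 1) * (1 - sum(p^2) - ho / (2 * n))
    data.frame(locus = sub$loci[j], n = n, Ho = ho, He = he)
  })
  out <- do.call(rbind, res)
  keep <- !sub$flagged_null & !is.na(out$Ho)
  attr(out, "means") <- c(Ho = mean(out$Ho[keep]), He = mean(out$He[keep]))
  out
}

#' Rarefied allelic richness
#'
#' Expected number of alleles in a standardized subsample of `g` gene copies,
#' by hypergeometric rarefaction:
#' \deqn{A_r = \sum_a \Big[1 - \binom{2N - N_a}{g} \Big/ \binom{2N}{g}\Big]}
#' where \eqn{N_a} is the observed copy count of allele a. `g` defaults to
#' twice the smallest per-locus typed sample size across the listed groups
#' (rarefaction to the minimum sample, the FSTAT convention).
#'
#' @param table a [genotype_table()].
#' @param group population label(s) to summarise.
#' @param g standardized number of gene copies; must not exceed the number of
#'   copies available at any locus in the group.
#' @param groups_for_min groups used to determine the default `g`; defaults to
#'   all populations in the table.
#' @return named numeric vector of Ar per locus.
#' @export
allelic_richness <- function(table, group, g = NULL, groups_for_min = NULL) {
  if (is.null(g)) {
    gl <- if (is.null(groups_for_min)) unique(table$pop) else groups_for_min
    nmin <- min(vapply(gl, function(p) min(.n_typed(table, p)), numeric(1)))
    g <- 2L * nmin
  }
  sub <- subset_genotypes(table, pop = group)
  vapply(seq_along(sub$loci), function(j) {
    al <- c(sub$a1[, j], sub$a2[, j]); al <- al[!is.na(al)]
    n2 <- length(al)
    if (g > n2) stop("allelic_richness: g = ", g, " exceeds ", n2,
                     " available copies at locus ", sub$loci[j])
    counts <- base::table(al)
    # 1 - C(2N - Na, g)/C(2N, g), in log space for numerical safety
    sum(1 - exp(lchoose(n2 - counts, g) - lchoose(n2, g)))
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(sub$loci)
}

#' Total gene diversity over pooled samples
#'
#' Expected heterozygosity (Nei-Chesser) computed on the pooled individuals of
#' the listed groups; the "H_T in the total material" column of a diversity
#' table.
#'
#' @param table a [genotype_table()].
#' @param groups population labels to pool; `NULL` pools everything.
#' @return data.frame as [observed_expected_het()] (He column is H_T).
#' @export
total_gene_diversity <- function(table, groups = NULL) {
  observed_expected_het(table, group = groups)
}

## ---- Weir-Cockerham variance components ------------------------------------

# Per-locus, per-allele variance components a (among populations),
# b (among individuals within populations), c (within individuals) of
# Weir & Cockerham (1984). Populations given as list of groups.
.wc_components <- function(table, groups) {
  subs <- lapply(groups, function(g) subset_genotypes(table, pop = g))
  r <- length(subs)
  out <- vector("list", length(table$loci))
  names(out) <- table$loci
  for (j in seq_along(table$loci)) {
    ni <- vapply(subs, function(s) sum(!is.na(s$a1[, j])), numeric(1))
    if (any(ni < 1)) { out[[j]] <- NULL; next }
    alleles <- sort(unique(unlist(lapply(subs, function(s)
      c(s$a1[, j], s$a2[, j])))))
    alleles <- alleles[!is.na(alleles)]
    nbar <- mean(ni)
    nc <- if (r > 1) (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1) else nbar
    comp <- matrix(NA_real_, nrow = length(alleles), ncol = 3,
                   dimnames = list(alleles, c("a", "b", "c")))
    for (k in seq_along(alleles)) {
      al <- alleles[k]
      pi <- vapply(subs, function(s) {
        ok <- !is.na(s$a1[, j])
        mean(c(s$a1[ok, j], s$a2[ok, j]) == al)
      }, numeric(1))
      hi <- vapply(subs, function(s) {
        ok <- !is.na(s$a1[, j])
        mean((s$a1[ok, j] == al) != (s$a2[ok, j] == al))
      }, numeric(1))
      pbar <- sum(ni * pi) / (r * nbar)
      hbar <- sum(ni * hi) / (r * nbar)
      s2 <- if (r > 1) sum(ni * (pi - pbar)^2) / ((r - 1) * nbar) else 0
      if (r > 1) {
        a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                    hbar / 4) / (nbar - 1))
        b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                      (2 * nbar - 1) / (4 * nbar) * hbar)
      } else {
        a <- 0
        b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
                                      (2 * nbar - 1) / (4 * nbar) * hbar)
      }
      comp[k, ] <- c(a, b, hbar / 2)
    }
    out[[j]] <- comp
  }
  out
}

#' Weir-Cockerham inbreeding coefficient F_IS
#'
#' Small-f of Weir & Cockerham (1984) from the b and c variance components of
#' a single sample: per locus f = 1 - sum(c)/sum(b + c) over alleles, and the
#' multilocus value by the same ratio with components summed over loci
#' (ratio of sums, never a mean of per-locus ratios). Monomorphic and
#' null-flagged loci are excluded from the multilocus sums.
#'
#' @inheritParams allele_freqs
#' @return list with `per_locus` (named numeric, NA where undefined) and
#'   `multilocus`.
#' @export
fis_weir_cockerham <- function(table, group = NULL) {
  grp <- if (is.null(group)) unique(table$pop) else group
  comp <- .wc_components(table, list(grp))
  per <- vapply(comp, function(m) {
    if (is.null(m)) return(NA_real_)
    bc <- sum(m[, "b"] + m[, "c"])
    if (bc <= 0) return(NA_real_)   # monomorphic
    1 - sum(m[, "c"]) / bc
  }, numeric(1))
  use <- !table$flagged_null & !is.na(per)
  num <- 0; den <- 0
  for (j in which(use)) {
    num <- num + sum(comp[[j]][, "c"])
    den <- den + sum(comp[[j]][, "b"] + comp[[j]][, "c"])
  }
  list(per_locus = per, multilocus = if (den > 0) 1 - num / den else NA_real_)
}

#' Weir-Cockerham F_ST (theta)
#'
#' The theta estimator of Weir & Cockerham (1984): per locus
#' theta = sum(a)/sum(a + b + c) over alleles; multilocus by the ratio of
#' sums over loci. Slightly negative estimates are legitimate. Loci
#' monomorphic for the same allele in all groups contribute 0/0 and are
#' skipped; null-flagged loci are excluded from the multilocus ratio.
#' An exact G-based test of differentiation can be attached via
#' [ld_exact_test()]-style permutation with `n_perm` genotype permutations of
#' individuals across groups.
#'
#' @param table a [genotype_table()].
#' @param groupA,groupB population labels of the two samples (either may be a
#'   vector of labels to pool). For more than two samples use `groups` as a
#'   list of label vectors.
#' @param groups optional list of groups overriding `groupA`/`groupB`.
#' @param n_perm number of permutations for the differentiation test
#'   (0 = no test, p_value NA).
#' @param seed RNG seed for the permutation test.
#' @return list with `theta` (multilocus), `per_locus_theta` (named numeric),
#'   and `p_value`.
#' @export
fst_weir_cockerham <- function(table, groupA = NULL, groupB = NULL,
                               groups = NULL, n_perm = 0, seed = 1L) {
  if (is.null(groups)) groups <- list(groupA, groupB)
  comp <- .wc_components(table, groups)
  per <- vapply(comp, function(m) {
    if (is.null(m)) return(NA_real_)
    tot <- sum(m)
    if (tot == 0) return(NA_real_)
    sum(m[, "a"]) / tot
  }, numeric(1))
  theta_from <- function(cmp) {
    num <- 0; den <- 0
    for (j in seq_along(cmp)) {
      if (is.null(cmp[[j]]) || table$flagged_null[j]) next
      if (sum(cmp[[j]]) == 0) next
      num <- num + sum(cmp[[j]][, "a"])
      den <- den + sum(cmp[[j]])
    }
    if (den == 0) NA_real_ else num / den
  }
  theta <- theta_from(comp)
  pval <- NA_real_
  if (n_perm > 0) {
    sub <- subset_genotypes(table, pop = unlist(groups))
    glab <- rep(NA_integer_, length(sub$ids))
    for (k in seq_along(groups)) glab[sub$pop %in% groups[[k]]] <- k
    obs <- theta
    set.seed(seed)
    ge <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample(glab)
      tabp <- sub
      tabp$pop <- as.character(perm)
      cmp <- .wc_components(tabp, as.list(as.character(seq_along(groups))))
      if (!is.na(t2 <- theta_from(cmp)) && t2 >= obs) ge <- ge + 1L
    }
    pval <- (ge + 1) / (n_perm + 1)
  }
  list(theta = theta, per_locus_theta = per, p_value = pval)
}

## ---- Markov-chain exact tests -----------------------------------------------

#' Markov-chain test configuration
#'
#' Controls the Hardy-Weinberg and linkage-disequilibrium Monte-Carlo tests.
#' Defaults follow the GENEPOP settings used in the motivating study
#' (100,000 dememorization steps, 1,000 batches, 50,000 iterations per batch);
#' exploratory runs and test suites use much shorter chains. For the
#' permutation-based LD test, `batches` is the number of Monte-Carlo
#' permutations; `dememorization` and `iterations_per_batch` apply to the
#' Hardy-Weinberg chain only.
#'
#' @param dememorization burn-in steps of the chain.
#' @param batches number of batches (HW) / permutations (LD).
#' @param iterations_per_batch chain steps per batch (HW).
#' @param seed integer RNG seed.
#' @return a list of class `mc_config`.
#' @export
mc_config <- function(dememorization = 100000L, batches = 1000L,
                      iterations_per_batch = 50000L, seed = 1L) {
  stopifnot(dememorization > 0, batches > 0, iterations_per_batch > 0)
  structure(list(dememorization = as.integer(dememorization),
                 batches = as.integer(batches),
                 iterations_per_batch = as.integer(iterations_per_batch),
                 seed = as.integer(seed)), class = "mc_config")
}

# log conditional probability (up to a constant) of a genotype array given
# allele counts: log(2^H) - sum(log n_gt!) where H = # heterozygotes.
.hw_log_prob <- function(gt_counts, het_mask) {
  sum(gt_counts[het_mask]) * log(2) - sum(lfactorial(gt_counts))
}

#' Hardy-Weinberg exact test by Markov chain
#'
#' Estimates the exact conditional probability test (Guo & Thompson 1992):
#' the p-value is the probability, over all genotype arrays with the observed
#' allele counts, of arrays no more probable than the observed one. The chain
#' swaps single allele copies between two random individuals, which leaves the
#' uniform distribution over allele arrangements (hence the Levene conditional
#' distribution over arrays) invariant.
#'
#' @param table a [genotype_table()].
#' @param group population label(s).
#' @param locus locus name.
#' @param cfg an [mc_config()].
#' @return list with `p_value`, `se` (batch standard error), `flag`
#'   (`"ok"` or `"monomorphic"`).
#' @export
hw_exact_test <- function(table, group, locus, cfg = mc_config()) {
  sub <- subset_genotypes(table, pop = group, loci = locus)
  ok <- !is.na(sub$a1[, 1])
  g1 <- sub$a1[ok, 1]; g2 <- sub$a2[ok, 1]
  alleles <- sort(unique(c(g1, g2)))
  if (length(alleles) < 2)
    return(list(p_value = 1, se = 0, flag = "monomorphic"))
  n <- length(g1)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  logprob <- function(a, b) {
    k <- key(a, b)
    cnt <- base::table(k)
    het <- vapply(strsplit(names(cnt), " "), function(x) x[1] != x[2], logical(1))
    sum(cnt[het]) * log(2) - sum(lfactorial(cnt))
  }
  obs_lp <- logprob(g1, g2)
  set.seed(cfg$seed)
  a <- g1; b <- g2
  lp <- obs_lp
  step <- function() {
    i <- sample.int(n, 2L)       # two distinct individuals
    si <- sample(c(1L, 2L), 2L, replace = TRUE)
    a1i <- if (si[1] == 1L) a[i[1]] else b[i[1]]
    a2i <- if (si[2] == 1L) a[i[2]] else b[i[2]]
    if (a1i == a2i) return(FALSE)
    if (si[1] == 1L) a[i[1]] <<- a2i else b[i[1]] <<- a2i
    if (si[2] == 1L) a[i[2]] <<- a1i else b[i[2]] <<- a1i
    TRUE
  }
  recompute_every <- 1L   # incremental bookkeeping kept simple: full recompute
  run <- function(niter) {
    cnt_le <- 0L
    for (t in seq_len(niter)) {
      if (step()) lp <<- logprob(a, b)
      if (lp <= obs_lp + 1e-12) cnt_le <- cnt_le + 1L
    }
    cnt_le / niter
  }
  for (t in seq_len(cfg$dememorization)) if (step()) lp <- logprob(a, b)
  batch_p <- vapply(seq_len(cfg$batches), function(bi)
    run(cfg$iterations_per_batch), numeric(1))
  list(p_value = mean(batch_p),
       se = stats::sd(batch_p) / sqrt(cfg$batches),
       flag = "ok")
}

# genotypic G statistic between two loci's genotype classes
.g_stat <- function(ga, gb) {
  tab <- base::table(ga, gb)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  nz <- tab > 0
  2 * sum(tab[nz] * log(tab[nz] / e[nz]))
}

#' Genotypic linkage-disequilibrium test
#'
#' Monte-Carlo log-likelihood-ratio (G) test on the genotype-by-genotype
#' contingency table of two loci: one locus's genotypes are permuted among
#' individuals and the G statistics compared. p = (1 + #(G* >= G_obs)) /
#' (n_perm + 1), with `n_perm = cfg$batches`.
#'
#' @inheritParams hw_exact_test
#' @param locusA,locusB locus names.
#' @return list with `p_value`, `g_obs`, `flag` (`"ok"` or `"monomorphic"`).
#' @export
ld_exact_test <- function(table, group, locusA, locusB, cfg = mc_config()) {
  sub <- subset_genotypes(table, pop = group, loci = c(locusA, locusB))
  ok <- !is.na(sub$a1[, 1]) & !is.na(sub$a1[, 2])
  ga <- paste(sub$a1[ok, 1], sub$a2[ok, 1])
  gb <- paste(sub$a1[ok, 2], sub$a2[ok, 2])
  if (length(unique(ga)) < 2 || length(unique(gb)) < 2)
    return(list(p_value = 1, g_obs = 0, flag = "monomorphic"))
  g_obs <- .g_stat(ga, gb)
  set.seed(cfg$seed)
  n_perm <- cfg$batches
  ge <- 0L
  for (b in seq_len(n_perm))
    if (.g_stat(ga, sample(gb)) >= g_obs - 1e-12) ge <- ge + 1L
  list(p_value = (ge + 1) / (n_perm + 1), g_obs = g_obs, flag = "ok")
}

#' Null allele frequency (heterozygote-deficit estimator)
#'
#' Chakraborty-type moment estimator fn = (He - Ho) / (He + Ho) from the
#' apparent heterozygote deficit; negative values are legitimate (heterozygote
#' excess) and match the sign behaviour of the published marker panel.
#'
#' @inheritParams hw_exact_test
#' @param locus locus name.
#' @return list with `fn` and `flag` (`"ok"` or `"undefined"`).
#' @export
null_allele_freq <- function(table, group, locus) {
  het <- observed_expected_het(subset_genotypes(table, loci = locus), group)
  ho <- het$Ho[1]; he <- het$He[1]
  if (is.na(ho) || (he + ho) == 0)
    return(list(fn = NA_real_, flag = "undefined"))
  list(fn = (he - ho) / (he + ho), flag = "ok")
}

#' False discovery rate adjustment
#'
#' Step-up FDR control: Benjamini-Hochberg (`"bh"`) or Benjamini-Yekutieli
#' (`"by"`, with the harmonic-sum inflation for arbitrary dependence, the
#' convention for pairwise test tables). Wraps [stats::p.adjust()].
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param method `"bh"` or `"by"`.
#' @param alpha rejection level.
#' @return data.frame with `p`, `p_adj`, `reject` in the input order.
#' @export
fdr_adjust <- function(pvalues, method = c("bh", "by"), alpha = 0.05) {
  method <- match.arg(method)
  if (!length(pvalues))
    return(data.frame(p = numeric(), p_adj = numeric(), reject = logical()))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = toupper(method))
  data.frame(p = pvalues, p_adj = adj, reject = !is.na(adj) & adj <= alpha)
}

#' Per-locus diversity summary table
#'
#' The marker-panel summary in the layout of a classic microsatellite
#' diversity table: observed allele count, rarefied allelic richness,
#' observed/expected heterozygosity, Weir-Cockerham F_IS, and the null-allele
#' frequency, per group.
#'
#' @param table a [genotype_table()].
#' @param group population label(s) to summarise.
#' @param g rarefaction size (gene copies); see [allelic_richness()].
#' @return data.frame with one row per locus: columns
#'   `locus, n, A, Ar, Ho, He, Fis, fn`.
#' @export
locus_summary <- function(table, group, g = NULL) {
  sub <- subset_genotypes(table, pop = group)
  het <- observed_expected_het(table, group)
  ar <- allelic_richness(table, group, g = g)
  fis <- fis_weir_cockerham(table, group)
  fn <- vapply(table$loci, function(l)
    null_allele_freq(table, group, l)$fn, numeric(1))
  A <- vapply(seq_along(sub$loci), function(j)
    length(unique(c(sub$a1[, j], sub$a2[, j])[!is.na(c(sub$a1[, j], sub$a2[, j]))])),
    numeric(1))
  data.frame(locus = table$loci, n = het$n, A = A, Ar = as.numeric(ar),
             Ho = het$Ho, He = het$He, Fis = as.numeric(fis$per_locus),
             fn = as.numeric(fn), row.names = NULL)
}
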