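# Fixture builders shared across the suite. Everything is generated in code;
# no stored data files.

# random valid genotype table: n individuals split over pops, L loci
random_table <- function(n = 10, L = 3, pops = c("south", "west"),
                         alleles = 4, miss_rate = 0, seed = 1) {
  set.seed(seed)
  loci <- sprintf("T%02d", seq_len(L))
  a1 <- matrix(sample(100 + seq_len(alleles), n * L, TRUE), n, L)
  a2 <- matrix(sample(100 + seq_len(alleles), n * L, TRUE), n, L)
  if (miss_rate > 0) {
    m <- matrix(runif(n * L) < miss_rate, n, L)
    a1[m] <- NA; a2[m] <- NA
  }
  genotype_table(sprintf("I%03d", seq_len(n)),
                 rep_len(pops, n), loci, a1, a2)
}

# tiny trio world: two parents + offspring with prescribed genotypes at one
# locus each row of `geno` = c(off1, off2, mo1, mo2, fa1, fa2)
trio_table <- function(geno, extra_adults = NULL) {
  L <- nrow(geno)
  loci <- sprintf("T%02d", seq_len(L))
  ids <- c("off", "mom", "dad", rownames(extra_adults))
  a1 <- rbind(geno[, c(1, 3, 5), drop = FALSE] |> t(),
              if (!is.null(extra_adults)) extra_adults[, seq_len(L) * 2 - 1,
                                                       drop = FALSE])
  a2 <- rbind(geno[, c(2, 4, 6), drop = FALSE] |> t(),
              if (!is.null(extra_adults)) extra_adults[, seq_len(L) * 2,
                                                       drop = FALSE])
  genotype_table(ids, c("offspring", "south", "south",
                        rep("south", NROW(extra_adults))), loci, a1, a2)
}

# registry for a set of ids with given origins/tactics and unit sizes
quick_registry <- function(ids, origin, tactic, length_cm = 13, weight_g = 30) {
  breeder_registry(ids, origin, tactic,
                   ifelse(origin == "offspring", NA, length_cm),
                   ifelse(origin == "offspring", NA, weight_g),
                   tag = NA_character_)
}

# small simulation config that runs fast
small_cfg <- function(seed = 1, ...) {
  sim_config(n_loci = 8,
             n_south = c(nesting_male = 12, sneaker_male = 3, female = 15),
             n_west = c(nesting_male = 12, sneaker_male = 5, female = 16),
             n_offspring_sampled = 80, seed = seed, ...)
}

# reduced Markov-chain settings for fast tests
fast_mc <- function(seed = 1) mc_config(dememorization = 1000, batches = 100,
                                        iterations_per_batch = 500,
                                        seed = seed)

# Exact Hardy-Weinberg conditional p-value for a biallelic sample by full
# enumeration of the Levene distribution over heterozygote counts.
hw_exact_enumerate <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) +
      lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp)
  obs <- p[match(nAB, hets)]
  sum(p[p <= obs + 1e-12])
}
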