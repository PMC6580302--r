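## Generative model of the whole mesocosm experiment: two divergent source
## populations, adult phenotypes, pair-level mating governed by the logistic
## and Poisson fitness models, Mendelian transmission with genotyping error
## and a null-allele-bearing locus, and a known truth pedigree.

#' Simulation configuration
#'
#' Defaults mirror the motivating mesocosm study: 151 south + 167 west adults
#' (64/9/76 and 59/24/86 nesting males/sneakers/females), 11 microsatellite
#' loci with a multilocus differentiation target of F_ST = 0.094, one
#' null-allele-bearing locus (frequency 0.073), the published logistic and
#' Poisson mating coefficients, a 2% genotyping error rate, and 651 sampled
#' offspring. Size distributions are truncated normals with the published
#' per-origin, per-tactic means, SDs and ranges.
#'
#' @param n_loci number of loci.
#' @param alleles_per_locus integer range (min, max) of visible allele counts
#'   drawn per locus.
#' @param ancestral_freq_concentration symmetric Dirichlet concentration for
#'   ancestral allele frequencies.
#' @param target_fst Balding-Nichols divergence parameter in (0, 1).
#' @param n_south,n_west named integer vectors
#'   `c(nesting_male=, sneaker_male=, female=)`.
#' @param beta,gamma length-7 coefficient vectors of the success (logit) and
#'   count (log) models, order: intercept, male origin, female origin, same
#'   origin, male size, female size, sneaker.
#' @param covariate_mode size covariate used generatively: `"length"` or
#'   `"weight_length_ratio"`.
#' @param genotyping_error_rate per-individual-per-locus replacement error for
#'   recorded offspring genotypes.
#' @param null_allele_rate ancestral frequency of the hidden null allele at
#'   the flagged locus (0 disables).
#' @param n_null_loci number of null-allele-bearing loci (0 or 1 typical).
#' @param n_offspring_sampled offspring drawn (without replacement) from the
#'   total production, emulating edge-net sampling of an unknown total.
#' @param phenotypes list of per-origin, per-tactic size distributions; each
#'   entry `c(mean, sd, lo, hi)` for length (cm) and weight (g).
#' @param seed master RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 11L,
                       alleles_per_locus = c(5L, 30L),
                       ancestral_freq_concentration = 1,
                       target_fst = 0.094,
                       n_south = c(nesting_male = 64L, sneaker_male = 9L,
                                   female = 76L),
                       n_west = c(nesting_male = 59L, sneaker_male = 24L,
                                  female = 86L),
                       beta = c(-5.361, 1.133, 1.083, -0.167, -0.026, -0.029,
                                0.372),
                       gamma = c(-2.620, 0.270, 0.599, 0.009, 0.180, 0.055,
                                 -0.753),
                       covariate_mode = "length",
                       genotyping_error_rate = 0.02,
                       null_allele_rate = 0.073,
                       n_null_loci = 1L,
                       n_offspring_sampled = 651L,
                       phenotypes = NULL,
                       seed = 1L) {
  if (target_fst <= 0 || target_fst >= 1) stop("target_fst must be in (0, 1)")
  stopifnot(length(beta) == 7, length(gamma) == 7,
            genotyping_error_rate >= 0, genotyping_error_rate <= 1,
            null_allele_rate >= 0, null_allele_rate <= 1,
            all(n_south > 0), all(n_west > 0), n_offspring_sampled >= 1)
  if (is.null(phenotypes)) phenotypes <- list(
    south = list(
      nesting_male = list(len = c(14.0, 2.6, 10.5, 20.5),
                          wt = c(39.8, 22.6, 16.2, 108)),
      sneaker_male = list(len = c(11.8, 0.3, 11.5, 12.5),
                          wt = c(21.1, 2.6, 18.2, 27)),
      female = list(len = c(14.4, 2.4, 10.5, 20.0),
                    wt = c(44.5, 22.0, 14.6, 103.8))),
    west = list(
      nesting_male = list(len = c(12.8, 1.3, 10.5, 17.0),
                          wt = c(30.1, 8.6, 16.4, 59.3)),
      sneaker_male = list(len = c(12.3, 0.9, 10.5, 14.5),
                          wt = c(25.7, 5.0, 17.1, 37.2)),
      female = list(len = c(12.9, 1.3, 10.5, 19.5),
                    wt = c(30.0, 11.2, 16.5, 101.7))),
    offspring = list(
      immature = list(len = c(1.7, 0.5, 0.4, 3.5),
                      wt = c(0.1, 0.1, 0.01, 0.8))))
  structure(list(n_loci = as.integer(n_loci),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 ancestral_freq_concentration = ancestral_freq_concentration,
                 target_fst = target_fst, n_south = n_south, n_west = n_west,
                 beta = beta, gamma = gamma, covariate_mode = covariate_mode,
                 genotyping_error_rate = genotyping_error_rate,
                 null_allele_rate = null_allele_rate,
                 n_null_loci = as.integer(n_null_loci),
                 n_offspring_sampled = as.integer(n_offspring_sampled),
                 phenotypes = phenotypes, seed = as.integer(seed)),
            class = "sim_config")
}

.NULL_ALLELE <- 999L  # hidden allele code: never written to observed calls

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Draw divergent population allele frequencies
#'
#' Balding-Nichols construction: ancestral frequencies from a symmetric
#' Dirichlet, then each population's frequencies drawn from
#' Dirichlet(p_anc (1 - F)/F) with F the divergence parameter, giving an
#' expected Weir-Cockerham theta near F between the two populations. Hidden
#' null alleles (code 999) are placed in the ancestral pool of the flagged
#' loci so both populations share them.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed (default `cfg$seed`).
#' @return list with `south`, `west` (allele-frequency lists keyed by locus),
#'   `loci` (names), `flagged_null` (logical).
#' @export
draw_population_freqs <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  loci <- sprintf("L%02d", seq_len(cfg$n_loci))
  flagged <- seq_len(cfg$n_loci) <= cfg$n_null_loci
  F <- cfg$target_fst
  south <- list(); west <- list()
  for (j in seq_len(cfg$n_loci)) {
    K <- sample(seq(cfg$alleles_per_locus[1], cfg$alleles_per_locus[2]), 1L)
    codes <- 100L + seq_len(K)
    p_anc <- .rdirichlet(rep(cfg$ancestral_freq_concentration, K))
    if (flagged[j] && cfg$null_allele_rate > 0) {
      p_anc <- c(p_anc * (1 - cfg$null_allele_rate), cfg$null_allele_rate)
      codes <- c(codes, .NULL_ALLELE)
    }
    draw_pop <- function() {
      p <- .rdirichlet(p_anc * (1 - F) / F)
      stats::setNames(p, codes)
    }
    south[[j]] <- draw_pop(); west[[j]] <- draw_pop()
  }
  names(south) <- names(west) <- loci
  structure(list(south = south, west = west, loci = loci,
                 flagged_null = flagged), seed = seed)
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# mask hidden null alleles in a true genotype pair -> observed pair
.mask_null <- function(a, b) {
  if (a == .NULL_ALLELE && b == .NULL_ALLELE) return(c(NA_integer_, NA_integer_))
  if (a == .NULL_ALLELE) return(c(b, b))
  if (b == .NULL_ALLELE) return(c(a, a))
  c(a, b)
}

#' Sample the adult breeding stock
#'
#' Draws each adult's true genotype by Hardy-Weinberg random union of gametes
#' within its origin, assigns tactic labels per the configured censuses, and
#' draws lengths and weights from the configured truncated normals. Null
#' alleles are masked in the observed table (heterozygote-with-null recorded
#' as visible-allele homozygote; null homozygote recorded as missing).
#'
#' @param cfg a [sim_config()].
#' @param freqs output of [draw_population_freqs()].
#' @param seed RNG seed (default `cfg$seed + 1`).
#' @return list with `registry` (a [breeder_registry()]), `table` (observed
#'   [genotype_table()]), and `true_a1`/`true_a2` (unmasked allele matrices
#'   used for transmission).
#' @export
sample_adults <- function(cfg, freqs, seed = cfg$seed + 1L) {
  set.seed(seed)
  plan <- rbind(
    data.frame(origin = "south", tactic = rep(names(cfg$n_south), cfg$n_south)),
    data.frame(origin = "west", tactic = rep(names(cfg$n_west), cfg$n_west)))
  n <- nrow(plan)
  ids <- sprintf("A%03d", seq_len(n))
  L <- cfg$n_loci
  t1 <- matrix(NA_integer_, n, L); t2 <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    for (org in c("south", "west")) {
      idx <- which(plan$origin == org)
      p <- freqs[[org]][[j]]
      al <- as.integer(names(p))
      t1[idx, j] <- sample(al, length(idx), TRUE, p)
      t2[idx, j] <- sample(al, length(idx), TRUE, p)
    }
  }
  o1 <- t1; o2 <- t2
  for (j in which(freqs$flagged_null)) {
    for (i in seq_len(n)) {
      m <- .mask_null(t1[i, j], t2[i, j])
      o1[i, j] <- m[1]; o2[i, j] <- m[2]
    }
  }
  len <- numeric(n); wt <- numeric(n)
  for (org in c("south", "west")) for (tc in names(cfg$phenotypes[[org]])) {
    idx <- which(plan$origin == org & plan$tactic == tc)
    ph <- cfg$phenotypes[[org]][[tc]]
    len[idx] <- .rtruncnorm(length(idx), ph$len[1], ph$len[2], ph$len[3],
                            ph$len[4])
    wt[idx] <- .rtruncnorm(length(idx), ph$wt[1], ph$wt[2], ph$wt[3],
                           ph$wt[4])
  }
  registry <- breeder_registry(ids, plan$origin, plan$tactic,
                               round(len, 1), round(wt, 1),
                               tag = ifelse(plan$origin == "south", "pink",
                                            "yellow"))
  tab <- genotype_table(ids, plan$origin, freqs$loci, o1, o2,
                        flagged_null = freqs$flagged_null)
  structure(list(registry = registry, table = tab, true_a1 = t1, true_a2 = t2),
            seed = seed)
}

# zero-truncated Poisson draws
.rztpois <- function(n, lambda) {
  stats::qpois(stats::runif(n, stats::ppois(0, lambda), 1), lambda)
}

#' Simulate natural mating in the mesocosm
#'
#' For every male x female pair, success is Bernoulli with probability from
#' the logistic model (cfg coefficients beta); successful pairs draw an
#' offspring count from a zero-truncated Poisson whose mean comes from the
#' count model (gamma) — truncation keeps the "success iff at least one
#' offspring" invariant consistent. Offspring origin class follows parental
#' origins.
#'
#' @param cfg a [sim_config()].
#' @param registry adult [breeder_registry()].
#' @param seed RNG seed (default `cfg$seed + 2`).
#' @return `truth_pedigree` data.frame: `offspring_id`, `mother_id`,
#'   `father_id`, `origin_class`; one row per produced offspring (before
#'   sampling).
#' @export
simulate_mating <- function(cfg, registry, seed = cfg$seed + 2L) {
  if (length(cfg$beta) != 7 || length(cfg$gamma) != 7)
    stop("coefficient vectors must have length 7")
  set.seed(seed)
  males <- registry[registry$tactic %in% c("nesting_male", "sneaker_male"), ]
  females <- registry[registry$tactic == "female", ]
  if (!nrow(males) || !nrow(females))
    stop("registry must contain both sexes")
  covar <- function(df) switch(cfg$covariate_mode,
    length = df$total_length_cm,
    weight_length_ratio = df$body_weight_g / df$total_length_cm)
  grid <- expand.grid(m = seq_len(nrow(males)), f = seq_len(nrow(females)))
  O_i <- as.integer(males$origin[grid$m] == "west")
  O_j <- as.integer(females$origin[grid$f] == "west")
  O_ij <- as.integer(O_i == O_j)
  L_i <- covar(males)[grid$m]; L_j <- covar(females)[grid$f]
  S_i <- as.integer(males$tactic[grid$m] == "sneaker_male")
  X <- cbind(1, O_i, O_j, O_ij, L_i, L_j, S_i)
  p <- stats::plogis(as.numeric(X %*% cfg$beta))
  success <- stats::runif(nrow(grid)) < p
  if (!any(success))
    return(structure(data.frame(offspring_id = character(),
                                mother_id = character(),
                                father_id = character(),
                                origin_class = character()),
                     seed = seed, class = c("truth_pedigree", "data.frame")))
  lam <- exp(as.numeric(X[success, , drop = FALSE] %*% cfg$gamma))
  counts <- .rztpois(sum(success), lam)
  mid <- females$id[grid$f[success]]
  fid <- males$id[grid$m[success]]
  mo <- females$origin[grid$f[success]]
  fo <- males$origin[grid$m[success]]
  ped <- data.frame(
    offspring_id = sprintf("O%05d", seq_len(sum(counts))),
    mother_id = rep(mid, counts), father_id = rep(fid, counts),
    origin_class = rep(ifelse(mo == fo, mo, "hybrid"), counts),
    stringsAsFactors = FALSE)
  structure(ped, seed = seed, class = c("truth_pedigree", "data.frame"))
}

#' Transmit genotypes to offspring
#'
#' One random allele per parent per locus (Mendelian segregation from the
#' TRUE parental genotypes, null alleles included). With probability
#' `genotyping_error_rate` per offspring-locus the recorded genotype is
#' replaced by a random Hardy-Weinberg draw from the pooled adult
#' frequencies; at flagged loci hidden null alleles are masked as for adults.
#'
#' @param cfg a [sim_config()].
#' @param pedigree a `truth_pedigree`.
#' @param adults output of [sample_adults()].
#' @param freqs output of [draw_population_freqs()].
#' @param seed RNG seed (default `cfg$seed + 3`).
#' @return observed offspring [genotype_table()] (pop label `"offspring"`).
#' @export
transmit_genotypes <- function(cfg, pedigree, adults, freqs,
                               seed = cfg$seed + 3L) {
  set.seed(seed)
  n <- nrow(pedigree)
  L <- cfg$n_loci
  im <- match(pedigree$mother_id, adults$table$ids)
  ifa <- match(pedigree$father_id, adults$table$ids)
  if (anyNA(c(im, ifa))) stop("pedigree parents missing from adult table")
  o1 <- matrix(NA_integer_, n, L); o2 <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    ma <- ifelse(stats::runif(n) < 0.5, adults$true_a1[im, j],
                 adults$true_a2[im, j])
    fa <- ifelse(stats::runif(n) < 0.5, adults$true_a1[ifa, j],
                 adults$true_a2[ifa, j])
    # genotyping error: replace the recorded genotype with a random HW draw
    # from the pooled (south + west mean) population frequencies
    err <- stats::runif(n) < cfg$genotyping_error_rate
    if (any(err)) {
      p <- (freqs$south[[j]] + freqs$west[[j]]) / 2
      al <- as.integer(names(p))
      ma[err] <- sample(al, sum(err), TRUE, p)
      fa[err] <- sample(al, sum(err), TRUE, p)
    }
    if (freqs$flagged_null[j]) {
      for (i in seq_len(n)) {
        m <- .mask_null(ma[i], fa[i])
        o1[i, j] <- m[1]; o2[i, j] <- m[2]
      }
    } else {
      o1[, j] <- ma; o2[, j] <- fa
    }
  }
  structure(genotype_table(pedigree$offspring_id,
                           rep("offspring", n), freqs$loci, o1, o2,
                           flagged_null = freqs$flagged_null),
            seed = seed)
}

#' Run the full synthetic mesocosm
#'
#' Chains frequency drawing, adult sampling, mating and transmission, then
#' samples `cfg$n_offspring_sampled` offspring uniformly without replacement
#' from the total production (all, if fewer were produced). All stage seeds
#' derive from `cfg$seed` and are recorded in the `seeds` element.
#'
#' @param cfg a [sim_config()].
#' @return list with `table` (adults + sampled offspring, observed calls),
#'   `registry` (adults + offspring phenotypes), `truth` (sampled-offspring
#'   truth pedigree), `truth_all` (full production), `freqs`, `cfg`, `seeds`.
#' @export
simulate_mesocosm <- function(cfg = sim_config()) {
  freqs <- draw_population_freqs(cfg)
  adults <- sample_adults(cfg, freqs)
  ped_all <- simulate_mating(cfg, adults$registry)
  if (!nrow(ped_all)) stop("simulate_mesocosm: no offspring produced")
  set.seed(cfg$seed + 4L)
  take <- sort(sample.int(nrow(ped_all),
                          min(cfg$n_offspring_sampled, nrow(ped_all))))
  ped <- ped_all[take, , drop = FALSE]
  off_tab <- transmit_genotypes(cfg, ped, adults, freqs)
  ph <- cfg$phenotypes$offspring$immature
  off_reg <- breeder_registry(
    ped$offspring_id, "offspring", "immature",
    round(.rtruncnorm(nrow(ped), ph$len[1], ph$len[2], ph$len[3], ph$len[4]), 1),
    round(.rtruncnorm(nrow(ped), ph$wt[1], ph$wt[2], ph$wt[3], ph$wt[4]), 2),
    tag = NA_character_)
  tab <- genotype_table(
    c(adults$table$ids, off_tab$ids),
    c(adults$table$pop, off_tab$pop),
    freqs$loci,
    rbind(adults$table$a1, off_tab$a1),
    rbind(adults$table$a2, off_tab$a2),
    flagged_null = freqs$flagged_null)
  registry <- rbind(adults$registry, off_reg)
  class(registry) <- c("breeder_registry", "data.frame")
  list(table = tab, registry = registry, truth = ped, truth_all = ped_all,
       freqs = freqs, cfg = cfg,
       seeds = c(freqs = cfg$seed, adults = cfg$seed + 1L,
                 mating = cfg$seed + 2L, transmission = cfg$seed + 3L,
                 sampling = cfg$seed + 4L))
}

#' Write a simulated mesocosm to disk
#'
#' Emits the GenePop genotypes, the phenotype TSV, the truth pedigree TSV and
#' a key:value config echo.
#'
#' @param sim output of [simulate_mesocosm()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mesocosm <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genepop(sim$table, file.path(dir, "genotypes.gen"))
  write_phenotypes(sim$registry, file.path(dir, "phenotypes.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth_pedigree.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfgl <- sim$cfg
  cfgl$phenotypes <- NULL
  keys <- vapply(cfgl, function(v) paste(v, collapse = ","), character(1))
  writeLines(paste0(names(keys), ": ", keys), file.path(dir, "config.txt"))
  invisible(dir)
}
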