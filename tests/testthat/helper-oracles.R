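# Independent brute-force oracles shared by the module and acceptance tests.

# all unordered genotypes and their HW probabilities for a frequency vector
hw_genotypes <- function(p) {
  A <- length(p)
  gts <- NULL; pr <- NULL
  for (i in seq_len(A)) for (j in i:A) {
    gts <- rbind(gts, c(i, j))
    pr <- c(pr, if (i == j) p[i]^2 else 2 * p[i] * p[j])
  }
  list(g = gts, p = pr)
}

shares_allele <- function(g, h) any(g %in% h)
pair_compatible <- function(off, mo, fa) {
  (off[1] %in% mo && off[2] %in% fa) || (off[2] %in% mo && off[1] %in% fa)
}

# brute-force exclusion probabilities by enumerating every genotype combo
exclusion_oracle <- function(p, variant) {
  H <- hw_genotypes(p)
  e <- 0
  for (m in seq_along(H$p)) for (f in seq_along(H$p)) {
    pmf <- H$p[m] * H$p[f]
    mo <- H$g[m, ]; fa <- H$g[f, ]
    for (gm in 1:2) for (gf in 1:2) {
      off <- sort(c(mo[gm], fa[gf]))
      pofs <- pmf * 0.25
      for (c1 in seq_along(H$p)) {
        cand <- H$g[c1, ]
        excl <- switch(variant,
          P1 = !shares_allele(off, cand),
          P2 = !pair_compatible(off, mo, cand),
          PP = NA)
        if (variant != "PP") {
          e <- e + pofs * H$p[c1] * excl
        } else {
          for (c2 in seq_along(H$p)) {
            excl <- !pair_compatible(off, H$g[c1, ], H$g[c2, ])
            e <- e + pofs * H$p[c1] * H$p[c2] * excl
          }
        }
      }
    }
  }
  e
}

# Independent textbook variance-component oracle (two populations, one locus,
# straight transcription of the 1984 component formulas, scalar arithmetic)
wc_oracle_two_pops <- function(g1a, g1b, g2a, g2b) {
  pops <- list(cbind(g1a, g1b), cbind(g2a, g2b))
  alleles <- sort(unique(c(g1a, g1b, g2a, g2b)))
  r <- 2
  ni <- sapply(pops, nrow)
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  A <- B <- C <- 0
  for (al in alleles) {
    pi <- sapply(pops, function(g) mean(c(g[, 1], g[, 2]) == al))
    hi <- sapply(pops, function(g) mean((g[, 1] == al) != (g[, 2] == al)))
    pbar <- sum(ni * pi) / sum(ni)
    hbar <- sum(ni * hi) / sum(ni)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    A <- A + a; B <- B + b; C <- C + hbar / 2
  }
  list(theta = A / (A + B + C), fis = 1 - C / (B + C))
}
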