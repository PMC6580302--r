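# Pair universe construction, the success/count regressions, closed-form
# predictions, and the assortative-mating contingency test.

# small synthetic pair world with a known pedigree
toy_world <- function(n_m = 6, n_f = 7, seed = 1) {
  set.seed(seed)
  reg <- quick_registry(
    c(sprintf("m%d", seq_len(n_m)), sprintf("f%d", seq_len(n_f))),
    sample(c("south", "west"), n_m + n_f, TRUE),
    c(rep(c("nesting_male", "sneaker_male"), length.out = n_m),
      rep("female", n_f)),
    length_cm = round(runif(n_m + n_f, 11, 18), 1),
    weight_g = round(runif(n_m + n_f, 18, 60), 1))
  asn <- data.frame(offspring_id = sprintf("o%d", 1:5),
                    mother_id = c("f1", "f1", "f2", "f3", "f3"),
                    father_id = c("m1", "m1", "m2", "m1", "m4"))
  list(reg = reg, asn = asn)
}

test_that("the pair universe enumerates every male x female combination once", {
  w <- toy_world()
  pt <- build_pair_table(w$asn, w$reg)
  expect_equal(nrow(pt), 6 * 7)
  expect_false(any(duplicated(paste(pt$male_id, pt$female_id))))
  # study-scale census: 156 males x 162 females -> 25,272 records
  reg <- quick_registry(
    sprintf("A%03d", 1:318),
    rep(c("south", "west"), c(151, 167)),
    c(rep(c("nesting_male", "sneaker_male", "female"), c(64, 9, 76)),
      rep(c("nesting_male", "sneaker_male", "female"), c(59, 24, 86))))
  big <- build_pair_table(data.frame(offspring_id = character(),
                                     mother_id = character(),
                                     father_id = character()), reg)
  expect_equal(nrow(big), 25272)
  expect_false(any(big$success))
  # offspring conservation and the success <-> N >= 1 invariant
  expect_equal(sum(pt$N_offspring), nrow(w$asn))
  expect_equal(pt$success, pt$N_offspring >= 1)
})

test_that("covariate modes populate sizes as configured", {
  w <- toy_world()
  pt_len <- build_pair_table(w$asn, w$reg, "length")
  pt_wl <- build_pair_table(w$asn, w$reg, "weight_length_ratio")
  m1 <- w$reg[w$reg$id == "m1", ]
  expect_equal(unique(pt_len$L_i[pt_len$male_id == "m1"]), m1$total_length_cm)
  expect_equal(unique(pt_wl$L_i[pt_wl$male_id == "m1"]),
               m1$body_weight_g / m1$total_length_cm)
})

# independent generic ML oracle: numerical maximisation of the written
# likelihoods over the 7 coefficients
optim_oracle <- function(records, family) {
  X <- cbind(1, records$O_i, records$O_j, records$O_ij, records$L_i,
             records$L_j, records$S_i)
  if (family == "binomial") {
    y <- as.numeric(records$success)
    nll <- function(b) { eta <- X %*% b; -sum(y * eta - log1p(exp(eta))) }
    grd <- function(b) { mu <- plogis(X %*% b); -as.numeric(t(X) %*% (y - mu)) }
  } else {
    y <- records$N_offspring
    nll <- function(b) { eta <- X %*% b; -sum(y * eta - exp(eta)) }
    grd <- function(b) { mu <- exp(X %*% b); -as.numeric(t(X) %*% (y - mu)) }
  }
  stats::optim(rep(0, 7), nll, grd, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))$par
}

test_that("logistic and Poisson fits agree with direct likelihood maximisation", {
  set.seed(10)
  n <- 200
  rec <- data.frame(O_i = rbinom(n, 1, 0.5), O_j = rbinom(n, 1, 0.5),
                    L_i = runif(n, 11, 16), L_j = runif(n, 11, 16),
                    S_i = rbinom(n, 1, 0.2))
  rec$O_ij <- as.integer(rec$O_i == rec$O_j)
  eta <- -1 + 0.8 * rec$O_i - 0.5 * rec$O_j + 0.1 * rec$L_i - 0.1 * rec$L_j
  rec$success <- runif(n) < plogis(eta)
  rec$N_offspring <- ifelse(rec$success, 1 + rpois(n, exp(0.3 + 0.3 * rec$O_j)),
                            0L)
  e1 <- fit_logistic_eq1(rec)
  expect_equal(unname(e1$coefficients), optim_oracle(rec, "binomial"),
               tolerance = 1e-5)
  e2 <- fit_poisson_eq2(rec)
  expect_equal(unname(e2$coefficients),
               optim_oracle(rec[rec$success, ], "poisson"), tolerance = 1e-5)
})

test_that("degenerate designs are rejected or flagged", {
  w <- toy_world()
  pt <- build_pair_table(data.frame(offspring_id = character(),
                                    mother_id = character(),
                                    father_id = character()), w$reg)
  expect_error(fit_logistic_eq1(pt), "both outcome classes")
  expect_error(fit_poisson_eq2(pt), "at least 8")
})

test_that("a null simulation keeps effect estimates near zero", {
  set.seed(77)
  n <- 4000
  rec <- data.frame(O_i = rbinom(n, 1, 0.5), O_j = rbinom(n, 1, 0.5),
                    L_i = runif(n, 11, 16), L_j = runif(n, 11, 16),
                    S_i = rbinom(n, 1, 0.2))
  rec$O_ij <- as.integer(rec$O_i == rec$O_j)
  rec$success <- runif(n) < 0.2
  rec$N_offspring <- as.integer(rec$success)
  fit <- fit_logistic_eq1(rec)
  z <- abs(fit$coefficients[-1]) / fit$se[-1]
  expect_true(all(z < 3))
})

test_that("doubling all counts shifts only the Poisson intercept by log 2", {
  set.seed(5)
  n <- 150
  rec <- data.frame(O_i = rbinom(n, 1, 0.5), O_j = rbinom(n, 1, 0.5),
                    L_i = runif(n, 11, 16), L_j = runif(n, 11, 16),
                    S_i = rbinom(n, 1, 0.2))
  rec$O_ij <- as.integer(rec$O_i == rec$O_j)
  rec$N_offspring <- 1L + rpois(n, 2)
  rec$success <- TRUE
  f1 <- fit_poisson_eq2(rec)
  rec2 <- rec; rec2$N_offspring <- 2L * rec$N_offspring
  f2 <- fit_poisson_eq2(rec2)
  expect_equal(unname(f2$coefficients[1] - f1$coefficients[1]), log(2),
               tolerance = 1e-6)
  expect_equal(unname(f2$coefficients[-1]), unname(f1$coefficients[-1]),
               tolerance = 1e-6)
})

test_that("closed-form predictions reproduce the published worked examples", {
  eq1 <- mating_fit(c(-5.361, 1.133, 1.083, -0.167, -0.026, -0.029, 0.372),
                    "logistic_eq1")
  expect_equal(round(predict_success_probability(eq1), 4), 0.0047)
  expect_equal(round(predict_success_probability(eq1, O_i = 1), 4), 0.0144)
  # the published both-west arithmetic adds the two origin effects only; its
  # printed result (0.0412) carries a last-digit rounding slip (exact
  # arithmetic on the printed coefficients gives 0.0413), so allow one unit
  # in the last printed digit
  expect_equal(predict_success_probability(eq1, O_i = 1, O_j = 1), 0.0412,
               tolerance = 1e-4 / 0.0412)
  eq2 <- mating_fit(c(-2.620, 0.270, 0.599, 0.009, 0.180, 0.055, -0.752),
                    "poisson_eq2")
  # the printed base value (1.52) also carries a last-digit slip: the printed
  # arithmetic evaluates to 1.5079 -> 1.51, so allow one unit in the last
  # printed digit plus the rounding half-unit
  base <- predict_offspring_count(eq2, L_i = 12.806, L_j = 13.194)
  expect_lt(abs(base - 1.52), 0.015)
  expect_equal(signif(predict_offspring_count(eq2, O_j = 1, L_i = 12.806,
                                              L_j = 13.194), 2), 2.7)
  expect_equal(round(predict_offspring_count(eq2, S_i = 1, L_i = 12.806,
                                             L_j = 13.194), 2), 0.71)
  # wrong model type is rejected
  expect_error(predict_success_probability(eq2), "logistic_eq1")
  expect_error(predict_offspring_count(eq1), "poisson_eq2")
})

test_that("the Yates-corrected contingency test matches hand computation", {
  # proportional table -> clamped statistic 0, p = 1
  reg <- quick_registry(
    c(sprintf("m%d", 1:40), sprintf("f%d", 1:40)),
    rep(rep(c("south", "west"), each = 20), 2),
    c(rep("nesting_male", 40), rep("female", 40)))
  mk_asn <- function(counts) {
    # counts = c(SS, SW, WS, WW) distinct pairs (male origin first)
    pairs <- rbind(
      if (counts[1]) cbind(sprintf("m%d", 1:counts[1]),
                           sprintf("f%d", 1:counts[1])),
      if (counts[2]) cbind(sprintf("m%d", 1:counts[2]),
                           sprintf("f%d", 20 + (1:counts[2]))),
      if (counts[3]) cbind(sprintf("m%d", 20 + (1:counts[3])),
                           sprintf("f%d", 1:counts[3])),
      if (counts[4]) cbind(sprintf("m%d", 20 + (1:counts[4])),
                           sprintf("f%d", 20 + (1:counts[4]))))
    data.frame(offspring_id = sprintf("o%d", seq_len(nrow(pairs))),
               mother_id = pairs[, 2], father_id = pairs[, 1])
  }
  r <- assortative_test(mk_asn(c(10, 10, 10, 10)), reg)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  # agreement with the standard corrected test on a generic table
  r2 <- assortative_test(mk_asn(c(12, 5, 8, 15)), reg)
  ct <- suppressWarnings(chisq.test(r2$table, correct = TRUE))
  expect_equal(r2$chi2, unname(ct$statistic), tolerance = 1e-10)
  expect_equal(r2$p, ct$p.value, tolerance = 1e-10)
})

test_that("the family-count table derived from the study's tallies gives chi2 ~ 0.54", {
  # distinct-pair counts by male x female origin: (south,south)=11,
  # (south,west)=43, (west,south)=50, (west,west)=139
  tab <- matrix(c(11, 43, 50, 139), 2, byrow = TRUE)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum(pmax(abs(tab - e) - 0.5, 0)^2 / e)
  expect_equal(round(chi2, 2), 0.54)
})
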