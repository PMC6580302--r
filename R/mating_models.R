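## Assortative-mating contingency test and the two reproductive-fitness
## regressions: a logistic model of pair success over the full male x female
## pair universe and a Poisson model of offspring counts over successful pairs.

#' Build the breeding-pair universe
#'
#' One record per male x female combination of the adult registry, with origin
#' indicators (1 = west, 0 = south), a same-origin indicator, the size
#' covariates of both parents, the sneaker indicator, and success / offspring
#' count taken from the pedigree. `success` is true exactly when
#' `N_offspring >= 1`.
#'
#' @param assignments a `pedigree_assignment` data.frame (resolved rows used).
#' @param registry a [breeder_registry()].
#' @param covariate_mode `"length"` (total length, cm; default) or
#'   `"weight_length_ratio"` (body weight / total length, g/cm).
#' @return data.frame with columns `male_id, female_id, O_i, O_j, O_ij,
#'   L_i, L_j, S_i, success, N_offspring`.
#' @export
build_pair_table <- function(assignments, registry,
                             covariate_mode = c("length",
                                                "weight_length_ratio")) {
  covariate_mode <- match.arg(covariate_mode)
  adults <- registry[registry$origin %in% c("south", "west"), , drop = FALSE]
  males <- adults[adults$tactic %in% c("nesting_male", "sneaker_male"), ]
  females <- adults[adults$tactic == "female", ]
  covar <- function(df) switch(covariate_mode,
    length = df$total_length_cm,
    weight_length_ratio = df$body_weight_g / df$total_length_cm)
  if (anyNA(covar(males)) || anyNA(covar(females)))
    stop("adults missing size covariate: ",
         paste(adults$id[is.na(covar(adults))], collapse = ", "))
  grid <- expand.grid(m = seq_len(nrow(males)), f = seq_len(nrow(females)))
  out <- data.frame(
    male_id = males$id[grid$m], female_id = females$id[grid$f],
    O_i = as.integer(males$origin[grid$m] == "west"),
    O_j = as.integer(females$origin[grid$f] == "west"),
    L_i = covar(males)[grid$m], L_j = covar(females)[grid$f],
    S_i = as.integer(males$tactic[grid$m] == "sneaker_male"),
    stringsAsFactors = FALSE)
  out$O_ij <- as.integer(out$O_i == out$O_j)
  res <- assignments[!is.na(assignments$mother_id) &
                       !is.na(assignments$father_id), , drop = FALSE]
  key <- paste(out$male_id, out$female_id)
  cnt <- base::table(paste(res$father_id, res$mother_id))
  out$N_offspring <- as.integer(cnt[key])
  out$N_offspring[is.na(out$N_offspring)] <- 0L
  out$success <- out$N_offspring >= 1L
  out[, c("male_id", "female_id", "O_i", "O_j", "O_ij", "L_i", "L_j", "S_i",
          "success", "N_offspring")]
}

.model_terms <- c("(Intercept)", "O_i", "O_j", "O_ij", "L_i", "L_j", "S_i")
.term_labels <- c("Intercept", "Male origin", "Female origin",
                  "Both parents of same origin", "Male size", "Female size",
                  "Sneaker male")

# extract name-aligned estimates from a glm; aliased (dropped) terms keep NA
.glm_mating_fit <- function(fit, model, n, converged) {
  co <- stats::coef(fit)
  sm <- summary(fit)$coefficients
  se <- pv <- rep(NA_real_, length(co))
  m <- match(rownames(sm), names(co))
  se[m] <- sm[, 2]; pv[m] <- sm[, 4]
  .as_mating_fit(model, unname(co), se, pv, converged, n)
}

# wrap a fitted glm (or raw coefficients) as a mating model fit
.as_mating_fit <- function(model, coefs, se, pvals, converged, n) {
  structure(list(model = model,
                 coefficients = stats::setNames(coefs, .model_terms),
                 se = stats::setNames(se, .model_terms),
                 p_values = stats::setNames(pvals, .model_terms),
                 converged = converged, n_records = n),
            class = "mating_model_fit")
}

#' Construct a mating model fit from known coefficients
#'
#' Packs a coefficient vector (intercept + 6 effects, in the order intercept,
#' male origin, female origin, same origin, male size, female size, sneaker)
#' into a `mating_model_fit`, e.g. to evaluate published estimates with
#' [predict_success_probability()] / [predict_offspring_count()].
#'
#' @param coefficients numeric vector of length 7.
#' @param model `"logistic_eq1"` or `"poisson_eq2"`.
#' @return a `mating_model_fit`.
#' @export
mating_fit <- function(coefficients, model = c("logistic_eq1", "poisson_eq2")) {
  model <- match.arg(model)
  if (length(coefficients) != 7)
    stop("coefficient vector must have length 7 (intercept + 6 effects)")
  .as_mating_fit(model, as.numeric(coefficients), rep(NA_real_, 7),
                 rep(NA_real_, 7), TRUE, NA_integer_)
}

#' @export
print.mating_model_fit <- function(x, ...) {
  cat("mating model:", x$model, "- n =", x$n_records,
      if (!x$converged) "(NOT converged)" else "", "\n")
  print(data.frame(term = .term_labels, estimate = x$coefficients,
                   se = x$se, p = x$p_values, row.names = NULL))
  invisible(x)
}

#' Logistic model of pair success
#'
#' Fits, over all male x female pairs,
#' \deqn{\mathrm{logit}\, p_{ij} = \beta_0 + \beta_1 O_i + \beta_2 O_j +
#'   \beta_3 O_{ij} + \beta_4 L_i + \beta_5 L_j + \beta_6 S_i}
#' by maximum likelihood (iteratively reweighted least squares), with Wald
#' standard errors and p-values. Complete separation or non-convergence is
#' flagged (`converged = FALSE`) with the coefficients still reported.
#'
#' @param records pair table from [build_pair_table()].
#' @return a `mating_model_fit`.
#' @export
fit_logistic_eq1 <- function(records) {
  if (length(unique(records$success)) < 2)
    stop("fit_logistic_eq1: both outcome classes must be present")
  fit <- suppressWarnings(
    stats::glm(success ~ O_i + O_j + O_ij + L_i + L_j + S_i,
               data = records, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  .glm_mating_fit(fit, "logistic_eq1", nrow(records),
                  fit$converged && !fit$boundary)
}

#' Poisson model of offspring counts of successful pairs
#'
#' Fits, over the successful pairs only,
#' \deqn{\log N_{ij} = \gamma_0 + \gamma_1 O_i + \gamma_2 O_j +
#'   \gamma_3 O_{ij} + \gamma_4 L_i + \gamma_5 L_j + \gamma_6 S_i}
#' with a Poisson response and log link, by IRLS maximum likelihood.
#'
#' @param records pair table from [build_pair_table()]; rows with
#'   `success == FALSE` are dropped automatically.
#' @return a `mating_model_fit`.
#' @export
fit_poisson_eq2 <- function(records) {
  rec <- records[records$success, , drop = FALSE]
  if (nrow(rec) < 8)
    stop("fit_poisson_eq2: need at least 8 successful pairs")
  fit <- suppressWarnings(
    stats::glm(N_offspring ~ O_i + O_j + O_ij + L_i + L_j + S_i,
               data = rec, family = stats::poisson(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  .glm_mating_fit(fit, "poisson_eq2", nrow(rec), fit$converged)
}

.linear_predictor <- function(fit, O_i, O_j, O_ij, L_i, L_j, S_i) {
  b <- unname(fit$coefficients)
  b[1] + b[2] * O_i + b[3] * O_j + b[4] * O_ij + b[5] * L_i + b[6] * L_j +
    b[7] * S_i
}

#' Predicted pair-success probability
#'
#' Inverse-logit of the linear predictor of a logistic fit; exact closed form.
#'
#' @param fit a `mating_model_fit` with `model == "logistic_eq1"`.
#' @param O_i,O_j,O_ij,L_i,L_j,S_i predictor values (defaults 0).
#' @return probability in `(0, 1)`.
#' @export
predict_success_probability <- function(fit, O_i = 0, O_j = 0, O_ij = 0,
                                        L_i = 0, L_j = 0, S_i = 0) {
  if (fit$model != "logistic_eq1")
    stop("predict_success_probability needs a logistic_eq1 fit")
  stats::plogis(.linear_predictor(fit, O_i, O_j, O_ij, L_i, L_j, S_i))
}

#' Predicted offspring count
#'
#' Exponential of the linear predictor of a Poisson fit; exact closed form.
#'
#' @param fit a `mating_model_fit` with `model == "poisson_eq2"`.
#' @inheritParams predict_success_probability
#' @return expected offspring count (> 0).
#' @export
predict_offspring_count <- function(fit, O_i = 0, O_j = 0, O_ij = 0,
                                    L_i = 0, L_j = 0, S_i = 0) {
  if (fit$model != "poisson_eq2")
    stop("predict_offspring_count needs a poisson_eq2 fit")
  exp(.linear_predictor(fit, O_i, O_j, O_ij, L_i, L_j, S_i))
}

#' Assortative-mating contingency test
#'
#' 2x2 chi-square test with Yates continuity correction on the counts of
#' distinct mating pairs by male origin x female origin (one count per
#' parental pair regardless of family size; set
#' `weight = "offspring"` to weight by family size instead). The Yates
#' statistic clamps `|O - E| - 0.5` at zero so near-exact tables cannot
#' inflate the statistic.
#'
#' @param assignments a `pedigree_assignment` data.frame.
#' @param registry a [breeder_registry()].
#' @param weight `"pairs"` (default) or `"offspring"`.
#' @return list with `chi2`, `p`, `df` and the 2x2 `table`
#'   (rows = male origin, cols = female origin); `flag` is `"undefined"` when
#'   a margin is zero.
#' @export
assortative_test <- function(assignments, registry,
                             weight = c("pairs", "offspring")) {
  weight <- match.arg(weight)
  res <- assignments[!is.na(assignments$mother_id) &
                       !is.na(assignments$father_id), , drop = FALSE]
  if (!nrow(res)) stop("assortative_test: no resolved families")
  om <- registry$origin[match(res$father_id, registry$id)]
  of <- registry$origin[match(res$mother_id, registry$id)]
  if (weight == "pairs") {
    keep <- !duplicated(paste(res$father_id, res$mother_id))
    om <- om[keep]; of <- of[keep]
  }
  tab <- base::table(factor(om, levels = c("south", "west")),
                     factor(of, levels = c("south", "west")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(chi2 = NA_real_, p = NA_real_, df = 1, table = tab,
                flag = "undefined"))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum(pmax(abs(tab - e) - 0.5, 0)^2 / e)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       df = 1, table = tab, flag = "ok")
}
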