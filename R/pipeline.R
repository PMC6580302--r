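## Orchestration: runs the analysis stages in study order (diversity ->
## differentiation -> marker power -> parentage -> classification -> Nb ->
## mating models -> assortative test) and writes the report bundle.

#' Contribution summary by origin and tactic
#'
#' The per-stratum tally of a reconstructed pedigree: contributing parents,
#' offspring by origin class, family counts, largest family, and mean +/- SD
#' family size, for each origin x tactic stratum of the adults.
#'
#' @param assignments a `pedigree_assignment` data.frame.
#' @param registry a [breeder_registry()].
#' @return data.frame with one row per (origin, tactic) adult stratum.
#' @export
summarize_contributions <- function(assignments, registry) {
  res <- assignments[!is.na(assignments$mother_id) &
                       !is.na(assignments$father_id), , drop = FALSE]
  adults <- registry[registry$origin %in% c("south", "west"), , drop = FALSE]
  strata <- unique(adults[, c("origin", "tactic")])
  strata <- strata[order(strata$origin, strata$tactic), ]
  rows <- lapply(seq_len(nrow(strata)), function(s) {
    org <- strata$origin[s]; tc <- strata$tactic[s]
    ids <- adults$id[adults$origin == org & adults$tactic == tc]
    par_col <- if (tc == "female") "mother_id" else "father_id"
    mine <- res[res[[par_col]] %in% ids, , drop = FALSE]
    fam <- base::table(paste(mine$mother_id, mine$father_id))
    by_class <- function(cl) sum(mine$origin_class == cl)
    famsz <- if (length(fam)) as.numeric(fam) else numeric()
    data.frame(
      origin = org, tactic = tc, n_total = length(ids),
      n_contributing = length(unique(mine[[par_col]])),
      offspring_total = nrow(mine),
      offspring_south = by_class("south"),
      offspring_hybrid = by_class("hybrid"),
      offspring_west = by_class("west"),
      n_families = length(fam),
      largest_family = if (length(famsz)) max(famsz) else 0,
      mean_family = if (length(famsz)) mean(famsz) else NA_real_,
      sd_family = if (length(famsz) > 1) stats::sd(famsz) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Either simulates a mesocosm (`sim_cfg` given) or loads real inputs
#' (`genotypes` GenePop path + `phenotypes` TSV path), then runs diversity
#' and differentiation summaries, marker power, two-round parentage
#' assignment with hybrid classification, the effective-number-of-breeders
#' report, the two mating models, and the assortative-mating test, writing
#' TSV reports to `out_dir`. Null-flagged loci are excluded from the
#' diversity/differentiation reports but echoed in the genotype export.
#' Reruns with identical inputs and seed produce byte-identical reports.
#'
#' @param sim_cfg a [sim_config()] for simulate mode, or `NULL`.
#' @param genotypes,phenotypes input paths for real-input mode.
#' @param flagged_null locus names to flag when reading real inputs.
#' @param out_dir output directory.
#' @param error_rate parentage LOD error rate.
#' @param covariate_mode size covariate for the mating models.
#' @param mc_cfg an [mc_config()] for the exact tests (HW per locus/group).
#' @param run_mc_tests run the (slow) HW Markov-chain tests (default FALSE).
#' @param alpha FDR level.
#' @param seed seed echoed into the manifest (simulate mode uses
#'   `sim_cfg$seed`).
#' @return list with all stage results (`diversity`, `fst`, `marker_power`,
#'   `assignments`, `contributions`, `nb`, `eq1`, `eq2`, `assortative`,
#'   `manifest`), invisibly; reports written to `out_dir`.
#' @export
run_pipeline <- function(sim_cfg = NULL, genotypes = NULL, phenotypes = NULL,
                         flagged_null = character(), out_dir = tempdir(),
                         error_rate = 0.02, covariate_mode = "length",
                         mc_cfg = NULL, run_mc_tests = FALSE, alpha = 0.05,
                         seed = 1L) {
  if (is.null(sim_cfg) == is.null(genotypes))
    stop("exactly one of sim_cfg (simulate mode) or genotypes+phenotypes ",
         "(real-input mode) must be given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    val <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    val
  }
  tsv <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(sim_cfg)) {
    sim <- stage("simulate", simulate_mesocosm(sim_cfg))
    tab <- sim$table; registry <- sim$registry
    write_mesocosm(sim, file.path(out_dir, "inputs"))
    seed <- sim_cfg$seed
  } else {
    tab <- stage("load", read_genepop(genotypes, flagged_null = flagged_null))
    registry <- read_phenotypes(phenotypes)
    sim <- NULL
  }

  groups <- intersect(c("south", "west", "offspring"), unique(tab$pop))
  diversity <- stage("diversity", {
    do.call(rbind, lapply(groups, function(g)
      cbind(group = g, locus_summary(tab, g))))
  })
  tsv(diversity, "diversity.tsv")

  fst <- stage("differentiation", {
    prs <- utils::combn(groups, 2, simplify = FALSE)
    do.call(rbind, lapply(prs, function(pr) {
      r <- fst_weir_cockerham(tab, pr[1], pr[2])
      data.frame(groupA = pr[1], groupB = pr[2], theta = r$theta)
    }))
  })
  tsv(fst, "pairwise_fst.tsv")

  hw <- NULL
  if (run_mc_tests) {
    if (is.null(mc_cfg)) mc_cfg <- mc_config(seed = seed)
    hw <- stage("hw_tests", {
      rows <- list()
      for (g in groups) for (l in tab$loci) {
        r <- hw_exact_test(tab, g, l, mc_cfg)
        rows[[length(rows) + 1L]] <- data.frame(group = g, locus = l,
                                                p = r$p_value, se = r$se)
      }
      out <- do.call(rbind, rows)
      out$p_adj <- fdr_adjust(out$p, "bh", alpha)$p_adj
      out
    })
    tsv(hw, "hw_tests.tsv")
  }

  power <- stage("marker_power", marker_power(tab, c("south", "west")))
  pw <- power
  cmb <- attr(power, "combined")
  pw <- rbind(pw, data.frame(locus = "combined", PIC = NA, Q_P1 = cmb["Q_P1"],
                             Q_P2 = cmb["Q_P2"], Q_PP = cmb["Q_PP"],
                             I = cmb["I"]))
  tsv(pw, "marker_power.tsv")

  assignments <- stage("parentage",
    assign_parentage(tab, registry, error_rate = error_rate))
  tsv(assignments, "pedigree.tsv")

  contributions <- stage("contributions",
    summarize_contributions(assignments, registry))
  tsv(contributions, "contributions.tsv")

  nb <- stage("breeders_nb", nb_report(assignments, registry))
  tsv(nb, "nb_report.tsv")

  pairs <- stage("pair_table",
    build_pair_table(assignments, registry, covariate_mode))
  eq1 <- stage("logistic_model", fit_logistic_eq1(pairs))
  eq2 <- stage("poisson_model", fit_poisson_eq2(pairs))
  model_tsv <- function(fit) data.frame(
    parameter = c("b0", "b1", "b2", "b3", "b4", "b5", "b6"),
    description = .term_labels, estimate = fit$coefficients, se = fit$se,
    p = fit$p_values, row.names = NULL)
  tsv(model_tsv(eq1), "model_eq1.tsv")
  tsv(model_tsv(eq2), "model_eq2.tsv")

  assort <- stage("assortative", assortative_test(assignments, registry))
  tsv(data.frame(male_origin = rep(rownames(assort$table), 2),
                 female_origin = rep(colnames(assort$table), each = 2),
                 pairs = as.vector(assort$table),
                 chi2 = assort$chi2, p = assort$p),
      "assortative.tsv")

  manifest <- c(
    sprintf("mode: %s", if (is.null(sim)) "real-input" else "simulate"),
    sprintf("seed: %d", seed),
    sprintf("n_individuals: %d", length(tab$ids)),
    sprintf("n_loci: %d", length(tab$loci)),
    sprintf("flagged_null: %s",
            paste(tab$loci[tab$flagged_null], collapse = ",")),
    sprintf("covariate_mode: %s", covariate_mode),
    sprintf("error_rate: %g", error_rate))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))

  invisible(list(diversity = diversity, fst = fst, hw = hw,
                 marker_power = power, assignments = assignments,
                 contributions = contributions, nb = nb, eq1 = eq1, eq2 = eq2,
                 assortative = assort, sim = sim, manifest = manifest))
}
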