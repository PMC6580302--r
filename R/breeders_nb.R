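## Family-size accounting and the inbreeding effective number of breeders.

#' Family-size statistics of contributing breeders
#'
#' Tallies offspring per parent and per parental pair from resolved
#' assignments, per sex stratum, optionally excluding all offspring sired by
#' sneaker males (exclusion removes those offspring from BOTH the paternal and
#' the maternal tallies). Only contributing parents (>= 1 offspring after
#' filtering) enter the census N, the mean family size k-bar, and the
#' family-size variance Vk. `Vk` uses the population variance (divide by N)
#' by default, the convention of the Crow-Kimura moment derivations;
#' set `var_type = "sample"` for the n-1 divisor.
#'
#' @param assignments a `pedigree_assignment` data.frame (resolved rows used).
#' @param registry a [breeder_registry()].
#' @param include_sneakers keep sneaker-sired offspring (default `TRUE`).
#' @param origin `"south"`, `"west"` or `"all"`: restrict to families whose
#'   parent of the focal sex has this origin (`"all"` keeps everything).
#' @param var_type `"population"` (default) or `"sample"`.
#' @return list with elements `male` and `female`, each a list
#'   `(N, k_bar, Vk, counts)`, plus `pairs` (per-pair offspring counts) and
#'   the filter settings.
#' @export
family_stats <- function(assignments, registry, include_sneakers = TRUE,
                         origin = c("all", "south", "west"),
                         var_type = c("population", "sample")) {
  origin <- match.arg(origin)
  var_type <- match.arg(var_type)
  res <- assignments[!is.na(assignments$mother_id) &
                       !is.na(assignments$father_id), , drop = FALSE]
  if (!include_sneakers) {
    sneaker <- registry$id[registry$tactic == "sneaker_male"]
    res <- res[!res$father_id %in% sneaker, , drop = FALSE]
  }
  sex_stats <- function(parent_ids) {
    par_origin <- registry$origin[match(parent_ids, registry$id)]
    keep <- if (origin == "all") rep(TRUE, length(parent_ids))
            else par_origin == origin
    counts <- base::table(parent_ids[keep])
    if (!length(counts))
      return(list(N = 0L, k_bar = NA_real_, Vk = NA_real_, counts = counts))
    k <- as.numeric(counts)
    vk <- if (var_type == "population") mean((k - mean(k))^2)
          else stats::var(k)
    list(N = length(k), k_bar = mean(k), Vk = vk, counts = counts)
  }
  pairs <- if (nrow(res)) base::table(paste(res$mother_id, res$father_id,
                                            sep = " x ")) else base::table(character())
  list(male = sex_stats(res$father_id), female = sex_stats(res$mother_id),
       pairs = pairs, include_sneakers = include_sneakers, origin = origin,
       var_type = var_type)
}

#' Per-sex inbreeding effective number of breeders
#'
#' From the census of contributing breeders N, mean family size k-bar and
#' family-size variance Vk:
#' \deqn{N_b = \frac{\bar k N - 2}{\bar k - 1 + V_k/\bar k}}
#' With equal contributions (Vk = 0, k-bar = 2) this reduces to 2N - 2; a
#' larger Vk at fixed N and k-bar strictly decreases Nb.
#'
#' @param N number of contributing breeders of the sex.
#' @param k_bar mean offspring per contributing breeder (> 0).
#' @param Vk variance in offspring number (>= 0).
#' @return Nb (numeric); `NA` with a warning if the denominator is <= 0.
#' @export
nb_per_sex <- function(N, k_bar, Vk) {
  stopifnot(k_bar > 0, Vk >= 0, N > 0)
  den <- (k_bar - 1) + Vk / k_bar
  if (den <= 0) {
    warning("nb_per_sex: non-positive denominator; estimate undefined")
    return(NA_real_)
  }
  (k_bar * N - 2) / den
}

#' Combined two-sex effective number of breeders
#'
#' Harmonic-style combination of the per-sex values:
#' \deqn{N_b = \frac{4 N_{b,f} N_{b,m}}{N_{b,f} + N_{b,m}}}
#' Equal per-sex values x combine to 2x.
#'
#' @param Nb_f,Nb_m per-sex effective numbers (both positive).
#' @return combined Nb.
#' @export
nb_combined <- function(Nb_f, Nb_m) {
  if (any(c(Nb_f, Nb_m) <= 0) || anyNA(c(Nb_f, Nb_m)))
    stop("nb_combined: per-sex Nb must be positive")
  4 * Nb_f * Nb_m / (Nb_f + Nb_m)
}

#' Effective-number-of-breeders report
#'
#' Full breeder census table: per origin stratum (south, west, all) and
#' sneaker-inclusion setting, the per-sex (N, k-bar, Vk, Nb) and the combined
#' two-sex Nb. Reported values are rounded to one decimal (half-up); the
#' unrounded values are kept in the `raw` attribute.
#'
#' @inheritParams family_stats
#' @return data.frame with one row per (sneakers, origin) stratum.
#' @export
nb_report <- function(assignments, registry,
                      var_type = c("population", "sample")) {
  var_type <- match.arg(var_type)
  round_half_up <- function(x, d = 1) floor(x * 10^d + 0.5) / 10^d
  rows <- list(); raw <- list()
  for (inc in c(TRUE, FALSE)) for (org in c("south", "west", "all")) {
    fs <- family_stats(assignments, registry, include_sneakers = inc,
                       origin = org, var_type = var_type)
    nbm <- if (fs$male$N > 0) nb_per_sex(fs$male$N, fs$male$k_bar, fs$male$Vk)
           else NA_real_
    nbf <- if (fs$female$N > 0)
      nb_per_sex(fs$female$N, fs$female$k_bar, fs$female$Vk) else NA_real_
    nbc <- if (!is.na(nbm) && !is.na(nbf) && nbm > 0 && nbf > 0)
      nb_combined(nbf, nbm) else NA_real_
    raw[[length(raw) + 1L]] <- list(inc = inc, org = org, nbm = nbm, nbf = nbf,
                                    nbc = nbc, fs = fs)
    rows[[length(rows) + 1L]] <- data.frame(
      sneakers = if (inc) "included" else "excluded", origin = org,
      N_m = fs$male$N, k_bar_m = round_half_up(fs$male$k_bar),
      Vk_m = round_half_up(fs$male$Vk), Nb_m = round_half_up(nbm),
      N_f = fs$female$N, k_bar_f = round_half_up(fs$female$k_bar),
      Vk_f = round_half_up(fs$female$Vk), Nb_f = round_half_up(nbf),
      Nb = round_half_up(nbc))
  }
  out <- do.call(rbind, rows)
  attr(out, "raw") <- raw
  out
}
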