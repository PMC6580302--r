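#' Construct a diploid genotype table
#'
#' The central container of the package: an individuals-by-loci matrix pair of
#' diploid microsatellite allele calls, with one population (origin) label per
#' individual. Allele codes are opaque positive integers below 1000 (fragment
#' sizes or arbitrary 3-digit codes); no repeat-unit conversion is ever applied.
#'
#' @param ids character vector of unique individual identifiers.
#' @param pop character vector of population/origin labels, one per individual
#'   (typically `"south"`, `"west"` or `"offspring"`).
#' @param loci character vector of locus names (unique).
#' @param a1,a2 integer matrices (`length(ids)` x `length(loci)`) holding the
#'   two allele calls per individual and locus; `NA` in both slots marks a
#'   missing call. Pairs are unordered and stored with `a1 <= a2`.
#' @param flagged_null logical vector, one per locus: loci flagged as carrying
#'   null alleles (heterozygote-deficient, e.g. the SMD118 analogue). Flagged
#'   loci stay in the table but are excluded from diversity/differentiation
#'   summaries and used only for tie-breaking in parentage assignment.
#'
#' @return An object of class `genotype_table`: a list with elements `ids`,
#'   `pop`, `loci`, `a1`, `a2`, `flagged_null` and an allele registry
#'   `alleles` (list of sorted integer vectors, one per locus, built from the
#'   observed calls).
#' @export
genotype_table <- function(ids, pop, loci, a1, a2,
                           flagged_null = rep(FALSE, length(loci))) {
  ids <- as.character(ids)
  pop <- as.character(pop)
  loci <- as.character(loci)
  if (anyDuplicated(ids)) stop("duplicate individual ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(loci)) stop("duplicate locus names")
  if (length(pop) != length(ids)) stop("pop must have one label per individual")
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == c(length(ids), length(loci))) ||
      !all(dim(a2) == c(length(ids), length(loci))))
    stop("a1/a2 must be length(ids) x length(loci) matrices")
  if (xor(any(is.na(a1) != is.na(a2)), FALSE) && any(is.na(a1) != is.na(a2)))
    stop("half-missing calls are not allowed: both allele slots or neither")
  ok <- is.na(a1) | (a1 >= 1 & a1 < 1000 & a2 >= 1 & a2 < 1000)
  if (!all(ok)) stop("allele codes must be positive integers < 1000")
  # normalise unordered pairs
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  if (length(flagged_null) != length(loci)) stop("flagged_null: one flag per locus")
  alleles <- lapply(seq_along(loci), function(j)
    sort(unique(c(a1[, j], a2[, j])[!is.na(c(a1[, j], a2[, j]))])))
  names(alleles) <- loci
  structure(list(ids = ids, pop = pop, loci = loci, a1 = a1, a2 = a2,
                 flagged_null = stats::setNames(flagged_null, loci),
                 alleles = alleles),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$ids), "individuals x", length(x$loci),
      "loci\n")
  cat("populations:", paste(sprintf("%s (%d)", names(table(x$pop)),
                                    table(x$pop)), collapse = ", "), "\n")
  if (any(x$flagged_null))
    cat("null-flagged loci:", paste(x$loci[x$flagged_null], collapse = ", "), "\n")
  invisible(x)
}

#' Number of individuals in a genotype table
#' @param table a `genotype_table`.
#' @return integer count.
#' @export
n_individuals <- function(table) length(table$ids)

#' Subset a genotype table by population label or individual id
#'
#' @param table a `genotype_table`.
#' @param pop optional character vector of population labels to keep.
#' @param ids optional character vector of individual ids to keep.
#' @param loci optional character vector of locus names to keep.
#' @return a `genotype_table` restricted to the selection, in input order.
#' @export
subset_genotypes <- function(table, pop = NULL, ids = NULL, loci = NULL) {
  keep <- rep(TRUE, length(table$ids))
  if (!is.null(pop)) keep <- keep & table$pop %in% pop
  if (!is.null(ids)) keep <- keep & table$ids %in% ids
  jkeep <- if (is.null(loci)) seq_along(table$loci) else {
    m <- match(loci, table$loci)
    if (anyNA(m)) stop("unknown loci: ", paste(loci[is.na(m)], collapse = ", "))
    m
  }
  genotype_table(table$ids[keep], table$pop[keep], table$loci[jkeep],
                 table$a1[keep, jkeep, drop = FALSE],
                 table$a2[keep, jkeep, drop = FALSE],
                 unname(table$flagged_null[jkeep]))
}

## ---- GenePop I/O -----------------------------------------------------------

# decode a concatenated diploid code string at a given digit width
.decode_call <- function(code, width) {
  a <- as.integer(substr(code, 1L, width))
  b <- as.integer(substr(code, width + 1L, 2L * width))
  if (is.na(a) || is.na(b)) return(c(NA_integer_, NA_integer_))
  if (a == 0L || b == 0L) return(c(NA_integer_, NA_integer_))
  c(a, b)
}

#' Read a GenePop file
#'
#' Parses the classic GENEPOP text dialect: a title line, locus names (one per
#' line or comma-separated on one line), `POP` separators, and per-individual
#' lines `id , code code ...` with 2- or 3-digit concatenated diploid codes
#' (`0000`/`000000` = missing). The digit width is auto-detected per file and
#' must be consistent throughout.
#'
#' @param path path to a GenePop file.
#' @param pop_labels character vector mapping POP blocks (in file order) to
#'   origin labels; recycled/truncated defaults are
#'   `c("south", "west", "offspring")` followed by `"pop4"`, `"pop5"`, ...
#' @param flagged_null optional character vector of locus names to flag as
#'   null-allele-bearing.
#' @return a [genotype_table()].
#' @export
read_genepop <- function(path, pop_labels = NULL, flagged_null = character()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 2L) stop("GenePop parse error: file too short")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("GenePop parse error: no POP separator found")
  header <- lines[2:(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("GenePop parse error: no locus names before first POP")

  ids <- character(); pops <- character()
  rows1 <- list(); rows2 <- list()
  width <- NA_integer_
  block <- 0L
  for (i in seq(first_pop, length(lines))) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (toupper(line) == "POP") { block <- block + 1L; next }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) != 2L)
      stop(sprintf("GenePop parse error at line %d: expected 'id , genotypes'", i))
    id <- trimws(parts[1])
    codes <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
    if (length(codes) != length(loci))
      stop(sprintf("GenePop parse error at line %d: %d genotypes for %d loci",
                   i, length(codes), length(loci)))
    w <- unique(nchar(codes)) / 2L
    if (any(nchar(codes) %% 2L != 0L) || !all(w %in% c(2L, 3L)))
      stop(sprintf("GenePop parse error at line %d: genotype codes must be 4 or 6 digits", i))
    if (length(unique(w)) > 1L)
      stop(sprintf("GenePop format error at line %d: mixed allele-code widths", i))
    if (is.na(width)) width <- unique(w)
    else if (unique(w) != width)
      stop(sprintf("GenePop format error at line %d: allele-code width %d differs from %d seen earlier",
                   i, unique(w), width))
    call <- vapply(codes, .decode_call, integer(2), width = width)
    ids <- c(ids, id); pops <- c(pops, as.character(block))
    rows1[[length(rows1) + 1L]] <- call[1, ]
    rows2[[length(rows2) + 1L]] <- call[2, ]
  }
  if (!length(ids)) stop("GenePop parse error: no individuals")
  labels <- if (is.null(pop_labels)) {
    nb <- max(as.integer(pops))
    c("south", "west", "offspring", paste0("pop", seq_len(max(nb - 3L, 0L)) + 3L))[seq_len(nb)]
  } else pop_labels
  pop <- labels[as.integer(pops)]
  a1 <- do.call(rbind, rows1); a2 <- do.call(rbind, rows2)
  genotype_table(ids, pop, loci, a1, a2,
                 flagged_null = loci %in% flagged_null)
}

#' Write a genotype table as GenePop
#'
#' Emits the 3-digit dialect with one POP block per distinct population label,
#' blocks in order of first appearance and individuals in input order within
#' each block. Missing calls are written as `000000`.
#'
#' @param table a [genotype_table()].
#' @param path output file path (UTF-8, LF line endings).
#' @param title title line; defaults to a generic stamp.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(table, path, title = "mesokin genotype export") {
  if (any(!is.na(table$a1) & (table$a1 > 999 | table$a2 > 999)))
    stop("encoding error: allele code >= 1000 cannot be written in 3-digit dialect")
  con <- file(path, open = "wb")
  on.exit(close(con))
  out <- function(s) writeLines(s, con, sep = "\n", useBytes = TRUE)
  out(title)
  out(table$loci)
  for (p in unique(table$pop)) {
    out("POP")
    idx <- which(table$pop == p)
    for (i in idx) {
      codes <- vapply(seq_along(table$loci), function(j) {
        if (is.na(table$a1[i, j])) "000000"
        else sprintf("%03d%03d", table$a1[i, j], table$a2[i, j])
      }, character(1))
      out(paste0(table$ids[i], " , ", paste(codes, collapse = " ")))
    }
  }
  invisible(path)
}

## ---- Phenotype / breeder registry ------------------------------------------

.origins <- c("south", "west", "offspring")
.tactics <- c("female", "nesting_male", "sneaker_male", "immature")

#' Read the per-individual phenotype table
#'
#' Tab-separated sidecar carrying the breeder metadata (origin, sex/tactic,
#' size) that GenePop files cannot hold; the individual id is the join key to
#' the genotype table. Adults (origin `south`/`west`) must have a mature
#' tactic and positive length and weight; offspring are `immature`.
#'
#' @param path path to a TSV with header columns
#'   `id, origin, tactic, total_length_cm, body_weight_g, tag`.
#' @return a `data.frame` (one row per individual) with validated, typed
#'   columns; class `breeder_registry`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  req <- c("id", "origin", "tactic", "total_length_cm", "body_weight_g", "tag")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("phenotype schema error: missing column(s) ",
                         paste(miss, collapse = ", "))
  breeder_registry(df$id, df$origin, df$tactic,
                   df$total_length_cm, df$body_weight_g, df$tag)
}

#' Construct a breeder registry
#'
#' @param id,origin,tactic,total_length_cm,body_weight_g,tag parallel vectors
#'   describing each individual; see [read_phenotypes()] for semantics.
#' @return a validated `breeder_registry` data.frame.
#' @export
breeder_registry <- function(id, origin, tactic, total_length_cm = NA_real_,
                             body_weight_g = NA_real_, tag = NA_character_) {
  df <- data.frame(id = as.character(id), origin = as.character(origin),
                   tactic = as.character(tactic),
                   total_length_cm = as.numeric(total_length_cm),
                   body_weight_g = as.numeric(body_weight_g),
                   tag = as.character(tag), stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("duplicate ids in phenotype table")
  bad <- !df$origin %in% .origins
  if (any(bad)) stop("unknown origin value(s): ",
                     paste(unique(df$origin[bad]), collapse = ", "))
  bad <- !df$tactic %in% .tactics
  if (any(bad)) stop("unknown tactic value(s): ",
                     paste(unique(df$tactic[bad]), collapse = ", "))
  adult <- df$origin %in% c("south", "west")
  if (any(adult & df$tactic == "immature"))
    stop("validation error: adults cannot have tactic 'immature'")
  if (any(!adult & df$tactic != "immature"))
    stop("validation error: offspring must have tactic 'immature'")
  sz_bad <- adult & (is.na(df$total_length_cm) | is.na(df$body_weight_g) |
                       df$total_length_cm <= 0 | df$body_weight_g <= 0)
  if (any(sz_bad))
    stop("validation error: adults need positive length and weight; offending ids: ",
         paste(df$id[sz_bad], collapse = ", "))
  class(df) <- c("breeder_registry", "data.frame")
  df
}

#' Write a breeder registry as TSV
#' @param registry a `breeder_registry`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(registry, path) {
  utils::write.table(registry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
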