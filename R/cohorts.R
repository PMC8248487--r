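#' Define a sequencing cohort
#'
#' A cohort is a named set of diploid individuals genotyped by exome or
#' genome sequencing. The individual count fixes the allele number (2N) used
#' for singleton allele frequencies and for back-computing allele counts
#' when a source table reports AF only.
#'
#' @param name Cohort name, unique within a run.
#' @param n_individuals Number of diploid individuals (>= 1).
#' @param assay `"exome"` or `"genome"`.
#' @return An object of class `"cohort"`.
#' @export
#' @examples
#' cohort("topmed", 132345, "genome")
cohort <- function(name, n_individuals, assay = c("exome", "genome")) {
  assay <- match.arg(assay)
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    .err("cohort name must be a non-empty string")
  if (!is.numeric(n_individuals) || length(n_individuals) != 1 ||
      is.na(n_individuals) || n_individuals < 1 ||
      n_individuals != floor(n_individuals))
    .err("n_individuals must be a positive integer")
  structure(list(name = name, n_individuals = as.numeric(n_individuals),
                 assay = assay), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %s: %s %ss\n", x$name,
              format(x$n_individuals, big.mark = ","), x$assay))
  invisible(x)
}

#' Allele frequency of a singleton variant
#'
#' A variant carried on a single allele in a cohort of N diploid individuals
#' has frequency 1/(2N). For the largest current biobanks this is of the
#' order 1e-6 (log10 AF around -5.4 for a 132,345-genome cohort).
#'
#' @param n_individuals Number of diploid individuals (>= 1).
#' @return A list with `af` and `log10_af`.
#' @export
#' @examples
#' singleton_af(132345)$log10_af  # about -5.42
singleton_af <- function(n_individuals) {
  if (!is.numeric(n_individuals) || length(n_individuals) != 1 ||
      is.na(n_individuals) || n_individuals < 1)
    .err("n_individuals must be >= 1")
  af <- 1 / (2 * n_individuals)
  list(af = af, log10_af = log10(af))
}

.req_obs_cols <- c("pos", "ref", "alt", "ac", "an", "af")

.validate_obs <- function(obs, where = "observation table") {
  miss <- setdiff(c("cohort", "pos", "ref", "alt", "af"), names(obs))
  if (length(miss))
    .err("%s is missing columns: %s", where, paste(miss, collapse = ", "))
  bad <- which(obs$af < 0 | obs$af > 1)
  if (length(bad))
    .err("%s has af outside [0,1] at rows: %s", where,
         paste(utils::head(bad, 5), collapse = ", "))
  if (all(c("ac", "an") %in% names(obs))) {
    ok <- is.na(obs$ac) | is.na(obs$an) |
      abs(obs$af - obs$ac / obs$an) <= 1e-12 + 1e-9 * obs$af
    if (!all(ok))
      .err("%s has af inconsistent with ac/an at rows: %s", where,
           paste(utils::head(which(!ok), 5), collapse = ", "))
  }
  invisible(obs)
}

#' Read per-cohort variant observations
#'
#' Reads a cohort's variant table from either a minimal VCF 4.x file (CHROM,
#' POS, REF, ALT with INFO keys AC/AN/AF) or a tab-delimited file with header
#' `pos ref alt ac an af`. Multi-allelic VCF records are split into one
#' observation per ALT allele; rows with `ac == 0` are dropped; indel alleles
#' are rejected (the pipeline is missense-only). When a delimited table
#' reports AF but no allele counts, `ac` is back-computed as
#' `round(af * 2N)` so singleton status can still be called.
#'
#' @param path Path to the variant file (gzip is handled transparently).
#' @param format `"tsv"` or `"vcf"`.
#' @param cohort A [cohort()] object.
#' @return A data.frame of observations with columns `cohort, pos, ref, alt,
#'   ac, an, af, is_singleton` (plus `chrom` for VCF input). The coordinate
#'   system is recorded in the `"coord"` attribute (`"cds"` for delimited
#'   input, `"genomic"` for VCF).
#' @export
read_cohort_variants <- function(path, format = c("tsv", "vcf"), cohort) {
  format <- match.arg(format)
  if (!inherits(cohort, "cohort")) .err("`cohort` must be a cohort() object")
  if (!file.exists(path)) .err("file not found: %s", path)
  obs <- switch(format,
    tsv = .read_cohort_tsv(path, cohort),
    vcf = .read_cohort_vcf(path, cohort))
  snv <- nchar(obs$ref) == 1 & nchar(obs$alt) == 1 &
    obs$ref %in% c("A", "C", "G", "T") & obs$alt %in% c("A", "C", "G", "T")
  if (!all(snv))
    .err("non-SNV alleles at rows: %s (missense pipeline accepts single nucleotides only)",
         paste(utils::head(which(!snv), 5), collapse = ", "))
  obs <- obs[obs$ac > 0 | is.na(obs$ac), , drop = FALSE]
  obs$is_singleton <- !is.na(obs$ac) & obs$ac == 1
  .validate_obs(obs, where = path)
  rownames(obs) <- NULL
  obs
}

.read_cohort_tsv <- function(path, cohort) {
  tab <- .read_tsv(path)
  miss <- setdiff(c("pos", "ref", "alt"), names(tab))
  if (length(miss))
    .err("%s: missing required columns: %s", path, paste(miss, collapse = ", "))
  if (!is.numeric(tab$pos) || anyNA(tab$pos))
    .err("%s: malformed `pos` at line(s): %s", path,
         paste(utils::head(which(!grepl("^[0-9]+$", as.character(tab$pos))), 5) + 1,
               collapse = ", "))
  an2 <- 2 * cohort$n_individuals
  if (is.null(tab$an)) tab$an <- an2
  if (is.null(tab$ac)) {
    if (is.null(tab$af)) .err("%s: need either `ac` or `af`", path)
    tab$ac <- pmax(1L, as.integer(round(tab$af * tab$an)))
  }
  if (is.null(tab$af)) tab$af <- tab$ac / tab$an
  out <- data.frame(cohort = cohort$name, pos = as.integer(tab$pos),
                    ref = toupper(tab$ref), alt = toupper(tab$alt),
                    ac = as.integer(tab$ac), an = as.numeric(tab$an),
                    af = as.numeric(tab$af), stringsAsFactors = FALSE)
  structure(out, coord = "cds")
}

.read_cohort_vcf <- function(path, cohort) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  info <- as.data.frame(fx, stringsAsFactors = FALSE)
  info$AC <- vcfR::extract.info(v, "AC")
  info$AN <- vcfR::extract.info(v, "AN")
  info$AF <- vcfR::extract.info(v, "AF")
  rows <- lapply(seq_len(nrow(info)), function(i) {
    alts <- strsplit(info$ALT[i], ",", fixed = TRUE)[[1]]
    nalt <- length(alts)
    per_a <- function(x) {
      if (is.na(x)) return(rep(NA_real_, nalt))
      xs <- as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])
      if (length(xs) == nalt) xs else rep(xs[1], nalt)
    }
    ac <- per_a(info$AC[i]); af <- per_a(info$AF[i])
    an <- suppressWarnings(as.numeric(info$AN[i]))
    if (is.na(an)) an <- 2 * cohort$n_individuals
    if (all(is.na(af))) af <- ac / an
    if (all(is.na(ac))) ac <- pmax(1, round(af * an))
    data.frame(chrom = info$CHROM[i], pos = as.integer(info$POS[i]),
               ref = info$REF[i], alt = alts, ac = as.integer(ac),
               an = an, af = af, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(cohort = cohort$name, out, stringsAsFactors = FALSE)
  structure(out, coord = "genomic")
}

#' Merge variant observations across cohorts
#'
#' Forms the cross-cohort union of variants keyed by `(pos, ref, alt)`
#' (plus `chrom` when present). For a variant seen in several cohorts the
#' merged allele frequency is the maximum per-cohort AF; the sharing class
#' is the number of cohorts carrying the variant. A merged variant is a
#' singleton when it was observed on exactly one allele in exactly one
#' cohort and is absent from all others (set `singleton_rule =
#' "per_cohort"` to instead flag any variant that is a singleton within at
#' least one cohort).
#'
#' @param obs_lists A list of per-cohort observation data.frames from
#'   [read_cohort_variants()] or [simulate_cohorts()].
#' @param singleton_rule `"merged"` (default) or `"per_cohort"`.
#' @return A data.frame with columns `pos, ref, alt, max_af, sharing_class,
#'   is_singleton, cohorts` (comma-joined member cohorts), sorted by
#'   position.
#' @export
merge_cohorts <- function(obs_lists, singleton_rule = c("merged", "per_cohort")) {
  singleton_rule <- match.arg(singleton_rule)
  if (inherits(obs_lists, "data.frame")) obs_lists <- list(obs_lists)
  if (!length(obs_lists)) .err("need at least one cohort")
  coords <- vapply(obs_lists, function(o) {
    co <- attr(o, "coord")
    if (is.null(co)) if ("chrom" %in% names(o)) "genomic" else "cds" else co
  }, character(1))
  if (length(unique(coords)) > 1)
    .err("cohort tables use mixed coordinate systems (%s); remap before merging",
         paste(unique(coords), collapse = " vs "))
  obs <- do.call(rbind, lapply(obs_lists, function(o) {
    o <- as.data.frame(o)
    o[, intersect(c("cohort", "chrom", "pos", "ref", "alt", "ac", "an", "af"),
                  names(o)), drop = FALSE]
  }))
  norm <- normalize_alleles(obs$pos, obs$ref, obs$alt)
  obs$pos <- norm$pos; obs$ref <- norm$ref; obs$alt <- norm$alt
  key <- if ("chrom" %in% names(obs))
    paste(obs$chrom, obs$pos, obs$ref, obs$alt, sep = ":")
  else paste(obs$pos, obs$ref, obs$alt, sep = ":")
  sp <- split(seq_len(nrow(obs)), key)
  merged <- do.call(rbind, lapply(sp, function(idx) {
    o <- obs[idx, , drop = FALSE]
    single <- if (singleton_rule == "merged")
      nrow(o) == 1 && !is.na(o$ac[1]) && o$ac[1] == 1
    else any(!is.na(o$ac) & o$ac == 1)
    data.frame(pos = o$pos[1], ref = o$ref[1], alt = o$alt[1],
               max_af = max(o$af), sharing_class = length(unique(o$cohort)),
               is_singleton = single,
               cohorts = paste(sort(unique(o$cohort)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  merged <- merged[order(merged$pos, merged$ref, merged$alt), , drop = FALSE]
  rownames(merged) <- NULL
  attr(merged, "coord") <- coords[1]
  merged
}

#' Left-normalize SNV/short alleles
#'
#' Trims shared trailing then leading bases from ref/alt pairs, shifting the
#' position as needed, so identical variants written differently collapse to
#' one key. For the missense pipeline alleles are single bases and this is a
#' no-op, but merged keys stay well-defined for padded input.
#'
#' @param pos,ref,alt Parallel vectors.
#' @return A list with normalized `pos`, `ref`, `alt`.
#' @export
normalize_alleles <- function(pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  for (i in seq_along(pos)) {
    r <- ref[i]; a <- alt[i]
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1); a <- substr(a, 1, nchar(a) - 1)
    }
    while (nchar(r) > 1 && nchar(a) > 1 && substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r)); a <- substr(a, 2, nchar(a))
      pos[i] <- pos[i] + 1
    }
    ref[i] <- r; alt[i] <- a
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Summarize the sharing/allele-frequency spectrum
#'
#' Counts merged variants per sharing class (number of cohorts carrying the
#' variant) and reports the mean of the per-variant maximum allele
#' frequencies within each class. Variants found in every cohort are
#' expected to sit at systematically higher AF than private ones.
#'
#' @param merged Output of [merge_cohorts()].
#' @return A data.frame `sharing_class, n, mean_max_af, n_singletons`.
#' @export
sharing_summary <- function(merged) {
  if (!nrow(merged)) .err("merged variant table is empty")
  sp <- split(merged, merged$sharing_class)
  out <- do.call(rbind, lapply(sp, function(m)
    data.frame(sharing_class = m$sharing_class[1], n = nrow(m),
               mean_max_af = mean(m$max_af),
               n_singletons = sum(m$is_singleton))))
  rownames(out) <- NULL
  out[order(out$sharing_class), , drop = FALSE]
}

#' Write a merged-variant table
#'
#' Tab-delimited with header `pos ref alt max_af sharing_class is_singleton
#' cohorts`.
#'
#' @param merged Output of [merge_cohorts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_merged_variants <- function(merged, path) {
  .write_tsv(merged[, c("pos", "ref", "alt", "max_af", "sharing_class",
                        "is_singleton", "cohorts")], path)
}
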