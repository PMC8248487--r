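#' Run the full landscape analysis
#'
#' Orchestrates the end-to-end analysis over a configuration of inputs and
#' writes the report bundle: (1) the merged-variant table, (2) the
#' saturation-enumeration table, (3) the per-position profile (residue,
#' region, local numbering, variant labels, max AF, deleteriousness scores,
#' conservation trace), (4) the per-peptide summary with contrasts against
#' the reference peptide, (5) the stability classification table, and a
#' machine-readable JSON manifest (inputs, md5 checksums, seed, package
#' version). Any stage failure aborts the run, names the stage, and removes
#' partial outputs. A missing score table degrades gracefully to a
#' conservation-only summary with a warning.
#'
#' @param config A list (see [run_config()]) with elements:
#'   `cohort_tables` (named list of observation data.frames or file paths),
#'   `cohorts` (list of [cohort()] when paths are given), `model`
#'   (a [transcript_model()]), `annotation` (a [precursor_annotation()]),
#'   `msa` (aligned sequences, optional), `scores` (score data.frame or
#'   path, optional), `ddg_runs` (replicate table or path, optional),
#'   `reference_peptide`, `n_boot`, `seed`, `out_dir`.
#' @return Invisibly, a list with the in-memory tables
#'   (`merged, enumeration, profile, peptide_summary, contrasts,
#'   stability, manifest`).
#' @export
run_landscape <- function(config) {
  cfg <- config
  stopifnot(!is.null(cfg$out_dir), !is.null(cfg$model), !is.null(cfg$annotation))
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$n_boot)) cfg$n_boot <- 5000
  if (is.null(cfg$reference_peptide)) cfg$reference_peptide <- "glucagon"
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(x, name) {
    p <- file.path(cfg$out_dir, name)
    .write_tsv(x, p)
    written <<- c(written, p)
    p
  }
  stage <- "setup"
  res <- tryCatch({
    # -- aggregate ---------------------------------------------------------
    stage <- "aggregate"
    tabs <- cfg$cohort_tables
    if (length(tabs) && is.character(tabs[[1]])) {
      stopifnot(length(cfg$cohorts) == length(tabs))
      tabs <- lapply(seq_along(tabs), function(i)
        read_cohort_variants(tabs[[i]], "tsv", cfg$cohorts[[i]]))
    }
    merged <- merge_cohorts(tabs)
    stage <- "annotate"
    annotated <- annotate_protein_consequence(merged, cfg$model)
    emit(write_fmt_merged(annotated), "merged_variants.tsv")
    # -- enumerate ---------------------------------------------------------
    stage <- "enumerate"
    enum <- enumerate_possible_missense(cfg$model)
    emit(enum$events, "theoretical_enumeration.tsv")
    # -- conservation ------------------------------------------------------
    stage <- "conserve"
    profile_cons <- NULL
    if (!is.null(cfg$msa)) profile_cons <- conservation_profile(cfg$msa)
    # -- scores ------------------------------------------------------------
    stage <- "scores"
    scores <- cfg$scores
    if (is.character(scores)) scores <- .read_tsv(scores)
    if (is.null(scores))
      warning("no score table supplied; per-peptide summary is conservation-only")
    # -- profile -----------------------------------------------------------
    stage <- "profile"
    profile <- per_position_profile(annotated, cfg$annotation, scores,
                                    profile_cons)
    emit(profile, "per_position_profile.tsv")
    # -- per-peptide summary and contrasts --------------------------------
    stage <- "stats"
    pepsum <- peptide_variant_summary(annotated, cfg$annotation,
                                      include_composites = TRUE)
    emit(pepsum, "peptide_variant_summary.tsv")
    contrasts <- NULL
    if (!is.null(profile_cons)) {
      cons_scores <- data.frame(pos = profile_cons$position,
                                r4s = profile_cons$score)
      contrasts <- contrast_vs_reference(
        cons_scores, cfg$annotation, "r4s",
        reference = cfg$reference_peptide, n_boot = cfg$n_boot,
        seed = derive_seed(cfg$seed, "contrasts"))
      emit(contrasts, "peptide_contrasts.tsv")
    }
    # -- stability ---------------------------------------------------------
    stage <- "stability"
    stab <- NULL
    if (!is.null(cfg$ddg_runs)) {
      runs <- if (is.character(cfg$ddg_runs)) read_ddg_table(cfg$ddg_runs)
              else cfg$ddg_runs
      stab <- stability_records(runs)
      emit(stab, "stability_classification.tsv")
    }
    # -- manifest ----------------------------------------------------------
    stage <- "manifest"
    manifest <- list(
      package = "pepscape",
      version = as.character(utils::packageVersion("pepscape")),
      seed = cfg$seed, n_boot = cfg$n_boot,
      reference_peptide = cfg$reference_peptide,
      transcript_id = cfg$model$transcript_id,
      outputs = lapply(stats::setNames(written, basename(written)),
                       function(p) unname(tools::md5sum(p))))
    mp <- file.path(cfg$out_dir, "run_manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
    written <- c(written, mp)
    list(merged = annotated, enumeration = enum, profile = profile,
         peptide_summary = pepsum, contrasts = contrasts, stability = stab,
         manifest = manifest)
  }, error = function(e) {
    unlink(written)
    .err("pipeline failed at stage `%s`: %s", stage, conditionMessage(e))
  })
  invisible(res)
}

# merged table restricted to its stable on-disk columns
write_fmt_merged <- function(annotated) {
  cols <- intersect(c("pos", "ref", "alt", "max_af", "sharing_class",
                      "is_singleton", "cohorts", "protein_pos", "ref_aa",
                      "alt_aa", "consequence"), names(annotated))
  annotated[, cols, drop = FALSE]
}

#' Per-position landscape profile
#'
#' One row per precursor residue: residue, region and local numbering,
#' number of variants and their labels, max AF, per-position score means,
#' and the conservation trace.
#'
#' @param annotated Annotated merged-variant table (with `protein_pos`,
#'   `ref_aa`, `alt_aa`, `max_af`).
#' @param annotation A [precursor_annotation()].
#' @param scores Optional per-variant score table (`protein_pos`/`pos`,
#'   `cadd_phred`, `primateai`).
#' @param conservation Optional output of [conservation_profile()] indexed
#'   by precursor position.
#' @return Data.frame, one row per residue.
#' @export
per_position_profile <- function(annotated, annotation, scores = NULL,
                                 conservation = NULL) {
  L <- nchar(annotation$protein)
  aa <- strsplit(annotation$protein, "")[[1]]
  prim <- primary_regions(annotation)
  region <- rep("linker", L); local <- rep(NA_integer_, L)
  for (i in seq_len(nrow(prim))) {
    idx <- prim$start[i]:prim$end[i]
    region[idx] <- prim$name[i]
    local[idx] <- idx - prim$start[i] + 1
  }
  out <- data.frame(pos = seq_len(L), aa = aa, region = region,
                    local_pos = local, n_variants = 0L,
                    labels = NA_character_, max_af = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(annotated)) {
    sp <- split(seq_len(nrow(annotated)), annotated$protein_pos)
    for (p in names(sp)) {
      i <- as.integer(p)
      rows <- annotated[sp[[p]], , drop = FALSE]
      out$n_variants[i] <- nrow(rows)
      out$labels[i] <- paste(vapply(seq_len(nrow(rows)), function(k)
        label_variant(i, rows$ref_aa[k], rows$alt_aa[k], annotation),
        character(1)), collapse = ";")
      out$max_af[i] <- max(rows$max_af)
    }
  }
  if (!is.null(scores)) {
    poscol <- if ("protein_pos" %in% names(scores)) "protein_pos" else "pos"
    for (m in intersect(c("cadd_phred", "primateai"), names(scores))) {
      agg <- tapply(scores[[m]], scores[[poscol]], mean, na.rm = TRUE)
      out[[m]] <- NA_real_
      idx <- as.integer(names(agg))
      keep <- idx >= 1 & idx <= L
      out[[m]][idx[keep]] <- as.numeric(agg)[keep]
    }
  }
  if (!is.null(conservation)) {
    idx <- conservation$position
    keep <- idx >= 1 & idx <= L
    for (m in c("score", "smoothed", "ci_low", "ci_high")) {
      out[[paste0("cons_", m)]] <- NA_real_
      out[[paste0("cons_", m)]][idx[keep]] <- conservation[[m]][keep]
    }
  }
  out
}

#' Assemble a run configuration
#'
#' Light validation wrapper for the [run_landscape()] input list.
#'
#' @param ... Named configuration elements (see [run_landscape()]).
#' @return The validated list.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  for (p in Filter(is.character, cfg[intersect(names(cfg),
                                    c("scores", "ddg_runs"))]))
    if (!file.exists(p)) .err("configured input does not exist: %s", p)
  if (!is.null(cfg$cohort_tables) && length(cfg$cohort_tables) &&
      is.character(cfg$cohort_tables[[1]]))
    for (p in unlist(cfg$cohort_tables))
      if (!file.exists(p)) .err("cohort table does not exist: %s", p)
  cfg
}

#' Materialize the bundled fixture files
#'
#' Writes the synthetic preproglucagon-like fixture into a directory:
#' precursor protein FASTA, synthetic CDS FASTA, the region annotation
#' table, and seeded example cohort/score/ddG tables produced by the
#' synthetic generators. All files are plain text in the formats the
#' reading stages consume.
#'
#' @param dir Target directory.
#' @param seed Seed for the example tables.
#' @return Named vector of paths, invisibly.
#' @export
make_fixture <- function(dir, seed = 20210617) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- gcg_annotation()
  model <- synthetic_transcript()
  paths <- c()
  p <- file.path(dir, "precursor_protein.synthetic.fa")
  writeLines(c(">SYNTH_GCG_precursor synthetic preproglucagon-like fixture",
               ann$protein), p)
  paths["protein"] <- p
  p <- file.path(dir, "precursor_cds.synthetic.fa")
  writeLines(c(">SYNTH_GCG_cds synthetic reverse-translated CDS", model$cds), p)
  paths["cds"] <- p
  p <- file.path(dir, "precursor_regions.tsv")
  .write_tsv(ann$regions, p)
  paths["regions"] <- p
  cfg <- sim_config(seed = seed)
  sim <- simulate_cohorts(cfg, model)
  paths <- c(paths, write_simulated_cohorts(sim, dir))
  scores <- simulate_scores(cfg, sim$truth)
  p <- file.path(dir, "scores.tsv")
  .write_tsv(scores, p)
  paths["scores"] <- p
  ddg <- simulate_ddg(cfg, n_subs = 24, complex_id = "glucagon_gcgr")
  p <- file.path(dir, "ddg_runs.tsv")
  .write_tsv(ddg$runs_table, p)
  paths["ddg"] <- p
  invisible(paths)
}
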