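#' Simulation configuration
#'
#' Bundles the parameters of every synthetic-data generator. The defaults
#' echo the observed shape of large multi-cohort missense landscapes: three
#' cohorts at biobank scale, a variant pool at the 184-variant scale of a
#' small hormone gene, close to half of all variants private singletons,
#' non-singleton allele frequencies spread log-uniformly over several
#' decades, gamma-distributed site rates for the orthologue alignment, a
#' deleteriousness-score pair correlated at 0.65, and ten replicate runs
#' per stability scan. One global seed fans out to per-stage substreams via
#' [derive_seed()].
#'
#' @param seed Global integer seed (mandatory).
#' @param cohorts List of [cohort()] objects.
#' @param n_true_variants Number of distinct missense variants in the
#'   simulated union.
#' @param singleton_fraction Fraction of union variants that are
#'   single-cohort singletons.
#' @param af_log10_range Log10-AF bounds for non-singleton variants.
#' @param msa List `n_seqs, n_sites, gamma_shape, gamma_scale`.
#' @param score_model List `target_pearson, conservation_coupling,
#'   cadd_mean, cadd_sd`.
#' @param ddg_model List `n_runs, run_sd`.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed,
                       cohorts = list(
                         cohort("gnomad", 135743, "exome"),
                         cohort("ukb", 200629, "exome"),
                         cohort("topmed", 132345, "genome")),
                       n_true_variants = 184,
                       singleton_fraction = 0.47,
                       af_log10_range = c(-5.5, -2.5),
                       msa = list(n_seqs = 100, n_sites = 200,
                                  gamma_shape = 2, gamma_scale = 0.5),
                       score_model = list(target_pearson = 0.65,
                                          conservation_coupling = 0.55,
                                          cadd_mean = 21.9, cadd_sd = 5.5),
                       ddg_model = list(n_runs = 10, run_sd = 0.3)) {
  if (missing(seed)) .err("`seed` is mandatory")
  stopifnot(singleton_fraction >= 0, singleton_fraction <= 1,
            n_true_variants >= 1, length(cohorts) >= 1)
  nm <- vapply(cohorts, function(co) co$name, character(1))
  if (anyDuplicated(nm)) .err("cohort names must be unique")
  structure(list(seed = seed, cohorts = cohorts,
                 n_true_variants = n_true_variants,
                 singleton_fraction = singleton_fraction,
                 af_log10_range = af_log10_range, msa = msa,
                 score_model = score_model, ddg_model = ddg_model),
            class = "sim_config")
}

#' Synthetic coding sequence for a precursor
#'
#' Deterministically reverse-translates a precursor protein into a CDS
#' (most common human codon per residue, TAA stop), yielding a synthetic
#' transcript model whose translation matches the protein exactly.
#'
#' @param protein Amino-acid string (defaults to the built-in
#'   preproglucagon-like fixture).
#' @param transcript_id Identifier.
#' @return A [transcript_model()].
#' @export
synthetic_transcript <- function(protein = gcg_annotation()$protein,
                                 transcript_id = "SYNTH_GCG") {
  pref <- c(A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC", G = "GGC",
            H = "CAC", I = "ATC", K = "AAG", L = "CTG", M = "ATG", N = "AAC",
            P = "CCC", Q = "CAG", R = "CGG", S = "AGC", T = "ACC", V = "GTG",
            W = "TGG", Y = "TAC")
  aas <- strsplit(protein, "")[[1]]
  bad <- setdiff(aas, names(pref))
  if (length(bad)) .err("protein contains unsupported residues: %s",
                        paste(unique(bad), collapse = ", "))
  transcript_model(paste0(paste(pref[aas], collapse = ""), "TAA"),
                   transcript_id)
}

#' Simulate per-cohort variant tables with known truth
#'
#' Draws a union of distinct missense-capable SNVs from the transcript's
#' saturation enumeration, marks a configurable fraction as singletons
#' (one allele in one cohort), assigns the remainder to random non-empty
#' cohort subsets with log-uniform allele frequencies, and emits one
#' observation table per cohort plus a truth record (intended union,
#' sharing classes, singleton flags) sufficient to score the merge stage
#' without external files.
#'
#' @param config A [sim_config()].
#' @param model A [transcript_model()] (default: the synthetic fixture
#'   transcript).
#' @return List with `cohort_tables` (named list of observation
#'   data.frames), `truth` (data.frame `pos, ref, alt, sharing_class,
#'   is_singleton, max_af`), and `cohorts`.
#' @export
simulate_cohorts <- function(config, model = synthetic_transcript()) {
  enum <- enumerate_possible_missense(model)
  mis <- enum$events[enum$events$consequence == "missense", , drop = FALSE]
  mis <- mis[!(mis$codon_index == 1 & mis$ref_aa == "M"), , drop = FALSE]
  if (config$n_true_variants > nrow(mis))
    .err("n_true_variants (%d) exceeds available missense sites (%d)",
         config$n_true_variants, nrow(mis))
  ncoh <- length(config$cohorts)
  names_coh <- vapply(config$cohorts, function(co) co$name, character(1))
  an <- stats::setNames(vapply(config$cohorts,
                               function(co) 2 * co$n_individuals, numeric(1)),
                        names_coh)
  with_seed(derive_seed(config$seed, "cohorts"), {
    pick <- mis[sample.int(nrow(mis), config$n_true_variants), , drop = FALSE]
    rownames(pick) <- NULL
    n <- nrow(pick)
    is_single <- rep(FALSE, n)
    is_single[sample.int(n, round(config$singleton_fraction * n))] <- TRUE
    member <- matrix(FALSE, n, ncoh, dimnames = list(NULL, names_coh))
    for (i in seq_len(n)) {
      if (is_single[i]) {
        member[i, sample.int(ncoh, 1)] <- TRUE
      } else {
        k <- sample.int(ncoh, 1)
        member[i, sample.int(ncoh, k)] <- TRUE
      }
    }
    lo <- config$af_log10_range[1]; hi <- config$af_log10_range[2]
    tabs <- list(); max_af <- numeric(n)
    acs <- matrix(0, n, ncoh, dimnames = list(NULL, names_coh))
    for (j in seq_len(ncoh)) {
      idx <- which(member[, j])
      ac <- integer(length(idx))
      for (k in seq_along(idx)) {
        i <- idx[k]
        if (is_single[i]) ac[k] <- 1L
        else {
          af <- 10^stats::runif(1, lo, hi)
          ac[k] <- max(2L, as.integer(round(af * an[j])))
        }
      }
      acs[idx, j] <- ac
      tabs[[names_coh[j]]] <- structure(
        data.frame(cohort = names_coh[j], pos = pick$cds_pos[idx],
                   ref = pick$ref[idx], alt = pick$alt[idx], ac = ac,
                   an = unname(an[j]), af = ac / unname(an[j]),
                   is_singleton = ac == 1L, stringsAsFactors = FALSE),
        coord = "cds")
    }
    for (i in seq_len(n))
      max_af[i] <- max(acs[i, member[i, ]] / an[member[i, ]])
    truth <- data.frame(pos = pick$cds_pos, ref = pick$ref, alt = pick$alt,
                        protein_pos = pick$codon_index,
                        ref_aa = pick$ref_aa, alt_aa = pick$alt_aa,
                        sharing_class = as.integer(rowSums(member)),
                        is_singleton = is_single, max_af = max_af,
                        stringsAsFactors = FALSE)
    truth <- truth[order(truth$pos, truth$ref, truth$alt), , drop = FALSE]
    rownames(truth) <- NULL
    list(cohort_tables = tabs, truth = truth, cohorts = config$cohorts)
  })
}

#' Simulate an orthologue alignment with known site rates
#'
#' Draws per-site rates from a gamma law, evolves each sequence
#' independently from a common ancestor with substitution probability
#' `1 - exp(-rate)` per site (a single-branch Poisson model), and returns
#' the alignment together with the true rates. Fast sites accumulate many
#' non-consensus residues; near-zero-rate sites stay invariant.
#'
#' @param config A [sim_config()] (uses the `msa` block and seed).
#' @return List `msa` (named character vector of aligned sequences),
#'   `true_rates` (numeric), `ancestor`.
#' @export
simulate_msa <- function(config) {
  m <- config$msa
  if (m$n_seqs < 3) .err("need n_seqs >= 3")
  with_seed(derive_seed(config$seed, "msa"), {
    rates <- stats::rgamma(m$n_sites, shape = m$gamma_shape,
                           scale = m$gamma_scale)
    anc <- sample(.AA20, m$n_sites, replace = TRUE)
    p_sub <- 1 - exp(-rates)
    seqs <- vapply(seq_len(m$n_seqs), function(s) {
      mut <- stats::runif(m$n_sites) < p_sub
      res <- anc
      if (any(mut))
        res[mut] <- vapply(res[mut], function(a)
          sample(setdiff(.AA20, a), 1), character(1))
      paste(res, collapse = "")
    }, character(1))
    names(seqs) <- sprintf("orth_%03d", seq_len(m$n_seqs))
    list(msa = seqs, true_rates = rates, ancestor = paste(anc, collapse = ""))
  })
}

#' Simulate correlated deleteriousness scores
#'
#' Generates a CADD-like and a PrimateAI-like score per variant as a
#' bivariate Gaussian pair with a target correlation, both coupled to the
#' (negated) conservation truth so that conserved positions score as more
#' deleterious. The Gaussian pair is then mapped to a CADD-like scale
#' (affine, floored at 0) and a PrimateAI-like scale (probit to [0,1]);
#' the monotone maps shrink the realized Pearson correlation only
#' slightly.
#'
#' @param config A [sim_config()].
#' @param variants Data.frame with `protein_pos` (e.g. the truth record of
#'   [simulate_cohorts()]).
#' @param conservation Optional numeric vector of per-position conservation
#'   scores (lower = conserved) indexed by position; when given, scores
#'   couple to it with weight `conservation_coupling`.
#' @return Data.frame `pos, ref, alt, protein_pos, cadd_phred, primateai`.
#' @export
simulate_scores <- function(config, variants, conservation = NULL) {
  sm <- config$score_model
  if (abs(sm$target_pearson) >= 1) .err("target_pearson must be in (-1, 1)")
  n <- nrow(variants)
  with_seed(derive_seed(config$seed, "scores"), {
    alpha <- if (is.null(conservation)) 0 else sm$conservation_coupling
    base <- if (is.null(conservation)) rep(0, n) else {
      cz <- conservation[variants$protein_pos]
      cz[is.na(cz)] <- 0
      -scale(cz)[, 1]
    }
    w <- alpha * base + sqrt(1 - alpha^2) * stats::rnorm(n)
    r <- sm$target_pearson
    e <- stats::rnorm(n)
    z2 <- r * w + sqrt(1 - r^2) * (alpha * base + sqrt(1 - alpha^2) * e)
    cadd <- pmax(0, sm$cadd_mean + sm$cadd_sd * w)
    pai <- stats::pnorm(z2)
    out <- data.frame(pos = variants$pos, ref = variants$ref,
                      alt = variants$alt,
                      protein_pos = variants$protein_pos,
                      cadd_phred = cadd, primateai = pai,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Simulate replicate ddG tables with known categories
#'
#' Each substitution gets a true mean stability change; replicate runs add
#' Gaussian noise with `run_sd`. The truth record carries the category
#' implied by the true mean, so classification recovery can be scored.
#'
#' @param config A [sim_config()].
#' @param true_means Named numeric vector (names `"ref|pos|alt"` optional)
#'   of true mean ddG values; default draws `n_subs` uniformly in
#'   [-3, 4].
#' @param n_subs Number of substitutions when `true_means` is not given.
#' @param complex_id Complex label for the table.
#' @param bins A [stability_bins()].
#' @return List `runs_table` (`complex_id, position, ref, alt, run_index,
#'   ddg`) and `truth` (`position, ref, alt, true_mean, true_category`).
#' @export
simulate_ddg <- function(config, true_means = NULL, n_subs = 50,
                         complex_id = "ligand_receptor",
                         bins = stability_bins()) {
  dm <- config$ddg_model
  if (dm$n_runs < 1) .err("n_runs must be >= 1")
  with_seed(derive_seed(config$seed, "ddg"), {
    if (is.null(true_means))
      true_means <- stats::runif(n_subs, -3, 4)
    n <- length(true_means)
    ref <- sample(.AA20, n, replace = TRUE)
    alt <- vapply(ref, function(a) sample(setdiff(.AA20, a), 1), character(1))
    pos <- seq_len(n)
    runs <- data.frame(
      complex_id = complex_id,
      position = rep(pos, each = dm$n_runs),
      ref = rep(ref, each = dm$n_runs),
      alt = rep(alt, each = dm$n_runs),
      run_index = rep(seq_len(dm$n_runs), times = n),
      ddg = rep(true_means, each = dm$n_runs) +
        stats::rnorm(n * dm$n_runs, 0, dm$run_sd),
      stringsAsFactors = FALSE)
    truth <- data.frame(position = pos, ref = ref, alt = alt,
                        true_mean = true_means,
                        true_category = as.character(
                          classify_ddg(true_means, bins)),
                        stringsAsFactors = FALSE)
    list(runs_table = runs, truth = truth)
  })
}

#' Write simulated cohorts to disk
#'
#' One tab-delimited observation file per cohort (`<dir>/<name>.tsv`) and
#' a JSON truth record, in the formats the reading/merging stage consumes.
#'
#' @param sim Output of [simulate_cohorts()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_simulated_cohorts <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in names(sim$cohort_tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    .write_tsv(sim$cohort_tables[[nm]][, c("pos", "ref", "alt", "ac", "an",
                                           "af")], p)
    paths[nm] <- p
  }
  if (!is.null(sim$truth)) {
    tp <- file.path(dir, "truth.json")
    jsonlite::write_json(sim$truth, tp, digits = NA)
    paths["truth"] <- tp
  }
  invisible(paths)
}
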