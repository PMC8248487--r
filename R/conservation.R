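#' Filter orthologues by alignment-quality metrics
#'
#' Keeps orthologue records passing all three Ensembl-Compara style
#' quality thresholds: Gene Order Conservation (GOC) score, Whole Genome
#' Alignment (WGA) coverage, and percent identity. Thresholds are
#' boundary-inclusive ("a minimum of 50" retains 50).
#'
#' @param records Data.frame with columns `species, goc, wga, pid` (and
#'   optionally `sequence`).
#' @param min_goc,min_wga,min_pid Minimum acceptable values
#'   (defaults 50, 50, 25).
#' @param on_missing `"warn"` (reject the record with a warning) or
#'   `"error"`.
#' @return The retained subset, same columns.
#' @export
filter_orthologues <- function(records, min_goc = 50, min_wga = 50,
                               min_pid = 25, on_missing = c("warn", "error")) {
  on_missing <- match.arg(on_missing)
  need <- c("goc", "wga", "pid")
  miss_col <- setdiff(need, names(records))
  if (length(miss_col))
    .err("orthologue table missing columns: %s", paste(miss_col, collapse = ", "))
  incomplete <- !stats::complete.cases(records[, need])
  if (any(incomplete)) {
    msg <- sprintf("%d orthologue record(s) with missing QC metrics", sum(incomplete))
    if (on_missing == "error") .err(msg) else warning(msg, ": rejected")
  }
  keep <- !incomplete & records$goc >= min_goc & records$wga >= min_wga &
    records$pid >= min_pid
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Henikoff position-based sequence weights on an alignment character matrix
.henikoff_weights <- function(mat) {
  n <- nrow(mat)
  w <- numeric(n)
  ncols <- 0L
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    res <- col[col != "-"]
    if (!length(res)) next
    ncols <- ncols + 1L
    tab <- table(res)
    k <- length(tab)
    contrib <- 1 / (k * as.numeric(tab[col]))
    contrib[col == "-"] <- 0
    w <- w + contrib
  }
  if (ncols == 0L) return(rep(1 / n, n))
  w <- w / ncols
  w / sum(w)
}

#' Estimate per-site relative evolutionary rates from an MSA
#'
#' The built-in estimator is a sequence-weighted substitution-diversity
#' measure: each aligned sequence receives a Henikoff position-based weight
#' (so clusters of near-identical orthologues do not dominate), and a
#' column's raw rate is the weighted fraction of non-gap residues that
#' differ from the column's weighted consensus. Invariant columns receive
#' the alignment's minimum rate; all-gap columns are `NA`. Columns with
#' more than half gaps are flagged low-confidence. This is deliberately a
#' tree-free estimator; exact reproduction of tree-based empirical-Bayes
#' rates (Rate4Site/ConSurf output) is available through
#' [read_external_rates()].
#'
#' @param msa Aligned sequences: a character vector, a named list, or an
#'   `AAStringSet`; all the same length, gaps as `-`.
#' @param method `"weighted_count"` (built-in) — use
#'   [read_external_rates()] for externally computed rates.
#' @return Data.frame `position, raw_rate, n_nongap, low_confidence`.
#' @export
estimate_site_rates <- function(msa, method = c("weighted_count")) {
  method <- match.arg(method)
  if (inherits(msa, "XStringSet")) msa <- as.character(msa)
  if (is.list(msa)) msa <- unlist(msa)
  if (length(msa) < 3) .err("need at least 3 aligned sequences")
  lens <- nchar(msa)
  if (length(unique(lens)) != 1)
    .err("ragged alignment: sequence lengths %s", paste(unique(lens), collapse = ", "))
  mat <- do.call(rbind, strsplit(toupper(msa), ""))
  w <- .henikoff_weights(mat)
  L <- ncol(mat)
  raw <- numeric(L); nng <- integer(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    ok <- col != "-" & col != "."
    nng[j] <- sum(ok)
    if (!any(ok)) { raw[j] <- NA_real_; next }
    wk <- w[ok]
    tot <- tapply(wk, col[ok], sum)
    cons <- names(tot)[which.max(tot)]
    raw[j] <- sum(wk[col[ok] != cons]) / sum(wk)
  }
  mn <- suppressWarnings(min(raw, na.rm = TRUE))
  raw[!is.na(raw) & raw == 0] <- mn
  data.frame(position = seq_len(L), raw_rate = raw, n_nongap = nng,
             low_confidence = nng < length(msa) / 2)
}

#' Normalize conservation scores
#'
#' Default mode `"z"` standardizes the raw rates to mean 0 and standard
#' deviation 1 (population denominator), so lower scores mean stronger
#' conservation. Mode `"min_neg1"` additionally rescales the z-scores so
#' the most conserved position sits exactly at -1, a display convention
#' used by some conservation servers; the two conventions are mutually
#' inconsistent in general, so the mode is explicit.
#'
#' @param raw_rate Numeric vector (NA allowed).
#' @param mode `"z"` or `"min_neg1"`.
#' @return Numeric vector of normalized scores, NAs preserved.
#' @export
normalize_scores <- function(raw_rate, mode = c("z", "min_neg1")) {
  mode <- match.arg(mode)
  ok <- !is.na(raw_rate)
  if (sum(ok) < 2) .err("need at least 2 non-missing rates")
  x <- raw_rate[ok]
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0)
    .err("zero variance: all rates identical (degenerate constant input)")
  z <- (x - mean(x)) / s
  if (mode == "min_neg1") z <- z / abs(min(z))
  out <- rep(NA_real_, length(raw_rate))
  out[ok] <- z
  out
}

#' Gaussian-smoothed conservation trace with a 50% band
#'
#' Convolves the per-position scores with a discrete Gaussian kernel
#' (truncated at 4 sigma and renormalized) under reflect boundary handling,
#' and reports a 50% interval band `smoothed +/- 0.6745 * local sd`, where
#' the local sd is computed under the same kernel weights.
#'
#' @param scores Numeric vector (no NAs; interpolate or drop first).
#' @param sigma Kernel standard deviation in residues (> 0), default 1.
#' @return Data.frame `position, smoothed, ci_low, ci_high`.
#' @export
smooth_trace <- function(scores, sigma = 1.0) {
  if (sigma <= 0) .err("sigma must be > 0")
  if (anyNA(scores)) .err("scores contain NA; handle missing positions first")
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  n <- length(scores)
  # reflect boundary: ... c b a | a b c ... (edge duplicated), period 2n
  refl <- function(i) {
    j <- (i - 1) %% (2 * n)
    j <- ifelse(j < 0, j + 2 * n, j)
    ifelse(j < n, j + 1, 2 * n - j)
  }
  idx <- refl(seq(1 - r, n + r))
  conv <- function(x) stats::filter(x[idx], k, sides = 2)[r + seq_len(n)]
  sm <- conv(scores)
  m2 <- conv(scores^2)
  lsd <- sqrt(pmax(m2 - sm^2, 0))
  q50 <- stats::qnorm(0.75) # 0.6745: half-width of the central 50% mass
  data.frame(position = seq_len(n), smoothed = as.numeric(sm),
             ci_low = as.numeric(sm - q50 * lsd),
             ci_high = as.numeric(sm + q50 * lsd))
}

#' Read externally computed per-site rates
#'
#' Adapter for per-position score files produced by external conservation
#' servers (e.g. Rate4Site output), for exact reproduction of published
#' traces. Expects a delimited table with columns `pos` and `score` (extra
#' columns ignored).
#'
#' @param path Score file.
#' @param protein_length If given, the file must cover exactly this many
#'   positions.
#' @return Data.frame `position, score`.
#' @export
read_external_rates <- function(path, protein_length = NULL) {
  tab <- .read_tsv(path)
  if (!all(c("pos", "score") %in% names(tab)))
    .err("%s: expected columns `pos` and `score`", path)
  if (anyDuplicated(tab$pos))
    .err("%s: duplicate positions: %s", path,
         paste(utils::head(tab$pos[duplicated(tab$pos)], 5), collapse = ", "))
  if (!is.null(protein_length) && nrow(tab) != protein_length)
    .err("%s: %d positions but protein has %d residues", path, nrow(tab),
         protein_length)
  out <- data.frame(position = as.integer(tab$pos), score = as.numeric(tab$score))
  out[order(out$position), , drop = FALSE]
}

#' Full per-position conservation profile
#'
#' Convenience wrapper: estimate raw rates, normalize, smooth.
#'
#' @param msa Aligned sequences (see [estimate_site_rates()]).
#' @param sigma Smoothing sigma.
#' @param mode Normalization mode, see [normalize_scores()].
#' @return Data.frame `position, raw_rate, score, smoothed, ci_low,
#'   ci_high, low_confidence`.
#' @export
conservation_profile <- function(msa, sigma = 1.0, mode = "z") {
  rates <- estimate_site_rates(msa)
  score <- normalize_scores(rates$raw_rate, mode = mode)
  filled <- score
  if (anyNA(filled)) filled[is.na(filled)] <- mean(filled, na.rm = TRUE)
  sm <- smooth_trace(filled, sigma = sigma)
  data.frame(position = rates$position, raw_rate = rates$raw_rate,
             score = score, smoothed = sm$smoothed, ci_low = sm$ci_low,
             ci_high = sm$ci_high, low_confidence = rates$low_confidence)
}
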