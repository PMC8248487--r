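#' Default stability classification bins
#'
#' Ordered thresholds, in kcal/mol, for classifying mean stability changes
#' of a receptor-ligand complex upon mutation. The default scheme is the
#' widely used 0.46/0.92/1.84 ladder (roughly 1, 2 and 4 times the typical
#' force-field error): values above +1.84 are highly destabilizing, the
#' neutral band is (-0.46, +0.46), and the stabilizing side mirrors the
#' destabilizing side, including a `highly_stabilizing` bin below -1.84
#' implied by symmetry.
#'
#' @param thresholds Decreasing numeric vector of six cut points.
#' @return An object of class `"stability_bins"`: list with `thresholds`
#'   and ordered `categories` (most stabilizing first ... most
#'   destabilizing last).
#' @export
stability_bins <- function(thresholds = c(1.84, 0.92, 0.46, -0.46, -0.92, -1.84)) {
  if (length(thresholds) != 6 || is.unsorted(rev(thresholds), strictly = TRUE))
    .err("thresholds must be six strictly decreasing values")
  structure(list(
    thresholds = thresholds,
    categories = c("highly_stabilizing", "stabilizing", "slightly_stabilizing",
                   "neutral", "slightly_destabilizing", "destabilizing",
                   "highly_destabilizing")),
    class = "stability_bins")
}

#' Classify a mean stability change
#'
#' Assigns each mean ddG to an ordered category. The top bin is strict
#' (`> +1.84` is highly destabilizing, so exactly +1.84 is destabilizing);
#' at interior positive thresholds a boundary value goes to the more
#' destabilizing of the two adjacent bins, and negative thresholds mirror
#' this (a boundary value goes to the more stabilizing bin). The bins
#' partition the real line.
#'
#' @param mean_ddg Numeric vector of mean stability changes (kcal/mol).
#' @param bins A [stability_bins()].
#' @return Ordered factor of categories.
#' @export
#' @examples
#' classify_ddg(c(6.74, 1.19, 0))
classify_ddg <- function(mean_ddg, bins = stability_bins()) {
  if (any(is.na(mean_ddg) | !is.finite(mean_ddg)))
    .err("mean_ddg contains NA/NaN/Inf")
  t <- bins$thresholds # c(1.84, 0.92, 0.46, -0.46, -0.92, -1.84)
  cat_idx <- vapply(mean_ddg, function(x) {
    if (x > t[1]) 7L          # highly_destabilizing: (+1.84, Inf)
    else if (x >= t[2]) 6L    # destabilizing:        [+0.92, +1.84]
    else if (x >= t[3]) 5L    # slightly_destab.:     [+0.46, +0.92)
    else if (x > t[4]) 4L     # neutral:              (-0.46, +0.46)
    else if (x > t[5]) 3L     # slightly_stab.:       (-0.92, -0.46]
    else if (x >= t[6]) 2L    # stabilizing:          [-1.84, -0.92]
    else 1L                   # highly_stabilizing:   (-Inf, -1.84)
  }, integer(1))
  factor(bins$categories[cat_idx], levels = bins$categories, ordered = TRUE)
}

#' Aggregate replicate ddG runs
#'
#' Mean and sample standard deviation (n-1 denominator; 0 for a single
#' run) of the replicate stability-change estimates for one substitution.
#' Repeated independent runs are needed because the underlying rotamer
#' search is stochastic, especially for large side chains.
#'
#' @param runs Numeric vector of per-run ddG values (kcal/mol).
#' @return List `mean, sd, n`.
#' @export
aggregate_runs <- function(runs) {
  if (!length(runs)) .err("no runs supplied")
  list(mean = mean(runs), sd = if (length(runs) > 1) stats::sd(runs) else 0,
       n = length(runs))
}

#' Read a replicate ddG table
#'
#' Tab-delimited `complex_id position ref alt run_index ddg`, one row per
#' run per substitution.
#'
#' @param path File path.
#' @return Data.frame as on disk.
#' @export
read_ddg_table <- function(path) {
  tab <- .read_tsv(path)
  need <- c("complex_id", "position", "ref", "alt", "run_index", "ddg")
  miss <- setdiff(need, names(tab))
  if (length(miss)) .err("%s: missing columns: %s", path,
                         paste(miss, collapse = ", "))
  tab
}

#' Aggregate and classify a replicate ddG table
#'
#' @param runs_table Data.frame `complex_id, position, ref, alt,
#'   run_index, ddg` (from [read_ddg_table()] or [simulate_ddg()]).
#' @param bins A [stability_bins()].
#' @return Data.frame `complex_id, position, ref, alt, substitution,
#'   n_runs, mean_ddg, sd_ddg, category`, one row per substitution.
#' @export
stability_records <- function(runs_table, bins = stability_bins()) {
  key <- paste(runs_table$complex_id, runs_table$position, runs_table$ref,
               runs_table$alt, sep = "|")
  sp <- split(seq_len(nrow(runs_table)), key)
  out <- do.call(rbind, lapply(sp, function(idx) {
    o <- runs_table[idx, , drop = FALSE]
    ag <- aggregate_runs(o$ddg)
    data.frame(complex_id = o$complex_id[1], position = o$position[1],
               ref = o$ref[1], alt = o$alt[1],
               substitution = sprintf("%s%d%s", o$ref[1], o$position[1],
                                      o$alt[1]),
               n_runs = ag$n, mean_ddg = ag$mean, sd_ddg = ag$sd,
               stringsAsFactors = FALSE)
  }))
  out$category <- classify_ddg(out$mean_ddg, bins)
  out <- out[order(out$complex_id, out$position, out$ref, out$alt), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Highly destabilizing hotspots
#'
#' Substitutions whose mean ddG exceeds the threshold (default +1.84
#' kcal/mol, the highly-destabilizing cut), sorted most destabilizing
#' first.
#'
#' @param records Output of [stability_records()].
#' @param threshold Strict lower bound in kcal/mol.
#' @return Subset of `records`, sorted by decreasing `mean_ddg`.
#' @export
hotspot_list <- function(records, threshold = 1.84) {
  hs <- records[records$mean_ddg > threshold, , drop = FALSE]
  hs <- hs[order(-hs$mean_ddg), , drop = FALSE]
  rownames(hs) <- NULL
  hs
}

#' Join natural variants with alanine-scan and literature data
#'
#' Outer-joins, per `(complex_id, position)`, the aggregated ddG of the
#' natural variant, the alanine substitution at the same position, and any
#' literature fold-change annotations (`position mutant fold_ic50
#' fold_ec50 source`). A discordance flag marks positions where the
#' natural variant and the alanine substitution fall on opposite sides of
#' neutral (one destabilizing, the other stabilizing).
#'
#' @param variant_records,alanine_records Outputs of
#'   [stability_records()]; `alanine_records` may be NULL.
#' @param literature Optional data.frame `position, mutant, fold_ic50,
#'   fold_ec50, source`.
#' @return Joined data.frame, one row per (complex, position) present in
#'   either record set.
#' @export
compare_ala_scan <- function(variant_records, alanine_records = NULL,
                             literature = NULL) {
  vk <- paste(variant_records$complex_id, variant_records$position)
  if (anyDuplicated(vk))
    .err("duplicate (complex, position) keys in variant records: %s",
         paste(utils::head(vk[duplicated(vk)], 3), collapse = "; "))
  v <- data.frame(complex_id = variant_records$complex_id,
                  position = variant_records$position,
                  variant = variant_records$substitution,
                  variant_ddg = variant_records$mean_ddg,
                  variant_category = as.character(variant_records$category),
                  stringsAsFactors = FALSE)
  if (!is.null(alanine_records)) {
    ak <- paste(alanine_records$complex_id, alanine_records$position)
    if (anyDuplicated(ak))
      .err("duplicate (complex, position) keys in alanine records")
    a <- data.frame(complex_id = alanine_records$complex_id,
                    position = alanine_records$position,
                    ala_ddg = alanine_records$mean_ddg,
                    ala_category = as.character(alanine_records$category),
                    stringsAsFactors = FALSE)
    out <- merge(v, a, by = c("complex_id", "position"), all = TRUE)
  } else {
    out <- v
    out$ala_ddg <- NA_real_
    out$ala_category <- NA_character_
  }
  if (!is.null(literature) && nrow(literature)) {
    out <- merge(out, literature, by = "position", all.x = TRUE)
  } else {
    out$mutant <- NA_character_
    out$fold_ic50 <- NA_real_
    out$fold_ec50 <- NA_real_
    out$source <- NA_character_
  }
  out$discordant <- !is.na(out$variant_ddg) & !is.na(out$ala_ddg) &
    sign(out$variant_ddg) != sign(out$ala_ddg) &
    (abs(out$variant_ddg) > 0.46 & abs(out$ala_ddg) > 0.46)
  out <- out[order(out$complex_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
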