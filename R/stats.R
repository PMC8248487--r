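#' Per-peptide score aggregation
#'
#' Means of each deleteriousness/conservation metric within each primary
#' region of the precursor, over non-missing values, with per-metric n.
#' Conservation scores are per-position quantities; CADD and PrimateAI are
#' per-variant quantities — both kinds of table work, as aggregation is by
#' the `pos`/`protein_pos` column.
#'
#' @param scores Data.frame with a position column (`protein_pos` or `pos`)
#'   and one or more numeric metric columns (e.g. `cadd_phred, primateai,
#'   r4s`).
#' @param annotation A [precursor_annotation()].
#' @param metrics Metric column names; default: all numeric columns except
#'   the position column.
#' @return Data.frame with one row per primary region (plus `linker`):
#'   `region`, then `mean_<metric>` and `n_<metric>` pairs.
#' @export
peptide_score_summary <- function(scores, annotation, metrics = NULL) {
  poscol <- if ("protein_pos" %in% names(scores)) "protein_pos" else "pos"
  if (!poscol %in% names(scores)) .err("scores need a `protein_pos` or `pos` column")
  if (is.null(metrics)) {
    metrics <- names(scores)[vapply(scores, is.numeric, logical(1))]
    metrics <- setdiff(metrics, c(poscol, "pos", "ref", "alt", "max_af",
                                  "sharing_class"))
  }
  prim <- primary_regions(annotation)
  covered <- unlist(lapply(seq_len(nrow(prim)),
                           function(i) prim$start[i]:prim$end[i]))
  linker <- setdiff(seq_len(nchar(annotation$protein)), covered)
  groups <- c(stats::setNames(lapply(seq_len(nrow(prim)), function(i)
    prim$start[i]:prim$end[i]), prim$name), list(linker = linker))
  rows <- lapply(names(groups), function(g) {
    mask <- scores[[poscol]] %in% groups[[g]]
    row <- data.frame(region = g, stringsAsFactors = FALSE)
    for (m in metrics) {
      v <- scores[[m]][mask]
      v <- v[!is.na(v)]
      row[[paste0("mean_", m)]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0("n_", m)]] <- length(v)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. For small problems
#' (`n_a + n_b <= exact_limit`, default 12) the p-value is computed by
#' exact enumeration of all ways to assign the pooled observations to the
#' two groups, which handles ties exactly; larger problems use the normal
#' approximation with tie-corrected variance and continuity correction.
#' `U_a + U_b = n_a * n_b` always. The two-sided exact p is the probability
#' of a U at least as far from its null mean as observed.
#'
#' @param a,b Numeric samples.
#' @param alternative `"two_sided"`, `"less"` (a shifted below b), or
#'   `"greater"`.
#' @param exact_limit Largest pooled size for exact enumeration.
#' @return List with `u` (U statistic of sample `a`), `u_b`, `p_value`,
#'   `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6), "less")$p_value  # exactly 0.05
mann_whitney <- function(a, b, alternative = c("two_sided", "less", "greater"),
                         exact_limit = 12) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) .err("both samples must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_a <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  u_b <- na * nb - u_a
  mu <- na * nb / 2
  if (n <= exact_limit) {
    combs <- utils::combn(n, na)
    us <- apply(combs, 2, function(idx) sum(rk[idx]) - na * (na + 1) / 2)
    eps <- 1e-9
    p <- switch(alternative,
      two_sided = mean(abs(us - mu) >= abs(u_a - mu) - eps),
      less = mean(us <= u_a + eps),
      greater = mean(us >= u_a - eps))
    method <- "exact enumeration"
  } else {
    ties <- table(rk)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      cc <- 0.5
      z_two <- (abs(u_a - mu) - cc) / sqrt(sig2)
      p <- switch(alternative,
        two_sided = 2 * stats::pnorm(max(z_two, 0), lower.tail = FALSE),
        less = stats::pnorm((u_a - mu + cc) / sqrt(sig2)),
        greater = stats::pnorm((u_a - mu - cc) / sqrt(sig2),
                               lower.tail = FALSE))
      p <- min(p, 1)
    }
    method <- "normal approximation (tie-corrected)"
  }
  list(u = u_a, u_b = u_b, p_value = p, method = method)
}

#' Bootstrap mean-difference estimate
#'
#' Estimation-statistics style contrast: the point estimate is
#' `mean(b) - mean(a)` exactly; the interval is a percentile (default) or
#' BCa bootstrap over `n_boot` paired resamples. Deterministic given
#' `seed`.
#'
#' @param a,b Numeric samples (each of length >= 2).
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param seed Integer seed (required for reproducibility).
#' @param conf Confidence level (default 0.95).
#' @param ci `"percentile"` or `"bca"`.
#' @return List `mean_a, mean_b, mean_diff, ci_low, ci_high, n_boot, seed,
#'   conf`.
#' @export
bootstrap_mean_diff <- function(a, b, n_boot = 5000, seed, conf = 0.95,
                                ci = c("percentile", "bca")) {
  ci <- match.arg(ci)
  if (length(a) < 2 || length(b) < 2) .err("need >= 2 values per sample")
  if (missing(seed)) .err("`seed` is required")
  na <- length(a); nb <- length(b)
  diff_obs <- mean(b) - mean(a)
  boots <- with_seed(seed, {
    ia <- matrix(sample.int(na, na * n_boot, replace = TRUE), nrow = n_boot)
    ib <- matrix(sample.int(nb, nb * n_boot, replace = TRUE), nrow = n_boot)
    rowMeans(matrix(b[ib], nrow = n_boot)) -
      rowMeans(matrix(a[ia], nrow = n_boot))
  })
  alpha <- (1 - conf) / 2
  if (ci == "percentile") {
    qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
  } else {
    z0 <- stats::qnorm(mean(boots < diff_obs) +
                         0.5 * mean(boots == diff_obs))
    # jackknife acceleration
    jk <- c(vapply(seq_len(na), function(i) mean(b) - mean(a[-i]), numeric(1)),
            vapply(seq_len(nb), function(i) mean(b[-i]) - mean(a), numeric(1)))
    jm <- mean(jk)
    acc_den <- sum((jm - jk)^2)^1.5
    acc <- if (acc_den == 0) 0 else sum((jm - jk)^3) / (6 * acc_den)
    zl <- stats::qnorm(alpha); zu <- stats::qnorm(1 - alpha)
    a1 <- stats::pnorm(z0 + (z0 + zl) / (1 - acc * (z0 + zl)))
    a2 <- stats::pnorm(z0 + (z0 + zu) / (1 - acc * (z0 + zu)))
    if (!is.finite(z0)) { a1 <- alpha; a2 <- 1 - alpha }
    qs <- stats::quantile(boots, c(a1, a2), names = FALSE, type = 7)
  }
  list(mean_a = mean(a), mean_b = mean(b), mean_diff = diff_obs,
       ci_low = qs[1], ci_high = qs[2], n_boot = n_boot, seed = seed,
       conf = conf)
}

#' Pearson correlation with pairwise-complete handling
#'
#' @param x,y Numeric vectors of equal length; pairs with any NA are
#'   dropped.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) .err("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) .err("need >= 3 complete pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    .err("zero variance in one of the inputs")
  stats::cor(x[ok], y[ok])
}

#' Contrast every peptide against a reference peptide
#'
#' For each primary peptide other than the reference, compares the metric's
#' values (per-position for conservation scores, per-variant for CADD and
#' PrimateAI — set by `unit`) against the reference peptide with a
#' Mann-Whitney test and a bootstrap mean-difference interval. No
#' multiple-testing correction is applied by default; set
#' `p_adjust = "holm"` to add one.
#'
#' @param scores Score table with a position column and the metric column.
#' @param annotation A [precursor_annotation()].
#' @param metric Metric column name.
#' @param reference Reference peptide name (default `"glucagon"`).
#' @param include_signal Include the signal peptide among contrast groups
#'   (default `TRUE`, as in landscape figures that contrast SP too).
#' @param alternative Sidedness for the Mann-Whitney test.
#' @param n_boot,seed Bootstrap settings.
#' @param p_adjust `"none"` or `"holm"`.
#' @return Data.frame `peptide, n, mean, mean_diff, ci_low, ci_high, U, p`.
#' @export
contrast_vs_reference <- function(scores, annotation, metric,
                                  reference = "glucagon",
                                  include_signal = TRUE,
                                  alternative = "two_sided",
                                  n_boot = 5000, seed = 1,
                                  p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  poscol <- if ("protein_pos" %in% names(scores)) "protein_pos" else "pos"
  prim <- primary_regions(annotation)
  prim <- prim[prim$kind %in% c("peptide", if (include_signal) "signal"), ,
               drop = FALSE]
  if (!reference %in% prim$name) .err("reference peptide %s not found", reference)
  vals_for <- function(name) {
    r <- prim[prim$name == name, ]
    v <- scores[[metric]][scores[[poscol]] %in% (r$start:r$end)]
    v[!is.na(v)]
  }
  ref_vals <- vals_for(reference)
  if (length(ref_vals) < 2) .err("reference peptide has < 2 scored values")
  others <- setdiff(prim$name, reference)
  rows <- lapply(others, function(p) {
    v <- vals_for(p)
    if (length(v) < 2)
      return(data.frame(peptide = p, n = length(v), mean = NA_real_,
                        mean_diff = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, U = NA_real_, p = NA_real_))
    mw <- mann_whitney(ref_vals, v, alternative = alternative)
    bs <- bootstrap_mean_diff(ref_vals, v, n_boot = n_boot,
                              seed = derive_seed(seed, p))
    data.frame(peptide = p, n = length(v), mean = mean(v),
               mean_diff = bs$mean_diff, ci_low = bs$ci_low,
               ci_high = bs$ci_high, U = mw$u, p = mw$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "holm") out$p_adj <- stats::p.adjust(out$p, "holm")
  attr(out, "reference") <- reference
  attr(out, "reference_mean") <- mean(ref_vals)
  attr(out, "reference_n") <- length(ref_vals)
  rownames(out) <- NULL
  out
}
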