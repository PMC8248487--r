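test_that("orthologue QC filtering is boundary-inclusive and matches brute force", {
  rec <- data.frame(species = c("s1", "s2", "s3"),
                    goc = c(50, 49, 100), wga = c(50, 90, 100),
                    pid = c(25, 80, 24))
  kept <- filter_orthologues(rec)
  expect_equal(kept$species, "s1")
  set.seed(8)
  tab <- data.frame(species = sprintf("sp%02d", 1:200),
                    goc = runif(200, 0, 100), wga = runif(200, 0, 100),
                    pid = runif(200, 0, 100))
  kept2 <- filter_orthologues(tab)
  oracle <- tab[tab$goc >= 50 & tab$wga >= 50 & tab$pid >= 25, ]
  expect_equal(nrow(kept2), nrow(oracle))
  expect_equal(kept2$species, oracle$species)
})

test_that("raising any QC threshold never increases the retained count", {
  set.seed(9)
  tab <- data.frame(species = sprintf("sp%02d", 1:100),
                    goc = runif(100, 0, 100), wga = runif(100, 0, 100),
                    pid = runif(100, 0, 100))
  base_n <- nrow(filter_orthologues(tab))
  for (th in list(c(60, 50, 25), c(50, 70, 25), c(50, 50, 60))) {
    expect_lte(nrow(filter_orthologues(tab, th[1], th[2], th[3])), base_n)
  }
})

test_that("missing QC metrics reject the record (warn) or error", {
  rec <- data.frame(species = c("a", "b"), goc = c(90, NA),
                    wga = c(90, 90), pid = c(90, 90))
  expect_warning(kept <- filter_orthologues(rec), "missing QC")
  expect_equal(kept$species, "a")
  expect_error(filter_orthologues(rec, on_missing = "error"), "missing QC")
})

test_that("site-rate estimation ranks column diversity correctly", {
  # column 1 invariant, column 2 two states, column 3 maximal diversity
  msa <- c("AAW", "ACY", "AAH", "ACD", "AAE")
  est <- estimate_site_rates(msa)
  expect_equal(est$raw_rate[1], min(est$raw_rate))
  expect_lt(est$raw_rate[2], est$raw_rate[3])
  expect_error(estimate_site_rates(msa[1:2]), "at least 3")
  expect_error(estimate_site_rates(c("AA", "AAA", "A")), "ragged")
})

test_that("all-gap columns are missing, gappy columns flagged", {
  msa <- c("A-A", "C--", "G--", "T--")
  est <- estimate_site_rates(msa)
  expect_true(is.na(est$raw_rate[2]))
  expect_true(est$low_confidence[3]) # one non-gap residue out of four
  expect_false(est$low_confidence[1])
})

test_that("estimated rates are invariant to sequence order", {
  cfg <- sim_config(seed = 10, msa = list(n_seqs = 20, n_sites = 40,
                                          gamma_shape = 2, gamma_scale = 0.5))
  msa <- simulate_msa(cfg)$msa
  e1 <- estimate_site_rates(msa)
  e2 <- estimate_site_rates(rev(msa))
  expect_equal(e1$raw_rate, e2$raw_rate, tolerance = 1e-12)
})

test_that("z-normalization yields mean 0, sd 1 and known closed forms", {
  z <- normalize_scores(c(1, 2, 3))
  expect_equal(z, c(-1.224744871, 0, 1.224744871), tolerance = 1e-8)
  set.seed(12)
  x <- rexp(100)
  z2 <- normalize_scores(x)
  expect_equal(mean(z2), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z2^2)), 1, tolerance = 1e-9)
  # idempotence on already-standardized input
  expect_equal(normalize_scores(z2), z2, tolerance = 1e-9)
  expect_error(normalize_scores(rep(2, 5)), "zero variance")
  expect_error(normalize_scores(c(1, NA)), "non-missing")
  # alternate convention: most conserved position pinned at -1
  zm <- normalize_scores(x, mode = "min_neg1")
  expect_equal(min(zm), -1, tolerance = 1e-12)
})

test_that("Gaussian smoothing is exact on constants, kernels and ramps", {
  const <- rep(3.5, 25)
  sm <- smooth_trace(const, sigma = 1)
  expect_equal(sm$smoothed, const, tolerance = 1e-12)
  expect_equal(sm$ci_low, const, tolerance = 1e-12)
  # unit impulse reproduces the normalized kernel
  n <- 41; imp <- rep(0, n); imp[21] <- 1
  sm2 <- smooth_trace(imp, sigma = 1)
  r <- 4
  k <- dnorm(-r:r); k <- k / sum(k)
  expect_equal(sm2$smoothed[21 + (-r:r)], k, tolerance = 1e-12)
  # symmetric kernel leaves a linear ramp unchanged away from edges
  ramp <- seq(0, 5, length.out = 30)
  sm3 <- smooth_trace(ramp, sigma = 1)
  interior <- 6:25
  expect_equal(sm3$smoothed[interior], ramp[interior], tolerance = 1e-9)
  expect_error(smooth_trace(ramp, sigma = 0), "sigma")
})

test_that("the 50% band brackets the smoothed trace symmetrically", {
  set.seed(13)
  x <- rnorm(60)
  sm <- smooth_trace(x, sigma = 1.5)
  expect_true(all(sm$ci_low <= sm$smoothed & sm$smoothed <= sm$ci_high))
  expect_equal(sm$smoothed - sm$ci_low, sm$ci_high - sm$smoothed,
               tolerance = 1e-12)
})

test_that("external rate files are validated and aligned to the precursor", {
  p <- tempfile(fileext = ".tsv")
  tab <- data.frame(pos = 1:180, score = rnorm(180))
  write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- read_external_rates(p, protein_length = 180)
  expect_equal(nrow(out), 180)
  expect_equal(out$score, tab$score)
  dup <- tab; dup$pos[2] <- 1
  write.table(dup, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_external_rates(p), "duplicate positions")
  write.table(tab[1:100, ], p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_external_rates(p, protein_length = 180), "180 residues")
})

test_that("two-rate alignments are separated with high AUC", {
  set.seed(14)
  n_seqs <- 60; n_slow <- 50; n_fast <- 50
  slow_p <- 0.03; fast_p <- 0.5
  anc <- sample(c("A", "C", "D", "E", "F"), n_slow + n_fast, replace = TRUE)
  p <- c(rep(slow_p, n_slow), rep(fast_p, n_fast))
  seqs <- vapply(1:n_seqs, function(i) {
    res <- anc
    mut <- runif(length(p)) < p
    res[mut] <- sample(c("G", "H", "K", "L"), sum(mut), replace = TRUE)
    paste(res, collapse = "")
  }, character(1))
  est <- estimate_site_rates(seqs)
  lab <- c(rep(0, n_slow), rep(1, n_fast))
  r <- rank(est$raw_rate)
  auc <- (sum(r[lab == 1]) - n_fast * (n_fast + 1) / 2) / (n_slow * n_fast)
  expect_gte(auc, 0.9)
})

test_that("the full conservation profile composes rate, score and trace", {
  cfg <- sim_config(seed = 15, msa = list(n_seqs = 30, n_sites = 50,
                                          gamma_shape = 2, gamma_scale = 0.5))
  msa <- simulate_msa(cfg)$msa
  prof <- conservation_profile(msa)
  expect_equal(nrow(prof), 50)
  expect_equal(mean(prof$score), 0, tolerance = 1e-9)
  expect_true(all(prof$ci_low <= prof$smoothed))
})
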