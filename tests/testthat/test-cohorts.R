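test_that("delimited cohort tables are read with singleton flags", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("pos\tref\talt\tac\tan\taf",
               "10\tA\tG\t1\t2000\t5e-4",
               "20\tC\tT\t2\t2000\t1e-3",
               "30\tG\tA\t5\t2000\t2.5e-3"), p)
  co <- cohort("toy", 1000, "exome")
  obs <- read_cohort_variants(p, "tsv", co)
  expect_equal(nrow(obs), 3)
  expect_equal(obs$is_singleton, c(TRUE, FALSE, FALSE))
  expect_equal(attr(obs, "coord"), "cds")
})

test_that("AF-only tables back-compute allele counts from 2N", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("pos\tref\talt\taf",
               sprintf("10\tA\tG\t%.10g", 1 / 2000),
               sprintf("20\tC\tT\t%.10g", 10 / 2000)), p)
  obs <- read_cohort_variants(p, "tsv", cohort("toy", 1000, "exome"))
  expect_equal(obs$ac, c(1L, 10L))
  expect_equal(obs$is_singleton, c(TRUE, FALSE))
})

test_that("malformed or out-of-range rows are rejected with diagnostics", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("pos\tref\talt\tac\tan\taf", "10\tA\tG\t3\t2000\t1.5"), p)
  expect_error(read_cohort_variants(p, "tsv", cohort("x", 1000, "exome")),
               "af outside")
  p2 <- tempfile(fileext = ".tsv")
  writeLines(c("pos\tref\talt\tac\tan\taf", "10\tAT\tG\t3\t2000\t1.5e-3"), p2)
  expect_error(read_cohort_variants(p2, "tsv", cohort("x", 1000, "exome")),
               "non-SNV")
  expect_error(read_cohort_variants(tempfile(), "tsv",
                                    cohort("x", 1000, "exome")), "not found")
})

test_that("multi-allelic VCF records split into one observation per allele", {
  p <- write_toy_vcf(c(
    "2\t100\t.\tG\tA,T\t.\tPASS\tAC=1,4;AN=20000;AF=5e-05,2e-04",
    "2\t200\t.\tC\tT\t.\tPASS\tAC=2;AN=20000;AF=1e-04"))
  obs <- read_cohort_variants(p, "vcf", cohort("vcfco", 10000, "genome"))
  expect_equal(nrow(obs), 3)
  expect_equal(obs$alt, c("A", "T", "T"))
  expect_equal(obs$ac, c(1L, 4L, 2L))
  expect_equal(attr(obs, "coord"), "genomic")
  expect_true(obs$is_singleton[1] && !any(obs$is_singleton[-1]))
})

test_that("zero-count rows are dropped on read", {
  p <- write_toy_vcf("2\t100\t.\tG\tA\t.\tPASS\tAC=0;AN=20000;AF=0")
  obs <- read_cohort_variants(p, "vcf", cohort("vcfco", 10000, "genome"))
  expect_equal(nrow(obs), 0)
})

test_that("simulated cohort files round-trip losslessly through the reader", {
  cfg <- sim_config(seed = 7, n_true_variants = 40)
  sim <- simulate_cohorts(cfg)
  dir <- tempfile()
  paths <- write_simulated_cohorts(sim, dir)
  for (co in sim$cohorts) {
    back <- read_cohort_variants(paths[[co$name]], "tsv", co)
    orig <- sim$cohort_tables[[co$name]]
    expect_equal(back[, c("pos", "ref", "alt", "ac")],
                 orig[, c("pos", "ref", "alt", "ac")])
    expect_equal(back$af, orig$af, tolerance = 1e-12)
  }
})

test_that("merging takes the max AF and counts sharing cohorts", {
  a <- toy_obs("a", 50, "A", "G", ac = 2, an = 2e5)   # af 1.0e-5
  b <- toy_obs("b", 50, "A", "G", ac = 8, an = 2.5e5) # af 3.2e-5
  m <- merge_cohorts(list(a, b))
  expect_equal(nrow(m), 1)
  expect_equal(m$max_af, 3.2e-5)
  expect_equal(m$sharing_class, 2L)
  expect_false(m$is_singleton)
})

test_that("merged union matches a brute-force set union", {
  v <- function(pos) toy_obs("x", pos, "A", "G", ac = 2)
  mk <- function(name, poss) {
    o <- toy_obs(name, poss, "A", "G", ac = rep(2, length(poss)))
    o
  }
  m <- merge_cohorts(list(mk("A", c(1, 2)), mk("B", c(2, 3)), mk("C", c(3, 4))))
  expect_equal(nrow(m), 4)
  expect_equal(m$sharing_class[order(m$pos)], c(1L, 2L, 2L, 1L))
  # random synthetic cohorts vs an independent union oracle
  set.seed(42)
  for (rep in 1:20) {
    lists <- lapply(1:3, function(i) {
      poss <- sample(1:30, sample(3:12, 1))
      toy_obs(paste0("c", i), poss, "A", "G",
              ac = sample(1:5, length(poss), replace = TRUE))
    })
    m <- merge_cohorts(lists)
    union_keys <- unique(unlist(lapply(lists, function(o) o$pos)))
    expect_equal(nrow(m), length(union_keys))
    expect_lte(nrow(m), sum(vapply(lists, nrow, numeric(1))))
    counts <- table(unlist(lapply(lists, function(o) unique(o$pos))))
    expect_equal(m$sharing_class[order(m$pos)],
                 as.integer(counts[order(as.integer(names(counts)))]))
  }
})

test_that("max_af is invariant under cohort input order", {
  set.seed(11)
  lists <- lapply(1:4, function(i)
    toy_obs(paste0("c", i), sample(1:20, 8), "A", "G",
            ac = sample(1:9, 8, replace = TRUE), an = 1000 * i))
  m1 <- merge_cohorts(lists)
  m2 <- merge_cohorts(rev(lists))
  expect_equal(m1, m2)
})

test_that("mixed coordinate systems refuse to merge", {
  a <- toy_obs("a", 10, "A", "G", 1)
  b <- toy_obs("b", 10, "A", "G", 1)
  attr(b, "coord") <- "genomic"
  expect_error(merge_cohorts(list(a, b)), "mixed coordinate systems")
})

test_that("singleton AF follows 1/(2N) and decreases with cohort size", {
  expect_equal(singleton_af(1)$af, 0.5)
  expect_equal(round(singleton_af(132345)$log10_af, 1), -5.4)
  expect_equal(singleton_af(200629)$af, 1 / 401258, tolerance = 1e-12)
  ns <- c(1, 10, 1e3, 1e5, 5e5)
  afs <- vapply(ns, function(n) singleton_af(n)$af, numeric(1))
  expect_true(all(diff(afs) < 0))
  expect_error(singleton_af(0), ">= 1")
})

test_that("sharing summary counts are exhaustive and exact", {
  a <- toy_obs("a", c(1, 2, 3), "A", "G", c(1, 2, 2))
  b <- toy_obs("b", c(2, 3), "A", "G", c(4, 1))
  m <- merge_cohorts(list(a, b))
  s <- sharing_summary(m)
  expect_equal(sum(s$n), nrow(m))
  expect_equal(s$n[s$sharing_class == 1], 1)
  expect_equal(s$n[s$sharing_class == 2], 2)
  # known-class synthetic mixture: exact recovery
  cfg <- sim_config(seed = 3, n_true_variants = 60)
  sim <- simulate_cohorts(cfg)
  m2 <- merge_cohorts(sim$cohort_tables)
  s2 <- sharing_summary(m2)
  expect_equal(sum(s2$n), 60)
  truth_counts <- table(sim$truth$sharing_class)
  expect_equal(s2$n, as.integer(truth_counts))
  expect_error(sharing_summary(m2[0, ]), "empty")
})

test_that("merged-level singletons require one allele in one cohort only", {
  a <- toy_obs("a", c(1, 2), "A", "G", c(1, 1))
  b <- toy_obs("b", 2, "A", "G", 1)
  m <- merge_cohorts(list(a, b))
  m <- m[order(m$pos), ]
  expect_equal(m$is_singleton, c(TRUE, FALSE))
  m2 <- merge_cohorts(list(a, b), singleton_rule = "per_cohort")
  expect_equal(m2[order(m2$pos), ]$is_singleton, c(TRUE, TRUE))
})
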