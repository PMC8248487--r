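test_that("translation follows the standard code and strips the stop", {
  expect_equal(translate_cds("ATGGCA"), "MA")
  expect_equal(translate_cds("ATGTAA"), "M")
  expect_error(translate_cds("ATGTAAGCATAA"), "internal stop codon at codon 2")
  expect_error(translate_cds("ATGC"), "divisible by 3")
  expect_error(translate_cds("ATGNNN"), "non-ACGT")
  # random codon strings vs an independent table lookup
  set.seed(1)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  for (i in 1:25) {
    codons <- sample(sense, sample(1:40, 1), replace = TRUE)
    expect_equal(translate_cds(paste(codons, collapse = "")),
                 paste(code[codons], collapse = ""))
  }
})

test_that("saturation enumeration matches brute force on toy CDSs", {
  e <- enumerate_possible_missense(transcript_model("ATGGCATAA"))
  expect_equal(e$n_missense_events, 15)
  expect_equal(e$n_unique_aa_subs, 12)
  expect_equal(e$n_synonymous, 3)
  expect_equal(e$n_stop_gain, 0)
  # TGG codon scanned alone (stop codon appended, excluded from scan)
  e2 <- enumerate_possible_missense(transcript_model("TGGTAA"))
  expect_equal(e2$n_missense_events, 7)
  expect_equal(e2$n_unique_aa_subs, 5)
  expect_equal(e2$n_stop_gain, 2)
  # full event-level agreement with the independent oracle
  set.seed(2)
  for (i in 1:5) {
    cds <- random_cds(sample(3:12, 1))
    mine <- enumerate_possible_missense(transcript_model(cds))$events
    orac <- oracle_enumerate(cds)
    expect_equal(mine, orac)
  }
})

test_that("event counts obey the 9L conservation law on random CDSs", {
  set.seed(3)
  for (i in 1:50) {
    L <- sample(2:30, 1)
    e <- enumerate_possible_missense(transcript_model(random_cds(L)))
    expect_equal(e$n_missense_events + e$n_synonymous + e$n_stop_gain, 9 * L)
    expect_lte(e$n_unique_aa_subs, e$n_missense_events)
    expect_lte(e$n_missense_events, 9 * L)
  }
})

test_that("scanning the stop codon adds stop-loss events", {
  e <- enumerate_possible_missense(transcript_model("ATGTAA"),
                                   include_stop_codon = TRUE)
  expect_equal(nrow(e$events), 18)
  expect_true("stop_loss" %in% e$events$consequence)
})

test_that("CDS positions map to codons by thirds", {
  m <- transcript_model(random_cds(80))
  expect_equal(cds_to_protein_pos(1, m),
               data.frame(codon_index = 1, position_in_codon = 1))
  expect_equal(cds_to_protein_pos(208, m)$codon_index, 70)
  L <- m$n_codons + 1
  expect_equal(cds_to_protein_pos(3 * L, m)$codon_index, L)
  expect_error(cds_to_protein_pos(3 * L + 1, m), "out of range")
})

test_that("variant annotation keeps missense, drops start-lost and synonymous", {
  m <- transcript_model("ATGGCATGGTAA")
  mk <- function(pos, ref, alt) {
    structure(data.frame(pos = pos, ref = ref, alt = alt,
                         max_af = 1e-5, sharing_class = 1L,
                         is_singleton = TRUE, cohorts = "a",
                         stringsAsFactors = FALSE), coord = "cds")
  }
  # ATG -> GTG start-lost: excluded by default
  out <- annotate_protein_consequence(mk(1, "A", "G"), m)
  expect_equal(nrow(out), 0)
  out_all <- annotate_protein_consequence(mk(1, "A", "G"), m, keep_all = TRUE)
  expect_equal(out_all$consequence, "start_lost")
  # GCA -> GCG synonymous: excluded
  expect_equal(nrow(annotate_protein_consequence(mk(6, "A", "G"), m)), 0)
  # GCA -> GTA missense kept with protein coordinates
  out2 <- annotate_protein_consequence(mk(5, "C", "T"), m)
  expect_equal(out2$protein_pos, 2)
  expect_equal(out2$ref_aa, "A")
  expect_equal(out2$alt_aa, "V")
  expect_error(annotate_protein_consequence(mk(5, "G", "T"), m),
               "ref base mismatch")
})

test_that("annotated consequences agree with the enumeration table", {
  m <- transcript_model(random_cds(40))
  enum <- enumerate_possible_missense(m)$events
  set.seed(4)
  idx <- sample(nrow(enum), 60)
  merged <- structure(
    data.frame(pos = enum$cds_pos[idx], ref = enum$ref[idx],
               alt = enum$alt[idx], max_af = 1e-5,
               sharing_class = 1L, is_singleton = TRUE, cohorts = "a",
               stringsAsFactors = FALSE), coord = "cds")
  out <- annotate_protein_consequence(merged, m, keep_all = TRUE)
  is_start_lost <- enum$consequence[idx] == "missense" &
    enum$codon_index[idx] == 1 & enum$ref_aa[idx] == "M"
  expected <- ifelse(is_start_lost, "start_lost", enum$consequence[idx])
  expect_equal(out$consequence, expected)
  expect_equal(out$ref_aa, enum$ref_aa[idx])
  expect_equal(out$alt_aa, enum$alt_aa[idx])
  # every annotated missense substitution exists in the enumeration
  mis <- annotate_protein_consequence(merged, m)
  keys <- paste(mis$protein_pos, mis$ref_aa, mis$alt_aa)
  enum_keys <- paste(enum$codon_index, enum$ref_aa,
                     enum$alt_aa)[enum$consequence == "missense"]
  expect_true(all(keys %in% enum_keys))
})

test_that("genomic coordinates map through an exon model, both strands", {
  merged <- structure(
    data.frame(chrom = "2", pos = c(105, 204), ref = c("A", "C"),
               alt = c("G", "T"), max_af = 1e-5, sharing_class = 1L,
               is_singleton = TRUE, cohorts = "a", stringsAsFactors = FALSE),
    coord = "genomic")
  exons_plus <- data.frame(start = c(101, 201), end = c(110, 210),
                           strand = "+")
  out <- map_genomic_to_cds(merged, exons_plus)
  expect_equal(out$pos, c(5, 14))
  expect_equal(out$ref, c("A", "C"))
  exons_minus <- data.frame(start = c(201, 101), end = c(210, 110),
                            strand = "-")
  out2 <- map_genomic_to_cds(merged, exons_minus)
  expect_equal(out2$pos, c(10 + (110 - 105 + 1), 210 - 204 + 1))
  expect_equal(out2$ref, c("T", "G")) # reverse-complemented
  expect_warning(
    map_genomic_to_cds(structure(
      data.frame(chrom = "2", pos = 500, ref = "A", alt = "G",
                 stringsAsFactors = FALSE), coord = "genomic"), exons_plus),
    "outside the exon map")
})
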