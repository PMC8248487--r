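# in-code fixtures shared across test files

# a tiny observation table in CDS coordinates
toy_obs <- function(cohort_name, pos, ref, alt, ac, an = 2000) {
  structure(
    data.frame(cohort = cohort_name, pos = pos, ref = ref, alt = alt,
               ac = ac, an = an, af = ac / an, stringsAsFactors = FALSE),
    coord = "cds")
}

# write a minimal VCF 4.2 file, returns path
write_toy_vcf <- function(rows, path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele count\">",
           "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(hdr, rows), path)
  path
}

# independent per-event SNV consequence oracle: loops position by position,
# translating each mutated codon via a plain named-vector lookup
oracle_enumerate <- function(cds, n_codons = nchar(cds) / 3 - 1) {
  code <- Biostrings::GENETIC_CODE
  out <- list()
  for (i in seq_len(3 * n_codons)) {
    ref <- substr(cds, i, i)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      mut <- cds
      substr(mut, i, i) <- alt
      ci <- ceiling(i / 3)
      ra <- code[[substr(cds, 3 * ci - 2, 3 * ci)]]
      ma <- code[[substr(mut, 3 * ci - 2, 3 * ci)]]
      cons <- if (ra == ma) "synonymous" else if (ma == "*") "stop_gain"
        else if (ra == "*") "stop_loss" else "missense"
      out[[length(out) + 1]] <- data.frame(
        cds_pos = i, ref = ref, alt = alt, codon_index = ci, ref_aa = ra,
        alt_aa = ma, consequence = cons, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# random CDS of n codons with terminal stop, no internal stop
random_cds <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  paste0(paste(sample(sense, n_codons, replace = TRUE), collapse = ""), "TAA")
}

# a small annotation with known geometry for arithmetic tests
toy_annotation <- function() {
  protein <- paste(rep("A", 30), collapse = "")
  regions <- data.frame(
    name = c("pepA", "pepB"),
    start = c(1, 11), end = c(5, 20),
    kind = c("peptide", "peptide"),
    stringsAsFactors = FALSE)
  precursor_annotation(protein, regions)
}
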