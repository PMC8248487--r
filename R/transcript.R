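#' Build a coding-sequence model
#'
#' Holds a CDS (including the terminal stop codon), its translation, and the
#' codon map used to project nucleotide variants onto protein positions.
#' Translation uses the standard genetic code.
#'
#' @param cds Coding nucleotide sequence (A/C/G/T, length divisible by 3,
#'   ending in a stop codon).
#' @param transcript_id Identifier string for provenance.
#' @return An object of class `"transcript_model"` with elements `cds`,
#'   `protein`, `n_codons` (excluding the stop) and `transcript_id`.
#' @export
#' @examples
#' m <- transcript_model("ATGGCATAA", "toy")
#' m$protein  # "MA"
transcript_model <- function(cds, transcript_id = "unnamed") {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3 != 0) .err("CDS length (%d) is not divisible by 3", nchar(cds))
  if (grepl("[^ACGT]", cds)) .err("CDS contains non-ACGT characters")
  last <- substr(cds, nchar(cds) - 2, nchar(cds))
  if (!last %in% c("TAA", "TAG", "TGA"))
    .err("CDS must end in a stop codon (found %s)", last)
  protein <- translate_cds(cds)
  structure(list(cds = cds, protein = protein,
                 n_codons = nchar(cds) / 3 - 1,
                 transcript_id = transcript_id),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s: %d nt CDS, %d aa protein\n",
              x$transcript_id, nchar(x$cds), nchar(x$protein)))
  invisible(x)
}

#' Translate a CDS to protein
#'
#' Standard-code translation via [Biostrings::translate()]; a terminal stop
#' codon is stripped from the returned protein, an internal stop is an
#' error naming the codon.
#'
#' @param cds Nucleotide string, length divisible by 3, A/C/G/T only.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3 != 0) .err("CDS length (%d) is not divisible by 3", nchar(cds))
  if (grepl("[^ACGT]", cds)) .err("CDS contains non-ACGT characters")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  body <- if (substr(aa, nchar(aa), nchar(aa)) == "*")
    substr(aa, 1, nchar(aa) - 1) else aa
  internal <- regexpr("*", body, fixed = TRUE)
  if (internal > 0) .err("internal stop codon at codon %d", internal)
  body
}

#' Map a CDS position to its codon
#'
#' @param cds_pos 1-based CDS position(s).
#' @param model A [transcript_model()].
#' @return A data.frame `codon_index, position_in_codon`.
#' @export
cds_to_protein_pos <- function(cds_pos, model) {
  n <- nchar(model$cds)
  if (any(cds_pos < 1 | cds_pos > n))
    .err("cds_pos out of range 1..%d", n)
  data.frame(codon_index = ceiling(cds_pos / 3),
             position_in_codon = (cds_pos - 1) %% 3 + 1)
}

#' Enumerate all theoretically possible SNV consequences
#'
#' Substitutes every alternative base at every CDS position and translates
#' the mutated codon, producing the in-silico saturation table of
#' single-nucleotide consequences. For L codons scanned there are exactly
#' 9L events partitioned into missense, synonymous and stop-gain (plus
#' stop-loss when the terminal stop codon is included in the scan). The
#' number of distinct amino-acid substitutions collapses missense events to
#' unique `(codon_index, ref_aa, alt_aa)` triples; several SNVs in one codon
#' can yield the same substitution, so this count is at most the event
#' count.
#'
#' @param model A [transcript_model()].
#' @param include_stop_codon Scan the terminal stop codon as well
#'   (default `FALSE`; stop-loss events are then reported).
#' @return A list with `events` (data.frame `cds_pos, ref, alt, codon_index,
#'   ref_aa, alt_aa, consequence`), `n_missense_events`, `n_unique_aa_subs`,
#'   `n_synonymous`, `n_stop_gain`.
#' @export
#' @examples
#' enumerate_possible_missense(transcript_model("ATGGCATAA"))$n_missense_events
enumerate_possible_missense <- function(model, include_stop_codon = FALSE) {
  gc <- Biostrings::GENETIC_CODE
  L <- model$n_codons + if (include_stop_codon) 1L else 0L
  n <- 3L * L
  bases <- c("A", "C", "G", "T")
  refs <- strsplit(substr(model$cds, 1, n), "")[[1]]
  cds_pos <- rep(seq_len(n), each = 3)
  ref <- refs[cds_pos]
  alt <- unlist(lapply(refs, function(b) bases[bases != b]), use.names = FALSE)
  codon_index <- ceiling(cds_pos / 3)
  in_codon <- (cds_pos - 1L) %% 3L + 1L
  ref_codon <- substring(model$cds, 3L * codon_index - 2L, 3L * codon_index)
  alt_codon <- vapply(seq_along(ref_codon), function(i) {
    x <- ref_codon[i]; substr(x, in_codon[i], in_codon[i]) <- alt[i]; x
  }, character(1))
  ref_aa <- unname(gc[ref_codon])
  alt_aa <- unname(gc[alt_codon])
  consequence <- ifelse(ref_aa == alt_aa, "synonymous",
                 ifelse(alt_aa == "*", "stop_gain",
                 ifelse(ref_aa == "*", "stop_loss", "missense")))
  events <- data.frame(cds_pos = cds_pos, ref = ref, alt = alt,
                       codon_index = codon_index, ref_aa = ref_aa,
                       alt_aa = alt_aa, consequence = consequence,
                       stringsAsFactors = FALSE)
  mis <- events[events$consequence == "missense", , drop = FALSE]
  list(events = events,
       n_missense_events = nrow(mis),
       n_unique_aa_subs = length(unique(paste(mis$codon_index, mis$ref_aa,
                                              mis$alt_aa))),
       n_synonymous = sum(events$consequence == "synonymous"),
       n_stop_gain = sum(events$consequence == "stop_gain"))
}

#' Annotate merged variants with protein consequences
#'
#' Projects CDS-coordinate variants onto the protein, checks the reference
#' base against the CDS, and keeps missense records (excluding start-lost,
#' the convention used when harvesting cohort missense sets) unless
#' `keep_all = TRUE`.
#'
#' @param merged Merged-variant data.frame (CDS coordinates).
#' @param model A [transcript_model()].
#' @param keep_all Keep non-missense and start-lost records (flagged in the
#'   `consequence` column) instead of dropping them.
#' @return `merged` with columns `protein_pos, ref_aa, alt_aa, consequence`
#'   appended.
#' @export
annotate_protein_consequence <- function(merged, model, keep_all = FALSE) {
  if (!nrow(merged)) return(cbind(merged, protein_pos = integer(0),
                                  ref_aa = character(0), alt_aa = character(0),
                                  consequence = character(0)))
  if (identical(attr(merged, "coord"), "genomic"))
    .err("variants are in genomic coordinates; map to CDS first (see map_genomic_to_cds)")
  n <- nchar(model$cds)
  if (any(merged$pos < 1 | merged$pos > n)) .err("variant position outside CDS")
  refs <- substring(model$cds, merged$pos, merged$pos)
  bad <- which(refs != merged$ref)
  if (length(bad))
    .err("ref base mismatch with CDS for variants at pos: %s",
         paste(utils::head(merged$pos[bad], 10), collapse = ", "))
  gc <- Biostrings::GENETIC_CODE
  ci <- ceiling(merged$pos / 3)
  inc <- (merged$pos - 1L) %% 3L + 1L
  rc <- substring(model$cds, 3L * ci - 2L, 3L * ci)
  ac <- vapply(seq_along(rc), function(i) {
    x <- rc[i]; substr(x, inc[i], inc[i]) <- merged$alt[i]; x
  }, character(1))
  ref_aa <- unname(gc[rc]); alt_aa <- unname(gc[ac])
  consequence <- ifelse(ref_aa == alt_aa, "synonymous",
                 ifelse(alt_aa == "*", "stop_gain",
                 ifelse(ref_aa == "*", "stop_loss", "missense")))
  consequence[consequence == "missense" & ci == 1 & ref_aa == "M"] <- "start_lost"
  out <- merged
  out$protein_pos <- ci
  out$ref_aa <- ref_aa
  out$alt_aa <- alt_aa
  out$consequence <- consequence
  if (!keep_all) out <- out[out$consequence == "missense", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "coord") <- attr(merged, "coord")
  out
}

#' Map genomic variant coordinates onto a CDS
#'
#' Uses an explicit exon map (1-based inclusive genomic intervals in
#' transcription order, one strand for all exons). On the minus strand the
#' alleles are reverse-complemented. No annotation source is contacted.
#'
#' @param merged Merged-variant table with genomic `pos`.
#' @param exons Data.frame `start, end, strand` (`"+"` or `"-"`).
#' @return The table with `pos, ref, alt` rewritten in CDS coordinates;
#'   variants outside the exons are dropped with a warning.
#' @export
map_genomic_to_cds <- function(merged, exons) {
  if (!all(c("start", "end", "strand") %in% names(exons)))
    .err("exon map needs columns start, end, strand")
  if (length(unique(exons$strand)) != 1) .err("exons must share one strand")
  strand <- exons$strand[1]
  widths <- exons$end - exons$start + 1
  offs <- cumsum(c(0, widths[-length(widths)]))
  cds_pos <- rep(NA_integer_, nrow(merged))
  for (i in seq_len(nrow(exons))) {
    hit <- merged$pos >= exons$start[i] & merged$pos <= exons$end[i]
    cds_pos[hit] <- if (strand == "+")
      offs[i] + (merged$pos[hit] - exons$start[i] + 1)
    else offs[i] + (exons$end[i] - merged$pos[hit] + 1)
  }
  drop <- is.na(cds_pos)
  if (any(drop))
    warning(sprintf("%d variant(s) outside the exon map were dropped", sum(drop)))
  out <- merged[!drop, , drop = FALSE]
  out$pos <- cds_pos[!drop]
  if (strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    out$ref <- unname(comp[out$ref]); out$alt <- unname(comp[out$alt])
  }
  out$chrom <- NULL
  attr(out, "coord") <- "cds"
  out
}

#' Read the first sequence of a FASTA file
#'
#' @param path FASTA path.
#' @param type `"dna"` or `"aa"`.
#' @return Character sequence.
#' @export
read_fasta_seq <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::readDNAStringSet(path)
         else Biostrings::readAAStringSet(path)
  if (!length(set)) .err("no sequences in %s", path)
  as.character(set[[1]])
}

#' Write the saturation-enumeration table
#'
#' Tab-delimited `cds_pos ref alt codon_index ref_aa alt_aa consequence`.
#'
#' @param enum Output of [enumerate_possible_missense()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enumeration <- function(enum, path) .write_tsv(enum$events, path)
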