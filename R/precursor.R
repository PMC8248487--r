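#' Construct a precursor annotation
#'
#' Partitions a prohormone precursor into named regions: the signal peptide,
#' mature peptides, and (implicitly) the spacer/linker residues between
#' them, which include the dibasic cleavage sites recognized by the
#' prohormone convertases. Composite regions (e.g. glicentin,
#' oxyntomodulin, MPGF for proglucagon) are views over primary regions and
#' never enter per-peptide statistics.
#'
#' @param protein Precursor amino-acid sequence.
#' @param regions Data.frame `name, start, end, kind` with optional
#'   `composite_of` (comma-joined names); `kind` is one of `"signal"`,
#'   `"peptide"`, `"spacer"`, `"composite"`. Coordinates are 1-based
#'   inclusive precursor positions.
#' @param cleavage_motifs Optional data.frame `position, motif, enzyme`.
#' @return An object of class `"precursor_annotation"`.
#' @export
precursor_annotation <- function(protein, regions, cleavage_motifs = NULL) {
  L <- nchar(protein)
  need <- c("name", "start", "end", "kind")
  if (!all(need %in% names(regions)))
    .err("regions need columns: %s", paste(need, collapse = ", "))
  if (is.null(regions$composite_of)) regions$composite_of <- NA_character_
  if (any(regions$start < 1 | regions$end > L | regions$start > regions$end))
    .err("region outside protein (length %d) or start > end", L)
  if (anyDuplicated(regions$name)) .err("duplicate region names")
  prim <- regions[regions$kind != "composite", , drop = FALSE]
  occ <- integer(L)
  for (i in seq_len(nrow(prim)))
    occ[prim$start[i]:prim$end[i]] <- occ[prim$start[i]:prim$end[i]] + 1L
  if (any(occ > 1))
    .err("primary regions overlap at positions: %s",
         paste(utils::head(which(occ > 1), 5), collapse = ", "))
  comp <- regions[regions$kind == "composite", , drop = FALSE]
  for (i in seq_len(nrow(comp))) {
    parts <- strsplit(comp$composite_of[i], ",")[[1]]
    missing_parts <- setdiff(parts, prim$name)
    if (length(missing_parts))
      .err("composite %s refers to unknown region(s): %s", comp$name[i],
           paste(missing_parts, collapse = ", "))
    pr <- prim[prim$name %in% parts, , drop = FALSE]
    if (min(pr$start) < comp$start[i] || max(pr$end) > comp$end[i])
      .err("composite %s does not cover its parts", comp$name[i])
  }
  if (!is.null(cleavage_motifs)) {
    inside_primary <- vapply(cleavage_motifs$position, function(p)
      any(prim$start <= p & prim$end >= p & prim$kind == "peptide"), logical(1))
    if (any(inside_primary))
      warning("cleavage motif(s) fall inside a peptide region: positions ",
              paste(cleavage_motifs$position[inside_primary], collapse = ", "))
  }
  structure(list(protein = protein, regions = regions,
                 cleavage_motifs = cleavage_motifs),
            class = "precursor_annotation")
}

#' @export
print.precursor_annotation <- function(x, ...) {
  cat(sprintf("<precursor_annotation> %d aa, %d regions (%d primary)\n",
              nchar(x$protein), nrow(x$regions),
              sum(x$regions$kind != "composite")))
  invisible(x)
}

#' Load a precursor annotation from disk
#'
#' Accepts either JSON (`{"protein": ..., "regions": [...]}`) or a
#' tab-delimited region table `name start end kind composite_of` paired
#' with a protein FASTA.
#'
#' @param path Annotation file (JSON or TSV).
#' @param protein_fasta Protein FASTA, required for TSV input.
#' @return A [precursor_annotation()].
#' @export
load_annotation <- function(path, protein_fasta = NULL) {
  if (!file.exists(path)) .err("annotation file not found: %s", path)
  if (grepl("\\.json$", path)) {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    motifs <- if (!is.null(cfg$cleavage_motifs))
      as.data.frame(cfg$cleavage_motifs) else NULL
    precursor_annotation(cfg$protein, as.data.frame(cfg$regions), motifs)
  } else {
    if (is.null(protein_fasta))
      .err("TSV annotation needs a protein FASTA via `protein_fasta`")
    regions <- .read_tsv(path)
    precursor_annotation(read_fasta_seq(protein_fasta, "aa"), regions)
  }
}

#' Primary regions of an annotation
#' @param annotation A [precursor_annotation()].
#' @param peptides_only Drop the signal peptide and spacers.
#' @return Data.frame of regions.
#' @export
primary_regions <- function(annotation, peptides_only = FALSE) {
  r <- annotation$regions[annotation$regions$kind != "composite", , drop = FALSE]
  if (peptides_only) r <- r[r$kind == "peptide", , drop = FALSE]
  r
}

#' Which primary region contains a position
#' @keywords internal
.region_of <- function(pos, annotation) {
  prim <- primary_regions(annotation)
  hit <- which(prim$start <= pos & prim$end >= pos)
  if (!length(hit)) NULL else prim[hit[1], , drop = FALSE]
}

#' Dual-coordinate variant label
#'
#' Labels an amino-acid variant with both its precursor position and its
#' position within the mature peptide, the standard way of naming
#' prohormone variants (e.g. `R70H^Glucagon,18` — precursor residue 70,
#' glucagon residue 18). Variants falling on spacer/linker residues carry
#' the precursor position only.
#'
#' @param protein_pos Precursor position (1-based).
#' @param ref_aa,alt_aa Single-letter amino acids.
#' @param annotation A [precursor_annotation()].
#' @return Label string.
#' @export
#' @examples
#' label_variant(70, "R", "H", gcg_annotation())  # "R70H^glucagon,18"
label_variant <- function(protein_pos, ref_aa, alt_aa, annotation) {
  L <- nchar(annotation$protein)
  if (protein_pos < 1 || protein_pos > L)
    .err("protein_pos %d outside precursor 1..%d", protein_pos, L)
  reg <- .region_of(protein_pos, annotation)
  base <- sprintf("%s%d%s", ref_aa, protein_pos, alt_aa)
  if (is.null(reg) || reg$kind %in% c("spacer")) return(base)
  sprintf("%s^%s,%d", base, reg$name, protein_pos - reg$start + 1)
}

#' Parse a dual-coordinate label back to its parts
#'
#' @param label A string produced by [label_variant()].
#' @return List with `ref_aa, protein_pos, alt_aa, region, local_pos`
#'   (`region = "linker"`, `local_pos = NA` for spacer labels).
#' @export
parse_variant_label <- function(label) {
  m <- regmatches(label,
    regexec("^([A-Z*])([0-9]+)([A-Z*])(\\^([^,]+),([0-9]+))?$", label))[[1]]
  if (!length(m)) .err("unparseable label: %s", label)
  list(ref_aa = m[2], protein_pos = as.integer(m[3]), alt_aa = m[4],
       region = if (nzchar(m[6])) m[6] else "linker",
       local_pos = if (nzchar(m[7])) as.integer(m[7]) else NA_integer_)
}

#' Per-peptide variant counts and densities
#'
#' For each primary region: the number of unique amino-acid variants, the
#' number of distinct precursor positions hit, and the positional density
#' (positions hit / region length). Variants on linker residues are counted
#' in a `linker` row; composite regions are reported as derived views over
#' the union of their parts' positions.
#'
#' @param annotated Variant table with `protein_pos` (and ideally
#'   `ref_aa`/`alt_aa` to define uniqueness; falls back to
#'   `pos, ref, alt`).
#' @param annotation A [precursor_annotation()].
#' @param include_composites Append derived rows for composite regions.
#' @return Data.frame `region, kind, length, n_unique_variants,
#'   n_positions_hit, density`.
#' @export
peptide_variant_summary <- function(annotated, annotation,
                                    include_composites = FALSE) {
  # uniqueness at the nucleotide level when available (distinct SNVs can
  # encode the same amino-acid substitution), else at the aa level
  key <- if (all(c("pos", "ref", "alt") %in% names(annotated)))
    paste(annotated$pos, annotated$ref, annotated$alt)
  else paste(annotated$protein_pos, annotated$ref_aa, annotated$alt_aa)
  prim <- primary_regions(annotation)
  row_for <- function(name, kind, posset, mask) {
    data.frame(region = name, kind = kind, length = length(posset),
               n_unique_variants = length(unique(key[mask])),
               n_positions_hit = length(unique(annotated$protein_pos[mask])),
               density = if (length(posset))
                 length(unique(annotated$protein_pos[mask])) / length(posset)
               else NA_real_, stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(prim)), function(i) {
    posset <- prim$start[i]:prim$end[i]
    row_for(prim$name[i], prim$kind[i], posset,
            annotated$protein_pos %in% posset)
  })
  covered <- unlist(lapply(seq_len(nrow(prim)),
                           function(i) prim$start[i]:prim$end[i]))
  linker_pos <- setdiff(seq_len(nchar(annotation$protein)), covered)
  rows <- c(rows, list(row_for("linker", "spacer", linker_pos,
                               annotated$protein_pos %in% linker_pos)))
  out <- do.call(rbind, rows)
  if (include_composites) {
    comp <- annotation$regions[annotation$regions$kind == "composite", ,
                               drop = FALSE]
    crow <- lapply(seq_len(nrow(comp)), function(i) {
      posset <- comp$start[i]:comp$end[i]
      row_for(comp$name[i], "composite", posset,
              annotated$protein_pos %in% posset)
    })
    out <- rbind(out, do.call(rbind, crow))
  }
  rownames(out) <- NULL
  out
}

#' Built-in preproglucagon-like precursor fixture
#'
#' A synthetic reconstruction of the 180-residue human preproglucagon
#' architecture: a 20-aa signal peptide, GRPP (21-50), glucagon (53-81),
#' IP-1 (84-89), GLP-1 numbered from GLP-1(1-37) (92-128), IP-2 (131-142)
#' and GLP-2 (146-178), separated by dibasic cleavage motifs, with the
#' composite products glicentin (21-89), oxyntomodulin (53-89) and the
#' major proglucagon fragment MPGF (92-180). Region coordinates follow the
#' UniProt P01275 molecule-processing convention; the sequence itself is a
#' synthetic stand-in assembled from the well-characterized mature-peptide
#' sequences and is shipped for testing and examples, not as a reference
#' record.
#'
#' @return A [precursor_annotation()].
#' @export
gcg_annotation <- function() {
  protein <- paste0(
    "MKSIYFVAGLFVMLVQGSWQ",                  # signal peptide 1-20
    "RSLQDTEEKSRSFSASQADPLSDPDQMNED",        # GRPP 21-50
    "KR",                                    # cleavage 51-52
    "HSQGTFTSDYSKYLDSRRAQDFVQWLMNT",         # glucagon 53-81
    "KR",                                    # cleavage 82-83
    "NRNNIA",                                # IP-1 84-89
    "KR",                                    # cleavage 90-91
    "HDEFERHAEGTFTSDVSSYLEGQAAKEFIAWLVKGRG", # GLP-1(1-37) 92-128
    "RR",                                    # cleavage 129-130
    "DFPEEVAIVEEL",                          # IP-2 131-142
    "GRR",                                   # spacer + cleavage 143-145
    "HADGSFSDEMNTILDNLAARDFINWLIQTKITD",     # GLP-2 146-178
    "RK")                                    # C-terminal dibasic 179-180
  regions <- data.frame(
    name = c("signal", "GRPP", "glucagon", "IP-1", "GLP-1", "IP-2", "GLP-2",
             "glicentin", "oxyntomodulin", "MPGF"),
    start = c(1, 21, 53, 84, 92, 131, 146, 21, 53, 92),
    end = c(20, 50, 81, 89, 128, 142, 178, 89, 89, 180),
    kind = c("signal", rep("peptide", 6), rep("composite", 3)),
    composite_of = c(rep(NA, 7), "GRPP,glucagon,IP-1", "glucagon,IP-1",
                     "GLP-1,IP-2,GLP-2"),
    stringsAsFactors = FALSE)
  motifs <- data.frame(
    position = c(51, 82, 90, 129, 144, 179),
    motif = c("KR", "KR", "KR", "RR", "RR", "RK"),
    enzyme = c("PC1/3;PC2", "PC2", "PC1/3", "PC1/3", "PC1/3", "PC2"),
    stringsAsFactors = FALSE)
  precursor_annotation(protein, regions, motifs)
}
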