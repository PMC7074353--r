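## Core value types shared by all modules: a (possibly partial) circular
## genome record and the ordered gene table that annotates it.
## Coordinates are 1-based inclusive throughout, GenBank style; an
## origin-spanning feature on a circular genome has end < start.

IUPAC_NT <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N", "-")

FEATURE_CLASSES <- c("PCG", "tRNA", "rRNA", "control")

#' Create a genome record
#'
#' A genome record carries the identity, declared length, topology and
#' (optionally) the nucleotide sequence of a mitogenome. Annotation-only
#' workflows leave `sequence` as `NULL`; runs of ambiguous `N` bases are
#' recorded as gap intervals so downstream composition statistics can
#' account for unsequenced stretches such as a partial control region.
#'
#' @param id accession-like identifier.
#' @param length declared genome length in bp (positive integer).
#' @param circular is the molecule circular?
#' @param sequence IUPAC nucleotide string of exactly `length` characters,
#'   or `NULL` for annotation-only mode. Case-insensitive; stored uppercase.
#' @return an object of class `genome_record` with fields `id`, `length`,
#'   `circular`, `sequence` (or `NULL`) and `gap_runs` (two-column matrix of
#'   1-based start/end of `N` runs).
#' @export
genome_record <- function(id, length, circular = TRUE, sequence = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  length <- as.integer(length)
  if (is.na(length) || length <= 0L)
    stop("genome length must be a positive integer")
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    bad <- setdiff(unique(strsplit(sequence, "")[[1]]), IUPAC_NT)
    if (length(bad) > 0L)
      stop("non-IUPAC characters in sequence: ", paste(bad, collapse = ", "))
    if (nchar(sequence) != length)
      stop(sprintf("sequence length %d does not match declared length %d",
                   nchar(sequence), length))
  }
  structure(
    list(id = id, length = length, circular = isTRUE(circular),
         sequence = sequence, gap_runs = find_gap_runs(sequence)),
    class = "genome_record")
}

# N-run intervals of a sequence, as a start/end matrix (0 rows if none)
find_gap_runs <- function(sequence) {
  if (is.null(sequence))
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  r <- rle(strsplit(sequence, "")[[1]] == "N")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %s, %s\n", x$id, x$length,
              if (x$circular) "circular" else "linear",
              if (is.null(x$sequence)) "annotation-only"
              else sprintf("sequence present (%d N)", sum(x$gap_runs[, 2] - x$gap_runs[, 1] + 1L))))
  invisible(x)
}

#' Span length of a feature with circular wrap
#'
#' @param start,end 1-based inclusive coordinates; `end < start` denotes an
#'   origin-spanning feature and is only legal on a circular genome.
#' @param genome_length genome length in bp.
#' @param circular topology flag.
#' @return integer span in bp.
#' @export
span_length <- function(start, end, genome_length, circular = TRUE) {
  wrap <- end < start
  if (any(wrap & !circular))
    stop("end < start is only permitted on a circular genome")
  ifelse(wrap, genome_length - start + 1L + end, end - start + 1L)
}

#' Construct a single annotated feature
#'
#' @param gene gene symbol (e.g. `nad2`, `cox1`, `trnW`, `rrnL`,
#'   `control_region`).
#' @param klass feature class: one of `PCG`, `tRNA`, `rRNA`, `control`.
#' @param strand `"H"` (heavy) or `"L"` (light); `NA` is accepted for the
#'   control region, which has no coding strand.
#' @param start,end 1-based inclusive coordinates.
#' @param anticodon optional 3-letter anticodon (tRNAs).
#' @param start_codon,stop_codon optional codon annotations (PCGs); the stop
#'   codon may be an incomplete `T` or `TA`.
#' @param declared_length optional length in bp, cross-checked by
#'   [audit_lengths()], never trusted.
#' @param label optional display label as printed in the source table, e.g.
#'   `trnI(gat)`; kept verbatim and never reconciled with `anticodon`.
#' @return a one-row `data.frame` in gene-table layout.
#' @export
feature <- function(gene, klass, strand, start, end, anticodon = NA_character_,
                    start_codon = NA_character_, stop_codon = NA_character_,
                    declared_length = NA_integer_, label = NA_character_) {
  klass <- match.arg(klass, FEATURE_CLASSES)
  if (!is.na(strand) && !strand %in% c("H", "L"))
    stop("strand must be 'H', 'L' or NA")
  data.frame(gene = gene, klass = klass, strand = strand,
             start = as.integer(start), end = as.integer(end),
             anticodon = as.character(anticodon),
             start_codon = as.character(start_codon),
             stop_codon = as.character(stop_codon),
             declared_length = as.integer(declared_length),
             label = ifelse(is.na(label), gene, as.character(label)),
             stringsAsFactors = FALSE)
}

#' Assemble a validated gene table
#'
#' The gene table is the in-memory form of a mitogenome organization table:
#' one row per annotated gene/region, sorted by start coordinate, with the
#' genome length and topology attached as attributes.
#'
#' @param features a `data.frame` of rows built with [feature()] (or with the
#'   same columns).
#' @param genome_length genome length in bp.
#' @param circular topology flag.
#' @return a `data.frame` of class `gene_table` sorted by `start`, with
#'   attributes `genome_length` and `circular`.
#' @export
gene_table <- function(features, genome_length, circular = TRUE) {
  stopifnot(is.data.frame(features))
  genome_length <- as.integer(genome_length)
  if (nrow(features) == 0L) stop("no features")
  dup <- features$gene[duplicated(features$gene)]
  if (length(dup) > 0L)
    stop("duplicate gene name(s): ", paste(unique(dup), collapse = ", "))
  bad <- features$start < 1L | features$start > genome_length |
    features$end < 1L | features$end > genome_length
  if (any(bad))
    stop("coordinates outside [1, genome length] for: ",
         paste(features$gene[bad], collapse = ", "))
  if (!circular && any(features$end < features$start))
    stop("end < start on a linear genome for: ",
         paste(features$gene[features$end < features$start], collapse = ", "))
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  structure(features, genome_length = genome_length, circular = isTRUE(circular),
            class = c("gene_table", "data.frame"))
}

#' @export
print.gene_table <- function(x, ...) {
  cat(sprintf("<gene_table> %d features on a %d bp %s genome\n", nrow(x),
              attr(x, "genome_length"),
              if (attr(x, "circular")) "circular" else "linear"))
  print.data.frame(x, ...)
  invisible(x)
}

#' Genome length of a gene table
#' @param table a [gene_table()].
#' @return integer bp.
#' @export
genome_length <- function(table) attr(table, "genome_length")

#' Is the gene table's genome circular?
#' @param table a [gene_table()].
#' @return logical.
#' @export
is_circular <- function(table) attr(table, "circular")

# 1-based genomic positions covered by a (possibly origin-spanning) span,
# in 5'->3' order along the reference strand
span_positions <- function(start, end, genome_length) {
  if (end >= start) seq.int(start, end)
  else c(seq.int(start, genome_length), seq.int(1L, end))
}

#' Extract the sense-strand sequence of a feature
#'
#' Substring of the genome over the feature span (wrapping across the origin
#' when needed), reverse-complemented for light-strand (`L`) features so the
#' result always reads 5'->3' in the gene's own orientation.
#'
#' @param record a [genome_record()] with sequence present.
#' @param feat a one-row feature (a `data.frame` row of a [gene_table()]).
#' @return character string.
#' @export
feature_sequence <- function(record, feat) {
  if (is.null(record$sequence))
    stop("genome record has no sequence (annotation-only mode)")
  pos <- span_positions(feat$start, feat$end, record$length)
  s <- paste(strsplit(record$sequence, "")[[1]][pos], collapse = "")
  if (!is.na(feat$strand) && feat$strand == "L") revcomp(s) else s
}

#' Reverse complement of a nucleotide string
#'
#' IUPAC-aware; gaps (`-`) are preserved.
#' @param s nucleotide string.
#' @return character string.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
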