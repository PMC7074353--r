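## Circular-genome junction arithmetic: overlaps, intergenic spacers,
## strand partition and length audits.

#' Junction gaps between adjacent genes
#'
#' For consecutive features in coordinate order (wrapping last-to-first on a
#' circular genome) the gap is `downstream_start - upstream_end - 1`, taken
#' modulo the genome length across the origin. Negative values are overlaps
#' (shared bases), positive values intergenic spacers, zero means the genes
#' are contiguous.
#'
#' @param table a [gene_table()].
#' @return `data.frame` with columns `upstream`, `downstream`, `gap`
#'   (signed bp) and `wraps_origin` (logical), one row per adjacent pair in
#'   genome order.
#' @export
junction_gaps <- function(table) {
  L <- genome_length(table)
  n <- nrow(table)
  ## effective (unwrapped) end coordinate of possibly origin-spanning features
  lin_end <- ifelse(table$end < table$start, table$end + L, table$end)
  empty <- data.frame(upstream = character(), downstream = character(),
                      gap = integer(), wraps_origin = logical(),
                      stringsAsFactors = FALSE)
  if (n == 1L) {
    if (!is_circular(table)) return(empty)
    if (lin_end[1] - table$start[1] + 1L >= L) return(empty)  # covers the circle
    return(data.frame(upstream = table$gene[1], downstream = table$gene[1],
                      gap = table$start[1] + L - lin_end[1] - 1L,
                      wraps_origin = TRUE, stringsAsFactors = FALSE))
  }
  up <- seq_len(n - 1L)
  gaps <- data.frame(upstream = table$gene[up], downstream = table$gene[up + 1L],
                     gap = table$start[up + 1L] - lin_end[up] - 1L,
                     wraps_origin = FALSE, stringsAsFactors = FALSE)
  if (is_circular(table)) {
    gaps <- rbind(gaps, data.frame(
      upstream = table$gene[n], downstream = table$gene[1],
      gap = table$start[1] + L - lin_end[n] - 1L,
      wraps_origin = TRUE, stringsAsFactors = FALSE))
  }
  gaps
}

#' Summarize the organization of a mitogenome
#'
#' Aggregates [junction_gaps()] into overlap/spacer totals and counts,
#' reports the largest intergenic spacer with its flanking genes (ties
#' broken by first occurrence in genome order), partitions genes by strand
#' (the control region, having no coding strand, is excluded from strand
#' counts), and totals span length per feature class. When the table carries
#' stop-codon annotations for all protein-coding genes, the total stop-codon
#' bp and the encoded amino-acid residue count `(PCG bp - stop bp)/3` are
#' reported as well.
#'
#' @param table a [gene_table()].
#' @return object of class `organization_summary`: a list with fields
#'   `overlap_total_bp`, `overlap_junctions`, `overlap_range`,
#'   `spacer_total_bp`, `spacer_positions`, `spacer_range`,
#'   `largest_spacer` (list: `bp`, `upstream`, `downstream`),
#'   `strand_counts` (named: `H`, `L`), `class_totals` (named bp per class),
#'   `class_counts`, `pcg_stop_bp`, `pcg_residues`, and `gaps` (the
#'   junction table).
#' @export
summarize_organization <- function(table) {
  gaps <- junction_gaps(table)
  ov <- gaps$gap[gaps$gap < 0L]
  sp <- gaps$gap[gaps$gap > 0L]
  largest <- if (length(sp) > 0L) {
    i <- which(gaps$gap == max(sp))[1]
    list(bp = gaps$gap[i], upstream = gaps$upstream[i],
         downstream = gaps$downstream[i])
  } else list(bp = 0L, upstream = NA_character_, downstream = NA_character_)
  genes <- table[table$klass != "control", , drop = FALSE]
  spans <- span_length(table$start, table$end, genome_length(table),
                       is_circular(table))
  class_totals <- vapply(c("PCG", "tRNA", "rRNA"), function(k)
    sum(spans[table$klass == k]), integer(1))
  class_counts <- vapply(c("PCG", "tRNA", "rRNA", "control"), function(k)
    sum(table$klass == k), integer(1))
  pcg <- table$klass == "PCG"
  stops <- table$stop_codon[pcg]
  pcg_stop_bp <- if (any(pcg) && !anyNA(stops)) sum(nchar(stops)) else NA_integer_
  pcg_residues <- if (!is.na(pcg_stop_bp))
    (class_totals[["PCG"]] - pcg_stop_bp) %/% 3L else NA_integer_
  structure(list(
    overlap_total_bp = sum(-ov), overlap_junctions = length(ov),
    overlap_range = if (length(ov)) range(-ov) else c(0L, 0L),
    spacer_total_bp = sum(sp), spacer_positions = length(sp),
    spacer_range = if (length(sp)) range(sp) else c(0L, 0L),
    largest_spacer = largest,
    strand_counts = c(H = sum(genes$strand == "H", na.rm = TRUE),
                      L = sum(genes$strand == "L", na.rm = TRUE)),
    class_totals = class_totals, class_counts = class_counts,
    pcg_stop_bp = pcg_stop_bp, pcg_residues = pcg_residues,
    gaps = gaps), class = "organization_summary")
}

#' @export
print.organization_summary <- function(x, ...) {
  cat(sprintf("Overlaps: %d bp in %d junctions (%d-%d bp)\n",
              x$overlap_total_bp, x$overlap_junctions,
              x$overlap_range[1], x$overlap_range[2]))
  cat(sprintf("Spacers:  %d bp in %d positions (%d-%d bp); largest %d bp between %s and %s\n",
              x$spacer_total_bp, x$spacer_positions,
              x$spacer_range[1], x$spacer_range[2], x$largest_spacer$bp,
              x$largest_spacer$upstream, x$largest_spacer$downstream))
  cat(sprintf("Strands:  %d heavy (H), %d light (L)\n",
              x$strand_counts[["H"]], x$strand_counts[["L"]]))
  cat(sprintf("Totals:   PCG %d bp, tRNA %d bp, rRNA %d bp\n",
              x$class_totals[["PCG"]], x$class_totals[["tRNA"]],
              x$class_totals[["rRNA"]]))
  if (!is.na(x$pcg_stop_bp))
    cat(sprintf("PCGs:     %d bp of stop codons, %d encoded residues\n",
                x$pcg_stop_bp, x$pcg_residues))
  invisible(x)
}

#' One-line JSON form of an organization summary
#'
#' @param x an `organization_summary`.
#' @return length-1 character, a JSON object with keys `overlap_bp`,
#'   `overlap_n`, `spacer_bp`, `spacer_n`, `largest_spacer`, `strand_H`,
#'   `strand_L`.
#' @export
organization_json <- function(x) {
  stopifnot(inherits(x, "organization_summary"))
  jsonlite::toJSON(list(
    overlap_bp = x$overlap_total_bp, overlap_n = x$overlap_junctions,
    spacer_bp = x$spacer_total_bp, spacer_n = x$spacer_positions,
    largest_spacer = list(bp = x$largest_spacer$bp,
                          upstream = x$largest_spacer$upstream,
                          downstream = x$largest_spacer$downstream),
    strand_H = x$strand_counts[["H"]], strand_L = x$strand_counts[["L"]]),
    auto_unbox = TRUE)
}

#' Audit declared lengths against computed spans
#'
#' @param table a [gene_table()].
#' @return `data.frame` with one row per discrepancy: `gene`, `declared`,
#'   `computed`. Zero rows means every declared length is consistent.
#' @export
audit_lengths <- function(table) {
  spans <- span_length(table$start, table$end, genome_length(table),
                       is_circular(table))
  has <- !is.na(table$declared_length)
  bad <- has & table$declared_length != spans
  data.frame(gene = table$gene[bad], declared = table$declared_length[bad],
             computed = spans[bad], stringsAsFactors = FALSE)
}
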