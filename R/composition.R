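## Base counts, AT/GC skew, and the per-class / per-codon-position
## composition breakdown. Skews follow AT-skew = (A-T)/(A+T) and
## GC-skew = (G-C)/(G+C); ambiguous bases (N and other IUPAC degeneracies)
## are excluded from numerators, denominators and A+T% so that an
## unsequenced stretch never biases the statistics.

#' Nucleotide composition of a sequence
#'
#' @param seq IUPAC nucleotide string (case-insensitive). `U` is counted
#'   with `T`.
#' @return object of class `composition_stats`: list with `counts` (named
#'   integer vector A/T/G/C), `ambiguous` (count of non-ATGC characters),
#'   `length`, `at_percent` (A+T as percent of unambiguous bases),
#'   `at_skew`, `gc_skew` (NA when the corresponding denominator is zero).
#' @export
composition <- function(seq) {
  seq <- chartr("u", "t", tolower(seq))
  chars <- strsplit(seq, "")[[1]]
  counts <- c(A = sum(chars == "a"), T = sum(chars == "t"),
              G = sum(chars == "g"), C = sum(chars == "c"))
  ambiguous <- length(chars) - sum(counts)
  at <- counts[["A"]] + counts[["T"]]
  gc <- counts[["G"]] + counts[["C"]]
  structure(list(
    counts = counts, ambiguous = ambiguous, length = length(chars),
    at_percent = if (at + gc > 0) 100 * at / (at + gc) else NA_real_,
    at_skew = if (at > 0) (counts[["A"]] - counts[["T"]]) / at else NA_real_,
    gc_skew = if (gc > 0) (counts[["G"]] - counts[["C"]]) / gc else NA_real_),
    class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf("%d bp (%d ambiguous): A=%d T=%d G=%d C=%d | A+T %.1f%% AT-skew %.3f GC-skew %.3f\n",
              x$length, x$ambiguous, x$counts[["A"]], x$counts[["T"]],
              x$counts[["G"]], x$counts[["C"]], x$at_percent, x$at_skew, x$gc_skew))
  invisible(x)
}

# sum of composition_stats objects (counts add; ratios recomputed)
combine_composition <- function(stats_list) {
  counts <- Reduce(`+`, lapply(stats_list, `[[`, "counts"))
  amb <- sum(vapply(stats_list, `[[`, integer(1), "ambiguous"))
  at <- counts[["A"]] + counts[["T"]]; gc <- counts[["G"]] + counts[["C"]]
  structure(list(
    counts = counts, ambiguous = amb,
    length = sum(vapply(stats_list, `[[`, integer(1), "length")),
    at_percent = if (at + gc > 0) 100 * at / (at + gc) else NA_real_,
    at_skew = if (at > 0) (counts[["A"]] - counts[["T"]]) / at else NA_real_,
    gc_skew = if (gc > 0) (counts[["G"]] - counts[["C"]]) / gc else NA_real_),
    class = "composition_stats")
}

#' Composition table by feature class and codon position
#'
#' Computes composition rows for the whole genome, all protein-coding genes
#' (sense-strand sequences, light-strand genes reverse-complemented,
#' concatenated in genome order), each of the three codon positions (frames
#' restart at each gene's first base; an incomplete trailing stop codon
#' contributes its bases at positions 1 and 2), and the tRNA and rRNA gene
#' classes (sense strands).
#'
#' @param record a [genome_record()] with sequence.
#' @param table a [gene_table()].
#' @param include_stops include each PCG's (complete or incomplete) stop
#'   codon in the protein-coding rows? Defaults to `TRUE`; the annotated
#'   span is then used verbatim.
#' @return object of class `composition_table`: named list of
#'   `composition_stats` with entries `whole_genome`, `PCG`, `codon_pos1`,
#'   `codon_pos2`, `codon_pos3`, `tRNA`, `rRNA`.
#' @export
composition_table <- function(record, table, include_stops = TRUE) {
  if (is.null(record$sequence))
    stop("composition_table requires sequence (annotation-only mode)")
  pcg_rows <- which(table$klass == "PCG")
  pos_chars <- list(character(), character(), character())
  pcg_chars <- character()
  for (i in pcg_rows) {
    s <- feature_sequence(record, table[i, ])
    n <- nchar(s)
    tail_len <- n %% 3L
    if (!include_stops) {
      stop_len <- if (tail_len > 0L) tail_len else 3L
      s <- substr(s, 1L, n - stop_len)
      n <- nchar(s)
      tail_len <- 0L
    }
    if (n %% 3L != 0L && tail_len == 0L)
      stop("PCG span not a multiple of 3 for gene ", table$gene[i])
    chars <- strsplit(s, "")[[1]]
    frame <- ((seq_len(n) - 1L) %% 3L) + 1L
    for (p in 1:3) pos_chars[[p]] <- c(pos_chars[[p]], chars[frame == p])
    pcg_chars <- c(pcg_chars, chars)
  }
  class_comp <- function(k) {
    idx <- which(table$klass == k)
    if (length(idx) == 0L) return(composition(""))
    combine_composition(lapply(idx, function(i)
      composition(feature_sequence(record, table[i, ]))))
  }
  out <- list(
    whole_genome = composition(record$sequence),
    PCG = composition(paste(pcg_chars, collapse = "")),
    codon_pos1 = composition(paste(pos_chars[[1]], collapse = "")),
    codon_pos2 = composition(paste(pos_chars[[2]], collapse = "")),
    codon_pos3 = composition(paste(pos_chars[[3]], collapse = "")),
    tRNA = class_comp("tRNA"),
    rRNA = class_comp("rRNA"))
  structure(out, class = "composition_table")
}

# round half up to `digits` decimals (display convention of composition tables)
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Composition table as a data frame (display precision)
#'
#' Percentages rounded half-up to one decimal and skews to three, the
#' conventional display precision; underlying [composition_table()] values
#' keep full precision.
#'
#' @param ct a `composition_table`.
#' @return `data.frame` with columns `region`, `T_pct`, `C_pct`, `A_pct`,
#'   `G_pct`, `AT_pct`, `AT_skew`, `GC_skew`.
#' @export
composition_df <- function(ct) {
  stopifnot(inherits(ct, "composition_table"))
  rows <- lapply(names(ct), function(nm) {
    x <- ct[[nm]]
    tot <- sum(x$counts)
    pct <- if (tot > 0) 100 * x$counts / tot else rep(NA_real_, 4)
    data.frame(region = nm,
               T_pct = round_half_up(pct[["T"]]), C_pct = round_half_up(pct[["C"]]),
               A_pct = round_half_up(pct[["A"]]), G_pct = round_half_up(pct[["G"]]),
               AT_pct = round_half_up(x$at_percent),
               AT_skew = round_half_up(x$at_skew, 3L),
               GC_skew = round_half_up(x$gc_skew, 3L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
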