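## CDS extraction on either strand, start/stop classification (including
## single-T and TA incomplete stops completed by polyadenylation), codon
## counting and RSCU under the invertebrate mitochondrial genetic code
## (NCBI transl_table 5: ATA=Met, TGA=Trp, AGA/AGG=Ser; stops TAA/TAG).

#' Genetic code table
#'
#' @param code_id NCBI translation table identifier; default 5, the
#'   invertebrate mitochondrial code.
#' @return named character vector mapping DNA codons to one-letter amino
#'   acids (`*` = stop).
#' @export
genetic_code <- function(code_id = 5) {
  Biostrings::getGeneticCode(as.character(code_id))
}

# translate a character vector of codons; anything not in the table
# (ambiguity, gaps) becomes "X"
translate_codons <- function(codons, code) {
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Extract the coding sequence of a protein-coding gene
#'
#' The annotated span is read on the gene's sense strand (light-strand genes
#' are reverse-complemented). A trailing remainder of 1 or 2 bases is
#' classified as an incomplete stop codon (`T` or `TA`). The start codon is
#' reported verbatim — nonstandard starts such as cox1's CGA are biology,
#' not corruption, and are never "corrected". An in-frame internal stop
#' before the final codon raises a warning naming the codon positions.
#'
#' @param record a [genome_record()] with sequence.
#' @param feat a one-row PCG feature from a [gene_table()].
#' @param code_id genetic code for the internal-stop check (default 5).
#' @return object of class `cds`: list with `gene`, `codons` (character
#'   vector of 3-mers, including a complete terminal stop), `start_codon`,
#'   `stop_codon` (`TAA`/`TAG`/…, or `T`/`TA` when incomplete),
#'   `incomplete_stop` (logical), `span_bp`.
#' @export
extract_cds <- function(record, feat, code_id = 5) {
  if (feat$klass != "PCG") stop("extract_cds requires a PCG feature, got ", feat$klass)
  s <- feature_sequence(record, feat)
  n <- nchar(s)
  tail_len <- n %% 3L
  ncod <- n %/% 3L
  if (ncod == 0L) stop("span too short for a codon in gene ", feat$gene)
  codons <- substring(s, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
  incomplete <- tail_len > 0L
  stop_codon <- if (incomplete) substr(s, n - tail_len + 1L, n) else codons[ncod]
  code <- genetic_code(code_id)
  internal <- codons[seq_len(ncod - 1L)][-1]
  aa <- translate_codons(internal, code)
  if (any(aa == "*"))
    warning(sprintf("premature stop codon(s) in %s at codon position(s) %s",
                    feat$gene, paste(which(aa == "*") + 1L, collapse = ", ")))
  structure(list(gene = feat$gene, codons = codons,
                 start_codon = codons[1], stop_codon = stop_codon,
                 incomplete_stop = incomplete, span_bp = n),
            class = "cds")
}

#' Extract all coding sequences of a genome
#'
#' @param record a [genome_record()] with sequence.
#' @param table a [gene_table()].
#' @param code_id genetic code (default 5).
#' @return named list of [extract_cds()] results, in genome order.
#' @export
extract_all_cds <- function(record, table, code_id = 5) {
  idx <- which(table$klass == "PCG")
  out <- lapply(idx, function(i) extract_cds(record, table[i, ], code_id))
  names(out) <- table$gene[idx]
  out
}

#' Start/stop codon summary with conformity flags
#'
#' @param record a [genome_record()] with sequence.
#' @param table a [gene_table()].
#' @param code_id genetic code (default 5).
#' @return `data.frame` with one row per protein-coding gene: `gene`,
#'   `strand`, `start_codon`, `stop_codon`, `incomplete_stop`, `atn_start`
#'   (does the start codon match `ATN`?).
#' @export
start_stop_summary <- function(record, table, code_id = 5) {
  cds <- extract_all_cds(record, table, code_id)
  data.frame(
    gene = vapply(cds, `[[`, character(1), "gene"),
    strand = table$strand[match(names(cds), table$gene)],
    start_codon = vapply(cds, `[[`, character(1), "start_codon"),
    stop_codon = vapply(cds, `[[`, character(1), "stop_codon"),
    incomplete_stop = vapply(cds, `[[`, logical(1), "incomplete_stop"),
    atn_start = grepl("^AT[ACGT]$", vapply(cds, `[[`, character(1), "start_codon")),
    row.names = NULL, stringsAsFactors = FALSE)
}

# display sub-family labels: Leu and Ser synonym sets are conventionally
# split by codon block (Leu1 = CUN, Leu2 = UUR; Ser1 = AGN, Ser2 = UCN)
AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val")

codon_family_label <- function(codon, aa) {
  lab <- unname(AA3[aa])
  lab[aa == "L"] <- ifelse(startsWith(codon[aa == "L"], "CT"), "Leu1", "Leu2")
  lab[aa == "S"] <- ifelse(startsWith(codon[aa == "S"], "AG"), "Ser1", "Ser2")
  lab
}

#' Relative synonymous codon usage
#'
#' For every sense codon, `RSCU = n_family * count / family_total`, where
#' the family is the codon's full synonym set under the genetic code (Leu1/
#' Leu2 and Ser1/Ser2 are display labels only; the Leu family has 6 members
#' and the table-5 Ser family 8). Stop codons — complete or incomplete — are
#' excluded from counting, as are codons containing ambiguous bases or gaps
#' (their number is reported in the `ambiguous_codons` attribute).
#'
#' @param cds_set list of [extract_cds()] objects (or a character vector of
#'   in-frame nucleotide sequences).
#' @param code_id genetic code (default 5).
#' @return `data.frame` of class `rscu_table`, one row per sense codon:
#'   `codon` (RNA alphabet), `dna_codon`, `aa`, `family`, `n_family`,
#'   `count`, `rscu`; sorted by amino acid then codon. Attributes:
#'   `ambiguous_codons`, `total_codons`, `genetic_code`.
#' @export
rscu <- function(cds_set, code_id = 5) {
  code <- genetic_code(code_id)
  sense <- names(code)[code != "*"]
  if (is.character(cds_set)) {
    cds_set <- lapply(seq_along(cds_set), function(i) {
      s <- toupper(cds_set[[i]])
      n3 <- nchar(s) %/% 3L
      list(codons = substring(s, 3L * seq_len(n3) - 2L, 3L * seq_len(n3)))
    })
  }
  counted <- character()
  for (cds in cds_set) {
    cod <- cds$codons
    ## drop a complete terminal stop; incomplete stops never enter `codons`
    if (length(cod) > 0L && !is.na(code[cod[length(cod)]]) &&
        code[cod[length(cod)]] == "*")
      cod <- cod[-length(cod)]
    counted <- c(counted, cod)
  }
  is_sense <- counted %in% sense
  is_stop <- counted %in% names(code)[code == "*"]
  ambiguous <- sum(!is_sense & !is_stop)
  counts <- table(factor(counted[is_sense], levels = sense))
  aa <- unname(code[sense])
  fam_total <- tapply(as.integer(counts), aa, sum)[aa]
  n_fam <- table(aa)[aa]
  val <- ifelse(fam_total > 0, as.integer(n_fam) * as.integer(counts) / fam_total, 0)
  out <- data.frame(
    codon = chartr("T", "U", sense), dna_codon = sense, aa = aa,
    family = codon_family_label(sense, aa),
    n_family = as.integer(n_fam), count = as.integer(counts),
    rscu = as.numeric(val), stringsAsFactors = FALSE)
  out <- out[order(out$aa, out$codon), ]
  rownames(out) <- NULL
  structure(out, ambiguous_codons = ambiguous,
            total_codons = sum(out$count),
            genetic_code = code_id,
            class = c("rscu_table", "data.frame"))
}
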