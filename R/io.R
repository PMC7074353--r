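## Readers/writers: gene-coordinate TSV (the organization-table dialect),
## FASTA (backed by Biostrings), and a small GenBank flat-file subset
## (LOCUS / FEATURES / ORIGIN with complement() locations).

GENE_TABLE_COLUMNS <- c("Gene", "Strand", "Location", "Length", "Anticodon",
                        "StartCodon", "StopCodon", "OVL_ITS")

# gene symbol -> feature class, the usual mitogenome naming convention
infer_klass <- function(gene) {
  ifelse(grepl("^trn", gene, ignore.case = TRUE), "tRNA",
  ifelse(grepl("^rrn", gene, ignore.case = TRUE), "rRNA",
  ifelse(grepl("control", gene, ignore.case = TRUE), "control", "PCG")))
}

norm_gene_name <- function(gene) {
  g <- gsub("\\s+", "_", trimws(gene))
  g <- sub("\\(.*\\)$", "", g)  # strip anticodon labels like trnI(gat)
  g[grepl("^control", g, ignore.case = TRUE)] <- "control_region"
  g
}

#' Read a gene-coordinate table (TSV)
#'
#' The dialect has a tab-separated header
#' `Gene Strand Location Length Anticodon StartCodon StopCodon OVL_ITS`
#' with locations formatted `start-end` (1-based inclusive) and `-` for
#' missing values. The `OVL_ITS` column — the printed junction gap after
#' each gene (negative = overlap, positive = spacer) — is retained as the
#' attribute `declared_gaps` for cross-checking but is never used as input:
#' all junction arithmetic is recomputed from coordinates.
#'
#' @param path file path.
#' @param genome_length genome length in bp.
#' @param circular topology flag.
#' @return a [gene_table()].
#' @export
read_gene_table <- function(path, genome_length, circular = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = character())
  if (nrow(df) == 0L) stop("no features in ", path)
  missing_cols <- setdiff(c("Gene", "Strand", "Location"), names(df))
  if (length(missing_cols) > 0L)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  loc <- trimws(df$Location)
  ok <- grepl("^[0-9]+-[0-9]+$", loc)
  if (any(!ok))
    stop("malformed location string in row(s): ",
         paste(sprintf("%s ('%s')", df$Gene[!ok], loc[!ok]), collapse = "; "))
  parts <- do.call(rbind, strsplit(loc, "-", fixed = TRUE))
  blank <- function(x) ifelse(is.na(x) | trimws(x) %in% c("", "-"), NA, trimws(x))
  col <- function(nm) if (nm %in% names(df)) blank(as.character(df[[nm]])) else
    rep(NA_character_, nrow(df))
  gene <- norm_gene_name(df$Gene)
  strand <- blank(df$Strand)
  if (any(!is.na(strand) & !strand %in% c("H", "L")))
    stop("strand values must be H, L or '-'")
  feats <- data.frame(
    gene = gene,
    klass = infer_klass(gene),
    strand = strand,
    start = as.integer(parts[, 1]),
    end = as.integer(parts[, 2]),
    anticodon = col("Anticodon"),
    start_codon = col("StartCodon"),
    stop_codon = col("StopCodon"),
    declared_length = suppressWarnings(as.integer(col("Length"))),
    label = trimws(df$Gene),
    stringsAsFactors = FALSE)
  tab <- gene_table(feats, genome_length = genome_length, circular = circular)
  if ("OVL_ITS" %in% names(df)) {
    dg <- suppressWarnings(as.integer(blank(df$OVL_ITS)))
    names(dg) <- gene
    attr(tab, "declared_gaps") <- dg[tab$gene]
  }
  tab
}

#' Write a gene-coordinate table (TSV)
#'
#' Emits the full column set of the dialect read by [read_gene_table()].
#' The `OVL_ITS` column is computed from coordinates via [junction_gaps()]
#' (the gap following each gene); the junction that wraps across the origin
#' is printed as `-`, matching the usual presentation of such tables.
#'
#' @param table a [gene_table()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_gene_table <- function(table, path) {
  gaps <- junction_gaps(table)
  gap_after <- rep(NA_integer_, nrow(table))
  if (nrow(gaps) > 0L) {
    m <- match(gaps$upstream, table$gene)
    keep <- !gaps$wraps_origin
    gap_after[m[keep]] <- gaps$gap[keep]
  }
  dash <- function(x) ifelse(is.na(x), "-", as.character(x))
  out <- data.frame(
    Gene = ifelse(is.na(table$label), table$gene, table$label),
    Strand = dash(table$strand),
    Location = sprintf("%d-%d", table$start, table$end),
    Length = span_length(table$start, table$end, genome_length(table),
                         is_circular(table)),
    Anticodon = dash(table$anticodon),
    StartCodon = dash(table$start_codon),
    StopCodon = dash(table$stop_codon),
    OVL_ITS = dash(gap_after),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read FASTA
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences (names = record ids,
#'   first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  bad <- lapply(seqs, function(s) setdiff(unique(strsplit(s, "")[[1]]), IUPAC_NT))
  offending <- unique(unlist(bad))
  if (length(offending) > 0L)
    stop("non-IUPAC characters in FASTA: ", paste(offending, collapse = ", "))
  seqs
}

#' Write FASTA
#'
#' @param records named character vector of sequences.
#' @param path output file path.
#' @param width line-wrap width.
#' @return invisibly, the path.
#' @export
write_fasta <- function(records, path, width = 70L) {
  ss <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Bundled organization table of the Amara aulica mitogenome
#'
#' The published gene-coordinate table of the nearly complete *Amara aulica*
#' (Carabidae) mitogenome, GenBank accession MN335930: 16,646 bp, 13
#' protein-coding genes, 22 tRNAs, 2 rRNAs and a partial control region.
#' Annotation only — the nucleotide sequence is not bundled and must be
#' fetched from GenBank if sequence-level statistics are wanted.
#'
#' @return a [gene_table()] with 38 features on a 16,646 bp circular genome.
#' @export
amara_aulica_gene_table <- function() {
  path <- system.file("extdata", "amara_aulica_gene_table.tsv",
                      package = "mitoprofile", mustWork = TRUE)
  read_gene_table(path, genome_length = 16646L, circular = TRUE)
}

## ---- GenBank flat-file subset ----------------------------------------------

GB_KEY_TO_KLASS <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                     misc_feature = "control", D_loop = "control")

#' Read a GenBank flat file (subset)
#'
#' Supports the subset sufficient for annotated mitogenomes: a `LOCUS` line
#' (name, length, `circular`/`linear`), a `FEATURES` block with `CDS`,
#' `tRNA`, `rRNA`, `misc_feature`, `D-loop` and `gene` keys, simple and
#' `complement(start..end)` locations (partial markers `<`/`>` tolerated),
#' `/gene` and `/anticodon` qualifiers, and an optional `ORIGIN` sequence
#' block. `complement()` maps to the light strand (`L`). When sequence is
#' present, start/stop codons of protein-coding genes are derived from it.
#'
#' @param path GenBank flat file.
#' @return list with elements `record` ([genome_record()]) and `table`
#'   ([gene_table()]).
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("not a GenBank flat file: missing LOCUS line")
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  id <- toks[2]
  len <- as.integer(toks[which(toks == "bp") - 1L])
  if (is.na(len)) stop("cannot parse length from LOCUS line")
  circular <- any(grepl("circular", toks, ignore.case = TRUE))

  ## ORIGIN block
  sequence <- NULL
  o <- grep("^ORIGIN", lines)
  if (length(o) > 0L) {
    end <- grep("^//", lines)
    end <- if (length(end) > 0L) min(end[end > o[1]]) else length(lines) + 1L
    body <- lines[seq.int(o[1] + 1L, end - 1L)]
    sequence <- toupper(gsub("[0-9 ]", "", paste(body, collapse = "")))
    if (nchar(sequence) == 0L) sequence <- NULL
  }

  ## FEATURES block: key lines start at column 6, qualifiers at column 22
  f0 <- grep("^FEATURES", lines)
  feats <- list()
  if (length(f0) > 0L) {
    i <- f0[1] + 1L
    while (i <= length(lines)) {
      ln <- lines[i]
      if (grepl("^(ORIGIN|CONTIG|//)", ln) || grepl("^\\S", ln)) break
      m <- regmatches(ln, regexec("^ {5}(\\S+)\\s+(\\S.*)$", ln))[[1]]
      if (length(m) == 3L && !startsWith(trimws(ln), "/")) {
        key <- m[2]; locstr <- m[3]
        quals <- character()
        j <- i + 1L
        while (j <= length(lines) && grepl("^ {10,}\\S", lines[j]) &&
               !grepl("^ {5}\\S", lines[j])) {
          quals <- c(quals, trimws(lines[j])); j <- j + 1L
        }
        feats[[length(feats) + 1L]] <- list(key = key, loc = locstr, quals = quals)
        i <- j
      } else i <- i + 1L
    }
  }

  parse_one <- function(f) {
    key <- sub("-", "_", f$key)
    strand <- if (grepl("^complement\\(", f$loc)) "L" else "H"
    core <- gsub("^complement\\(|\\)$", "", f$loc)
    m <- regmatches(core, regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", core))[[1]]
    if (length(m) != 3L)
      stop("unsupported location '", f$loc, "' for feature key ", f$key)
    q <- function(name) {
      hit <- grep(paste0("^/", name, "="), f$quals, value = TRUE)
      if (length(hit) == 0L) return(NA_character_)
      gsub("^\"|\"$", "", sub(paste0("^/", name, "="), "", hit[1]))
    }
    anti <- q("anticodon")
    if (!is.na(anti)) {
      seqm <- regmatches(anti, regexec("seq:([A-Za-z]{3})", anti))[[1]]
      anti <- if (length(seqm) == 2L) toupper(seqm[2]) else toupper(anti)
    }
    gene <- q("gene")
    if (is.na(gene)) gene <- q("product")
    list(key = key, gene = gene, strand = strand,
         start = as.integer(m[2]), end = as.integer(m[3]), anticodon = anti)
  }
  parsed <- lapply(feats, parse_one)

  keep <- vapply(parsed, function(p) p$key %in% names(GB_KEY_TO_KLASS), logical(1))
  main <- parsed[keep]
  ## standalone `gene` keys: kept only when no typed feature shares the name
  genes_only <- parsed[vapply(parsed, function(p) p$key == "gene", logical(1))]
  seen <- vapply(main, function(p) p$gene, character(1))
  for (p in genes_only)
    if (!is.na(p$gene) && !p$gene %in% seen) {
      p$key <- "gene"; main[[length(main) + 1L]] <- p
    }
  if (length(main) == 0L) stop("no features in ", path)

  rows <- lapply(main, function(p) {
    gene <- if (is.na(p$gene)) sprintf("feat_%d_%d", p$start, p$end)
            else norm_gene_name(p$gene)
    klass <- if (p$key %in% names(GB_KEY_TO_KLASS)) GB_KEY_TO_KLASS[[p$key]]
             else infer_klass(gene)
    strand <- if (klass == "control") NA_character_ else p$strand
    feature(gene, klass, strand, p$start, p$end, anticodon = p$anticodon)
  })
  feats_df <- do.call(rbind, rows)
  if (any(feats_df$start > len | feats_df$end > len))
    stop("feature coordinates exceed LOCUS length ", len)
  record <- genome_record(id, len, circular = circular, sequence = sequence)
  table <- gene_table(feats_df, genome_length = len, circular = circular)
  if (!is.null(sequence)) {
    for (i in which(table$klass == "PCG")) {
      cds <- extract_cds(record, table[i, ])
      table$start_codon[i] <- cds$start_codon
      table$stop_codon[i] <- cds$stop_codon
    }
  }
  list(record = record, table = table)
}

#' Write a GenBank flat file (subset)
#'
#' Inverse of [read_genbank()] over the supported subset: `LOCUS`, typed
#' features with `/gene` (and `/anticodon` for tRNAs), and an `ORIGIN`
#' block when the record carries sequence.
#'
#' @param record a [genome_record()].
#' @param table a [gene_table()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_genbank <- function(record, table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s   INV",
                     record$id, record$length,
                     if (record$circular) "circular" else "linear  "), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion.", record$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", record$length), con)
  key_of <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", control = "misc_feature")
  for (i in seq_len(nrow(table))) {
    f <- table[i, ]
    loc <- sprintf("%d..%d", f$start, f$end)
    if (!is.na(f$strand) && f$strand == "L") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-15s %s", key_of[[f$klass]], loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$gene), con)
    if (!is.na(f$anticodon))
      writeLines(sprintf("                     /anticodon=\"(seq:%s)\"",
                         tolower(f$anticodon)), con)
  }
  if (!is.null(record$sequence)) {
    writeLines("ORIGIN", con)
    s <- tolower(record$sequence)
    for (off in seq.int(1L, nchar(s), by = 60L)) {
      chunk <- substr(s, off, min(off + 59L, nchar(s)))
      groups <- regmatches(chunk, gregexpr(".{1,10}", chunk))[[1]]
      writeLines(sprintf("%9d %s", off, paste(groups, collapse = " ")), con)
    }
  }
  writeLines("//", con)
  invisible(path)
}
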