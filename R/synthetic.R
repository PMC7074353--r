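## Seeded generators: an annotated circular mitogenome built from a gene
## layout (defaulting to the 37-gene + control-region ancestral insect
## arrangement, with the published lengths, strands, junction gaps and
## start/stop codons of a carabid mitogenome), and a star-tree codon
## evolution simulator with known per-branch synonymous/nonsynonymous
## substitution counts.

#' Default mitogenome gene layout
#'
#' The ancestral insect arrangement: 13 protein-coding genes, 22 tRNAs,
#' 2 rRNAs and a control region, with realistic lengths, strands, junction
#' gaps (negative = overlap) and codon annotations.
#'
#' @return `data.frame` with columns `gene`, `klass`, `strand`, `length`,
#'   `anticodon`, `start_codon`, `stop_codon`, `gap_after` (gap between this
#'   gene and the next in genome order; the last entry is the gap across the
#'   origin back to the first gene).
#' @export
default_gene_layout <- function() {
  txt <- "gene klass strand length anticodon start_codon stop_codon gap_after
trnI tRNA H 65 GAU - - 3
trnQ tRNA L 69 UUG - - -1
trnM tRNA H 69 CAU - - 0
nad2 PCG H 1026 - ATA TAA 1
trnW tRNA H 68 UCA - - 32
trnC tRNA L 65 GCA - - 2
trnY tRNA L 68 GUA - - 1
cox1 PCG H 1536 - CGA TAA -5
trnL2 tRNA H 66 UAA - - 1
cox2 PCG H 688 - ATG T 0
trnK tRNA H 71 CUU - - 0
trnD tRNA H 67 GUC - - 0
atp8 PCG H 162 - ATT TAA -7
atp6 PCG H 678 - ATG TAA 8
cox3 PCG H 789 - ATG TAA 2
trnG tRNA H 66 UCC - - 0
nad3 PCG H 354 - ATT TAA 0
trnA tRNA H 68 UGC - - -1
trnR tRNA H 67 UCG - - 4
trnN tRNA H 64 GUU - - 0
trnS1 tRNA H 66 GCU - - 2
trnE tRNA H 67 UUC - - -2
trnF tRNA L 68 GAA - - -1
nad5 PCG L 1731 - ATT TAA 0
trnH tRNA L 68 GUG - - -1
nad4 PCG L 1341 - ATG TAA -7
nad4l PCG L 291 - ATT TAA 2
trnT tRNA H 64 UGU - - 0
trnP tRNA L 67 UGG - - 10
nad6 PCG H 516 - ATA TAA -1
cob PCG H 1140 - ATG TAG -2
trnS2 tRNA H 69 UGA - - 16
nad1 PCG L 942 - ATA TAG 10
trnL1 tRNA L 64 UAG - - 4
rrnL rRNA L 1293 - - - 18
trnV tRNA L 72 UGC - - -1
rrnS rRNA L 699 - - - 0
control_region control - 1895 - - - 0"
  df <- utils::read.table(text = txt, header = TRUE, stringsAsFactors = FALSE,
                          na.strings = "-")
  df$strand[df$klass == "control"] <- NA_character_
  df
}

#' Specification for a synthetic annotated mitogenome
#'
#' @param layout gene layout as from [default_gene_layout()].
#' @param at_bias target A+T fraction of the genome (default 0.804, the
#'   typical strong AT bias of beetle mitogenomes). A and T (and G and C)
#'   are drawn symmetrically, so expected skews are 0.
#' @param seed integer seed governing all randomness.
#' @param id record identifier.
#' @param start_overrides named character vector injecting nonstandard start
#'   codons, e.g. `c(nad2 = "GTG")`; applied after the layout's own codons.
#' @param gap_sampler optional `function(n)` returning `n` integer junction
#'   gaps, replacing the layout's `gap_after` for all but the origin-wrap
#'   junction (which stays at the layout value).
#' @return list of class `genome_spec`.
#' @export
genome_spec <- function(layout = default_gene_layout(), at_bias = 0.804,
                        seed = 1L, id = "SYNTHMT01", start_overrides = NULL,
                        gap_sampler = NULL) {
  stopifnot(at_bias > 0, at_bias < 1, is.data.frame(layout))
  structure(list(layout = layout, at_bias = at_bias, seed = as.integer(seed),
                 id = id, start_overrides = start_overrides,
                 gap_sampler = gap_sampler),
            class = "genome_spec")
}

# run expr with a private RNG stream seeded by `seed`
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

sample_bases <- function(n, at_bias) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c(at_bias / 2, at_bias / 2, (1 - at_bias) / 2, (1 - at_bias) / 2))
}

# Expected A+T fraction of a codon drawn base-wise at AT bias p and then
# conditioned on not being a stop (TAA/TAG under table 5). Rejecting the
# AT-rich stops depresses realized A+T below p; the generator inverts this
# analytically so protein-coding regions still hit the genome-wide target.
conditional_at <- function(p) {
  p_taa <- (p / 2)^3
  p_tag <- (p / 2)^2 * (1 - p) / 2
  (3 * p - 3 * p_taa - 2 * p_tag) / (3 * (1 - p_taa - p_tag))
}

calibrate_at_bias <- function(target) {
  stats::uniroot(function(p) conditional_at(p) - target,
                 lower = target, upper = min(0.999, target + 0.1),
                 tol = 1e-9)$root
}

# random sense codons under the AT-biased base distribution (stops rejected)
sample_sense_codons <- function(n, at_bias, code) {
  out <- character(0)
  while (length(out) < n) {
    m <- max(16L, 2L * (n - length(out)))
    cand <- paste0(sample_bases(m, at_bias), sample_bases(m, at_bias),
                   sample_bases(m, at_bias))
    out <- c(out, cand[code[cand] != "*"])
  }
  out[seq_len(n)]
}

write_span <- function(chars, start, s, L) {
  pos <- ((start - 1L + seq_len(nchar(s)) - 1L) %% L) + 1L
  chars[pos] <- strsplit(s, "")[[1]]
  chars
}

#' Generate an annotated synthetic mitogenome
#'
#' Lays the genes of `spec$layout` head to tail around a circle using the
#' layout's junction gaps, samples an AT-biased background sequence, writes
#' in-frame protein-coding sequences (random sense codons, annotated start
#' and stop codons, incomplete stops supported), and repairs any in-frame
#' internal stop codons created where genes overlap. Deterministic for a
#' given seed.
#'
#' @param spec a [genome_spec()].
#' @return list with `record` ([genome_record()]) and `table`
#'   ([gene_table()] whose codon columns carry the realized annotations).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  lay <- spec$layout
  n <- nrow(lay)
  gaps <- lay$gap_after
  if (!is.null(spec$gap_sampler)) {
    g <- as.integer(spec$gap_sampler(n - 1L))
    stopifnot(length(g) == n - 1L)
    gaps[seq_len(n - 1L)] <- g
  }
  if (any(-gaps[-n] >= pmin(lay$length[-n], lay$length[-1])))
    stop("infeasible spec: an overlap meets or exceeds a flanking gene length")
  starts <- cumsum(c(1L, lay$length[-n] + gaps[-n]))
  if (any(starts < 1L)) stop("infeasible spec: negative coordinates")
  ends <- starts + lay$length - 1L
  L <- ends[n] + gaps[n]
  if (L < max(ends)) stop("infeasible spec: genome shorter than its features")

  code <- genetic_code(5)
  with_seed(spec$seed, {
    chars <- sample_bases(L, spec$at_bias)
    feats <- do.call(rbind, lapply(seq_len(n), function(i)
      feature(lay$gene[i], lay$klass[i], lay$strand[i], starts[i], ends[i],
              anticodon = lay$anticodon[i], start_codon = lay$start_codon[i],
              stop_codon = lay$stop_codon[i], declared_length = lay$length[i])))
    if (!is.null(spec$start_overrides)) {
      m <- match(names(spec$start_overrides), feats$gene)
      if (anyNA(m)) stop("start_overrides for unknown gene(s)")
      feats$start_codon[m] <- unname(spec$start_overrides)
    }
    pcg <- which(feats$klass == "PCG")
    place <- function(chars, i, sense_seq, offset = 0L) {
      ## write `sense_seq` at sense-strand offset `offset` within feature i
      if (!is.na(feats$strand[i]) && feats$strand[i] == "L") {
        gstart <- ((feats$end[i] - 1L - offset - (nchar(sense_seq) - 1L)) %% L) + 1L
        write_span(chars, gstart, revcomp(sense_seq), L)
      } else {
        write_span(chars, ((feats$start[i] - 1L + offset) %% L) + 1L, sense_seq, L)
      }
    }
    pcg_bias <- calibrate_at_bias(spec$at_bias)
    for (i in pcg) {
      len <- lay$length[match(feats$gene[i], lay$gene)]
      stop_c <- feats$stop_codon[i]
      body_n <- (len - nchar(stop_c)) %/% 3L
      if ((len - nchar(stop_c)) %% 3L != 0L)
        stop("infeasible spec: length of ", feats$gene[i],
             " incompatible with its stop codon")
      body <- paste(sample_sense_codons(body_n, pcg_bias, code), collapse = "")
      chars <- place(chars, i, paste0(body, stop_c))
    }
    ## stamp start/stop codons last so overlapping neighbours cannot erase them
    for (i in pcg) {
      len <- feats$end[i] - feats$start[i] + 1L
      chars <- place(chars, i, feats$start_codon[i])
      chars <- place(chars, i, feats$stop_codon[i],
                     offset = len - nchar(feats$stop_codon[i]))
    }
    record <- genome_record(spec$id, L, circular = TRUE,
                            sequence = paste(chars, collapse = ""))
    table <- gene_table(feats, genome_length = L, circular = TRUE)
    ## repair in-frame internal stops introduced by overlap overwrites:
    ## rewrite the offending codon's middle base to C (TAA->TCA, TAG->TCG)
    for (pass in 1:30) {
      changed <- FALSE
      for (i in which(table$klass == "PCG")) {
        cds <- suppressWarnings(extract_cds(record, table[i, ]))
        k <- length(cds$codons)
        internal <- which(translate_codons(cds$codons, code) == "*")
        internal <- internal[internal < k]
        for (j in internal) {
          chars <- place(chars, i, paste0(substr(cds$codons[j], 1, 1), "C",
                                          substr(cds$codons[j], 3, 3)),
                         offset = 3L * (j - 1L))
          changed <- TRUE
        }
      }
      if (changed)
        record <- genome_record(spec$id, L, circular = TRUE,
                                sequence = paste(chars, collapse = ""))
      else break
      if (pass == 30L) stop("could not repair internal stop codons (overlap conflict)")
    }
    list(record = record, table = table)
  })
}

#' Specification for star-tree codon evolution
#'
#' @param n_codons codons per sequence (default 300).
#' @param n_taxa number of tip sequences diverged independently from one
#'   ancestor (default 6).
#' @param subs_per_codon expected proposed single-base changes per codon per
#'   branch (default 0.25, giving pairwise synonymous divergence around
#'   0.2-0.3 — the low end of typical mitogenome comparisons, where
#'   proportion-based estimators are near-unbiased).
#' @param omega target ka/ks: proposed nonsynonymous changes are accepted
#'   with this probability, synonymous ones always; changes creating a stop
#'   codon are rejected outright (default 0.1, strong purifying selection as
#'   seen in mitochondrial protein-coding genes).
#' @param seed integer seed.
#' @param code_id genetic code (default 5).
#' @return list of class `evol_spec`.
#' @export
evol_spec <- function(n_codons = 300L, n_taxa = 6L, subs_per_codon = 0.25,
                      omega = 0.1, seed = 1L, code_id = 5) {
  stopifnot(n_codons > 0, n_taxa >= 2, subs_per_codon >= 0, omega > 0)
  structure(list(n_codons = as.integer(n_codons), n_taxa = as.integer(n_taxa),
                 subs_per_codon = subs_per_codon, omega = omega,
                 seed = as.integer(seed), code_id = code_id),
            class = "evol_spec")
}

#' Simulate a coding alignment with known substitution ground truth
#'
#' Each tip evolves from a common ancestral sequence of random sense codons
#' by a Poisson number of proposed single-base changes; nonsynonymous
#' proposals are accepted with probability `omega`, synonymous ones always,
#' and proposals creating stop codons are rejected. Realized accepted
#' synonymous/nonsynonymous event counts are returned per branch and per
#' pair (the sum over the two branches).
#'
#' @param spec an [evol_spec()].
#' @return list with `alignment` (named character vector, `taxon_1`...),
#'   `ancestor`, `branch_truth` (`data.frame`: `taxon`, `syn`, `nonsyn`) and
#'   `pair_truth` (`data.frame`: `a`, `b`, `syn`, `nonsyn`).
#' @export
evolve_cds <- function(spec) {
  stopifnot(inherits(spec, "evol_spec"))
  code <- genetic_code(spec$code_id)
  with_seed(spec$seed, {
    anc <- sample_sense_codons(spec$n_codons, 0.5, code)
    tips <- list(); syn_n <- integer(spec$n_taxa); non_n <- integer(spec$n_taxa)
    for (t in seq_len(spec$n_taxa)) {
      cod <- anc
      n_events <- stats::rpois(1L, spec$subs_per_codon * spec$n_codons)
      for (e in seq_len(n_events)) {
        i <- sample.int(spec$n_codons, 1L)
        p <- sample.int(3L, 1L)
        b <- sample(setdiff(NT, substr(cod[i], p, p)), 1L)
        mut <- cod[i]
        substr(mut, p, p) <- b
        if (code[[mut]] == "*") next
        if (code[[mut]] == code[[cod[i]]]) {
          cod[i] <- mut; syn_n[t] <- syn_n[t] + 1L
        } else if (stats::runif(1L) < spec$omega) {
          cod[i] <- mut; non_n[t] <- non_n[t] + 1L
        }
      }
      tips[[t]] <- paste(cod, collapse = "")
    }
    names(tips) <- paste0("taxon_", seq_len(spec$n_taxa))
    pairs <- utils::combn(spec$n_taxa, 2L)
    pair_truth <- data.frame(
      a = paste0("taxon_", pairs[1, ]), b = paste0("taxon_", pairs[2, ]),
      syn = syn_n[pairs[1, ]] + syn_n[pairs[2, ]],
      nonsyn = non_n[pairs[1, ]] + non_n[pairs[2, ]],
      stringsAsFactors = FALSE)
    list(alignment = unlist(tips), ancestor = paste(anc, collapse = ""),
         branch_truth = data.frame(taxon = names(tips), syn = syn_n,
                                   nonsyn = non_n, stringsAsFactors = FALSE),
         pair_truth = pair_truth)
  })
}
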