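# A tiny hand-built genome: two PCGs (one on each strand), built so every
# expected codon is known by construction.
toy_genome <- function() {
  ## gene fwd: ATG AAA TTT TAA  (12 bp, positions 1-12, H strand)
  fwd <- "ATGAAATTTTAA"
  ## gene rev, sense ATT CCC GGG TA (11 bp, incomplete stop TA), L strand
  rev_sense <- "ATTCCCGGGTA"
  seqs <- paste0(fwd, "GG", revcomp(rev_sense))
  rec <- genome_record("TOY", nchar(seqs), circular = FALSE, sequence = seqs)
  tab <- gene_table(rbind(
    feature("fwd", "PCG", "H", 1, 12, start_codon = "ATG", stop_codon = "TAA"),
    feature("rev", "PCG", "L", 15, 25, start_codon = "ATT", stop_codon = "TA")),
    nchar(seqs), circular = FALSE)
  list(record = rec, table = tab)
}

test_that("extract_cds splits codons and classifies incomplete stops", {
  toy <- toy_genome()
  fwd <- extract_cds(toy$record, toy$table[1, ])
  expect_equal(fwd$codons, c("ATG", "AAA", "TTT", "TAA"))
  expect_equal(fwd$start_codon, "ATG")
  expect_equal(fwd$stop_codon, "TAA")
  expect_false(fwd$incomplete_stop)
  rev <- extract_cds(toy$record, toy$table[2, ])
  expect_equal(rev$codons, c("ATT", "CCC", "GGG"))
  expect_equal(rev$stop_codon, "TA")
  expect_true(rev$incomplete_stop)
  expect_equal(3L * length(rev$codons) + nchar(rev$stop_codon), rev$span_bp)
})

test_that("extract_cds warns on premature internal stops", {
  s <- "ATGTAAAAATAA"  # codon 2 is TAA
  rec <- genome_record("P", nchar(s), circular = FALSE, sequence = s)
  f <- feature("bad", "PCG", "H", 1, 12)
  expect_warning(extract_cds(rec, f), "premature stop.*bad.*2")
})

test_that("extracting an L gene from the reverse-complemented genome is identical", {
  sim <- generate_genome(genome_spec(seed = 31))
  L <- sim$record$length
  flipped <- genome_record("FLIP", L, circular = TRUE,
                           sequence = revcomp(sim$record$sequence))
  for (g in c("nad5", "nad1")) {
    f <- sim$table[sim$table$gene == g, ]
    f2 <- f
    f2$start <- L - f$end + 1L
    f2$end <- L - f$start + 1L
    f2$strand <- "H"
    expect_equal(extract_cds(flipped, f2)$codons,
                 extract_cds(sim$record, f)$codons, label = g)
  }
})

test_that("cox2-style spans give 229 codons plus a single-T stop", {
  sim <- generate_genome(genome_spec(seed = 17))
  cox2 <- extract_cds(sim$record, sim$table[sim$table$gene == "cox2", ])
  expect_equal(cox2$span_bp, 688L)
  expect_equal(length(cox2$codons), 229L)
  expect_equal(cox2$stop_codon, "T")
  expect_true(cox2$incomplete_stop)
})

test_that("start_stop_summary flags exactly the injected nonstandard starts", {
  base <- start_stop_summary(generate_genome(genome_spec(seed = 4))$record,
                             generate_genome(genome_spec(seed = 4))$table)
  expect_equal(base$gene[!base$atn_start], "cox1")  # layout default: CGA
  lay <- default_gene_layout()
  lay$start_codon[lay$gene == "cox1"] <- "ATG"      # all-ATN world
  clean <- generate_genome(genome_spec(layout = lay, seed = 4))
  expect_equal(sum(!start_stop_summary(clean$record, clean$table)$atn_start), 0L)
  for (k in 1:3) {
    inj <- c("GTG", "TTG", "GTT")[seq_len(k)]
    names(inj) <- c("nad3", "atp6", "cob")[seq_len(k)]
    sim <- generate_genome(genome_spec(layout = lay, seed = 4,
                                       start_overrides = inj))
    ss <- start_stop_summary(sim$record, sim$table)
    expect_equal(sum(!ss$atn_start), k)
    expect_setequal(ss$gene[!ss$atn_start], names(inj))
  }
})

test_that("RSCU normalizes to mean 1 per family and handles boundaries", {
  ## uniform family usage -> all 1.0
  uni <- rscu(list(list(codons = c("GGA", "GGC", "GGG", "GGT"))))
  expect_equal(uni$rscu[uni$aa == "G"], rep(1, 4))
  ## 2-codon family all on one member -> 2.0 / 0.0
  sk <- rscu(list(list(codons = c("AAA", "AAA", "AAA"))))
  expect_equal(sk$rscu[sk$dna_codon == "AAA"], 2)
  expect_equal(sk$rscu[sk$dna_codon == "AAG"], 0)
  ## empty input
  expect_equal(sum(rscu(list())$count), 0L)
})

test_that("RSCU family invariants hold on generated data", {
  sim <- generate_genome(genome_spec(seed = 23))
  cds <- extract_all_cds(sim$record, sim$table)
  tab <- rscu(cds)
  used <- tapply(tab$count, tab$aa, sum)
  for (aa in names(used)[used > 0]) {
    expect_equal(mean(tab$rscu[tab$aa == aa]), 1, label = aa)
    expect_equal(sum(tab$rscu[tab$aa == aa]), tab$n_family[tab$aa == aa][1])
  }
  expect_true(all((tab$rscu == 0) == (tab$count == 0)))
  ## stop and incomplete-stop bases excluded: counted codons = (span-stop)/3
  spans <- sim$table[sim$table$klass == "PCG", ]
  expected <- sum((span_length(spans$start, spans$end, sim$record$length) -
                     nchar(spans$stop_codon)) / 3)
  expect_equal(attr(tab, "total_codons"), as.integer(expected))
  ## no internal stops anywhere in the generated CDS set
  code <- genetic_code(5)
  for (cds1 in cds) {
    aa <- code[cds1$codons[-length(cds1$codons)]]
    expect_false(any(aa == "*", na.rm = TRUE), label = cds1$gene)
  }
})

test_that("table-5 idiosyncrasies are honoured (AUA=Met, UGA=Trp, 8-codon Ser)", {
  tab <- rscu(list(list(codons = c("ATA", "TGA", "AGA", "TCA"))))
  expect_equal(tab$aa[tab$dna_codon == "ATA"], "M")
  expect_equal(tab$aa[tab$dna_codon == "TGA"], "W")
  expect_equal(tab$n_family[tab$dna_codon == "AGA"], 8L)  # Ser AGN+UCN
  expect_equal(tab$family[tab$dna_codon == "AGA"], "Ser1")
  expect_equal(tab$family[tab$dna_codon == "TCA"], "Ser2")
  expect_equal(tab$family[tab$dna_codon == "TTA"], "Leu2")
  expect_equal(tab$n_family[tab$dna_codon == "TTA"], 6L)
  ## codons with ambiguity are dropped and reported
  amb <- rscu(list(list(codons = c("ATN", "AT-", "ATG"))))
  expect_equal(attr(amb, "ambiguous_codons"), 2L)
  expect_equal(attr(amb, "total_codons"), 1L)
})
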