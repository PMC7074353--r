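test_that("genome_record validates sequence and records gap runs", {
  r <- genome_record("X1", 10, sequence = "acgtnnNacg")
  expect_equal(r$length, 10L)
  expect_equal(r$sequence, "ACGTNNNACG")
  expect_equal(unname(r$gap_runs[1, ]), c(5L, 7L))
  expect_error(genome_record("X1", 9, sequence = "ACGTACGTAX"),
               "non-IUPAC")
  expect_error(genome_record("X1", 5, sequence = "ACGT"), "does not match")
  r2 <- genome_record("X2", 100)
  expect_null(r2$sequence)
  expect_equal(nrow(r2$gap_runs), 0L)
})

test_that("span_length handles origin-spanning features", {
  expect_equal(span_length(5L, 10L, 100L), 6L)
  expect_equal(span_length(95L, 4L, 100L, circular = TRUE), 10L)
  expect_error(span_length(95L, 4L, 100L, circular = FALSE), "circular")
})

test_that("gene_table enforces uniqueness and bounds", {
  f <- rbind(feature("a", "tRNA", "H", 1, 60),
             feature("b", "PCG", "L", 61, 120))
  tab <- gene_table(f, 200)
  expect_s3_class(tab, "gene_table")
  expect_equal(genome_length(tab), 200L)
  expect_error(gene_table(rbind(f, feature("a", "rRNA", "H", 130, 150)), 200),
               "duplicate")
  expect_error(gene_table(feature("z", "PCG", "H", 1, 300), 200),
               "outside")
  expect_error(gene_table(f[0, ], 200), "no features")
})

test_that("gene table TSV round-trips every field", {
  tab <- amara_aulica_gene_table()
  expect_equal(nrow(tab), 38L)
  expect_equal(as.integer(table(tab$klass)[c("PCG", "tRNA", "rRNA", "control")]),
               c(13L, 22L, 2L, 1L))
  path <- tempfile(fileext = ".tsv")
  write_gene_table(tab, path)
  back <- read_gene_table(path, genome_length(tab), is_circular(tab))
  for (col in c("gene", "klass", "strand", "start", "end", "anticodon",
                "start_codon", "stop_codon", "label"))
    expect_equal(back[[col]], tab[[col]], label = col)
  ## writer emits computed lengths; they equal the published declared ones
  expect_equal(back$declared_length, tab$declared_length)
})

test_that("gene table reader keeps printed labels and the OVL/ITS column untrusted", {
  tab <- amara_aulica_gene_table()
  expect_equal(tab$gene[tab$label == "trnI(gat)"], "trnI")
  ## the trnV row carries label (tac) and anticodon UGC, unreconciled
  expect_equal(tab$anticodon[tab$gene == "trnV"], "UGC")
  expect_equal(tab$label[tab$gene == "trnV"], "trnV(tac)")
  dg <- attr(tab, "declared_gaps")
  expect_equal(unname(dg[["trnW"]]), 32L)
  expect_equal(unname(dg[["atp8"]]), -7L)
})

test_that("gene table reader flags malformed rows", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("Gene\tStrand\tLocation", "nad2\tH\t206..1231"), path)
  expect_error(read_gene_table(path, 16646), "malformed location.*nad2")
  writeLines("Gene\tStrand\tLocation", path)
  expect_error(read_gene_table(path, 16646), "no features")
})

test_that("FASTA round-trips, rejects junk, accepts alignments", {
  path <- tempfile(fileext = ".fa")
  recs <- c(s1 = "ACGTACGTAA", s2 = "ACGTAC-TNA")
  write_fasta(recs, path)
  expect_equal(read_fasta(path), recs)
  writeLines(c(">bad", "ACGJQT"), path)
  expect_error(read_fasta(path), "non-IUPAC.*J")
  ## lower-case and wrapped input is normalized
  writeLines(c(">s1 extra words", "acg", "ta"), path)
  expect_equal(read_fasta(path), c(s1 = "ACGTA"))
})

test_that("GenBank reader parses complement() strands and maps keys", {
  path <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TEST01               9000 bp    DNA     circular INV",
    "FEATURES             Location/Qualifiers",
    "     source          1..9000",
    "     CDS             complement(6347..8077)",
    "                     /gene=\"nad5\"",
    "     tRNA            10..75",
    "                     /gene=\"trnI\"",
    "                     /anticodon=\"(pos:40..42,aa:Ile,seq:gat)\"",
    "     rRNA            complement(8100..8900)",
    "                     /gene=\"rrnS\"",
    "     misc_feature    8901..9000",
    "                     /gene=\"control region\"",
    "//"), path)
  gb <- read_genbank(path)
  expect_null(gb$record$sequence)
  expect_true(gb$record$circular)
  nad5 <- gb$table[gb$table$gene == "nad5", ]
  expect_equal(nad5$klass, "PCG")
  expect_equal(nad5$strand, "L")
  expect_equal(c(nad5$start, nad5$end), c(6347L, 8077L))
  expect_equal(gb$table$anticodon[gb$table$gene == "trnI"], "GAT")
  expect_equal(gb$table$klass[gb$table$gene == "control_region"], "control")
})

test_that("GenBank reader rejects structural problems", {
  path <- tempfile(fileext = ".gb")
  writeLines(c("DEFINITION  no locus here", "//"), path)
  expect_error(read_genbank(path), "LOCUS")
  writeLines(c(
    "LOCUS       T2               100 bp    DNA     linear INV",
    "FEATURES             Location/Qualifiers",
    "     CDS             50..150",
    "                     /gene=\"x\"",
    "//"), path)
  expect_error(read_genbank(path), "exceed")
})

test_that("generator output survives a GenBank round trip", {
  sim <- generate_genome(genome_spec(seed = 11))
  path <- tempfile(fileext = ".gb")
  write_genbank(sim$record, sim$table, path)
  back <- read_genbank(path)
  expect_equal(back$record$length, sim$record$length)
  expect_equal(back$record$sequence, sim$record$sequence)
  for (col in c("gene", "klass", "strand", "start", "end"))
    expect_equal(back$table[[col]], sim$table[[col]], label = col)
  ## codon annotations recomputed from ORIGIN match the generator's table
  pcg <- sim$table$klass == "PCG"
  expect_equal(back$table$start_codon[pcg], sim$table$start_codon[pcg])
  expect_equal(back$table$stop_codon[pcg], sim$table$stop_codon[pcg])
})
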