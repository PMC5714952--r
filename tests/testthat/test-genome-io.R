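test_that("translation follows the invertebrate mitochondrial code", {
  expect_equal(as.character(translate_cds("ATATGA")), "MW")
  expect_equal(as.character(translate_cds("ATGTAA")), "M")
  expect_equal(attr(translate_cds("ATGTAA"), "stop_codon"), "TAA")
  # AGA/AGG are serine, not arginine or stop
  expect_equal(as.character(translate_cds("AGAAGG")), "SS")
  expect_error(translate_cds("ATGTAAAAATAA"), "premature stop.*codon index 2")
})

test_that("truncated stop codons are completed and reported", {
  tr <- translate_cds("ATGT", complete_trailing = TRUE)
  expect_equal(as.character(tr), "M")
  expect_equal(attr(tr, "stop_codon"), "T-")
  expect_true(attr(tr, "truncated_stop"))
  tr2 <- translate_cds("ATGAAATA", complete_trailing = TRUE)
  expect_equal(attr(tr2, "stop_codon"), "TA-")
  expect_error(translate_cds("ATGAAAG", complete_trailing = TRUE),
               "inconsistent with a truncated")
  expect_error(translate_cds("ATGT"), "not a multiple of 3")
})

test_that("translation agrees with an independent per-codon oracle", {
  skip_if_not_installed("seqinr")
  set.seed(42)
  for (rep in 1:5) {
    cds <- random_valid_cds(300)
    mine <- as.character(translate_cds(cds))
    oracle <- paste(seqinr::translate(strsplit(tolower(cds), "")[[1]],
                                      numcode = 5), collapse = "")
    oracle <- sub("\\*$", "", oracle)
    expect_equal(mine, oracle)
  }
})

test_that("extract_gene honours strand and origin wrap", {
  # N-strand feature covering AAACGT must come back reverse-complemented
  g <- toy_genome("TTAAACGTTT", feat("x", 2, 8, strand = "N"))
  expect_equal(extract_gene(g, "x"), "ACGTTT")
  # J-strand verbatim
  gj <- toy_genome("TTAAACGTTT", feat("x", 2, 8, strand = "J"))
  expect_equal(extract_gene(gj, "x"), "AAACGT")
  # origin-spanning feature stitched across position 0
  s <- paste0("ACTCCCCCGT")   # len 10; [8,13) wrap -> "GT" + "ACT"
  gw <- toy_genome(s, feat("w", 8, 13, wrap = TRUE))
  expect_equal(extract_gene(gw, "w"), "GTACT")
  # double reverse complement is the identity
  set.seed(1)
  sq <- random_seq(120)
  gg <- toy_genome(sq, feat("y", 10, 90, strand = "N"))
  ext <- extract_gene(gg, "y")
  expect_equal(mitocomp:::revcomp(mitocomp:::revcomp(ext)), ext)
  expect_error(toy_genome("ACGT", feat("z", 2, 9)), "wrap flag")
})

test_that("genome constructor enforces annotation invariants", {
  expect_error(mito_genome("g", ""), "empty")
  expect_error(mito_genome("g", "ACGU"), "outside")
  expect_error(toy_genome(random_seq(200),
                          rbind(feat("a", 0, 10), feat("a", 50, 60))),
               "annotation conflict")
  expect_error(toy_genome(random_seq(200), feat("t", 0, 20, kind = "tRNA")),
               "\\[55, 80\\]")
  expect_error(toy_genome(random_seq(200), feat("p", 0, 3, kind = "PCG")),
               "shorter than 4")
})

test_that("gene-name canonicalization maps common GenBank spellings", {
  expect_equal(canonicalize_gene_name("ND2"), "nad2")
  expect_equal(canonicalize_gene_name("COI"), "cox1")
  expect_equal(canonicalize_gene_name("CYTB"), "cob")
  expect_equal(canonicalize_gene_name("16S ribosomal RNA"), "rrnL")
  expect_equal(canonicalize_gene_name("tRNA-Ser(AGN)"), "trnS1")
  expect_equal(canonicalize_gene_name("tRNA-Leu(UUR)"), "trnL2")
  expect_equal(canonicalize_gene_name("tRNA-Ala"), "trnA")
  expect_equal(canonicalize_gene_name("tRNA-Leu", anticodon = "TAG"), "trnL1")
  expect_equal(canonicalize_gene_name("trnS1"), "trnS1")
  expect_true(is.na(canonicalize_gene_name("mystery")))
})

test_that("GenBank round-trip preserves a synthetic genome exactly", {
  sim <- simulate_genome(genome_spec(seed = 5))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(sim$genome, path)
  back <- read_genbank(path)
  expect_equal(back$sequence, sim$genome$sequence)
  expect_equal(back$circular, TRUE)
  cols <- c("name", "kind", "start", "end", "strand", "wrap")
  expect_equal(back$features[, cols], sim$genome$features[, cols])
  # every protein-coding gene still translates without premature stops
  pcg <- back$features[back$features$kind == "PCG", ]
  for (i in seq_len(nrow(pcg))) {
    expect_no_error(translate_cds(extract_gene(back, pcg[i, ]),
                                  complete_trailing = TRUE))
  }
})

test_that("GenBank parser handles edge cases", {
  # record with zero features
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       mini 12 bp    DNA     circular UNK",
               "ORIGIN",
               "        1 acgtacgtacgt",
               "//"), path)
  g <- read_genbank(path)
  expect_equal(nrow(g$features), 0L)
  expect_equal(g$sequence, "ACGTACGTACGT")
  # malformed record
  bad <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("not a genbank file"), bad)
  expect_error(read_genbank(bad), "line 1")
})

test_that("per-gene FASTA export writes coding-orientation sequences", {
  sim <- simulate_genome(genome_spec(seed = 6))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_gene_fasta(sim$genome, path, genes = c("cox1", "nad5"))
  x <- Biostrings::readDNAStringSet(path)
  expect_equal(length(x), 2L)
  expect_match(names(x)[1], "\\|cox1\\|J")
  expect_equal(as.character(x[[2]]), extract_gene(sim$genome, "nad5"))
})
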