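make_aln <- function(taxa, len, coding = FALSE, seed = 1) {
  set.seed(seed)
  rows <- vapply(taxa, function(t) random_seq(len), character(1))
  mito_alignment(taxa, rows, coding = coding)
}

test_that("concatenation tiles partitions and fills missing taxa", {
  a <- make_aln(c("t1", "t2", "t3"), 300, seed = 1)
  b <- make_aln(c("t1", "t2", "t3"), 450, seed = 2)
  sm <- concatenate_alignments(list(g1 = a, g2 = b))
  expect_equal(nchar(sm$rows[[1]]), 750)
  expect_equal(sm$partitions$start, c(1, 301))
  expect_equal(sm$partitions$end, c(300, 750))
  # taxon present in gene A only gets gap fill in gene B
  b2 <- make_aln(c("t1", "t2"), 90, seed = 3)
  sm2 <- concatenate_alignments(list(g1 = make_aln(c("t1", "t2", "t3"), 30),
                                     g2 = b2))
  expect_equal(substr(sm2$rows[["t3"]], 31, 120), strrep("-", 90))
  # duplicate taxon is an input error
  dup <- structure(list(ids = c("t1", "t1"),
                        rows = c(t1 = "ACG", t1 = "ACT"),
                        coding = FALSE, frame_offset = 0L),
                   class = "mito_alignment")
  expect_error(concatenate_alignments(list(g = dup)), "duplicate taxon")
})

test_that("13 coding genes yield 39 codon-position partitions", {
  genes <- lapply(1:13, function(i) make_aln(c("t1", "t2", "t3"), 30,
                                             coding = TRUE, seed = i))
  names(genes) <- paste0("pcg", 1:13)
  sm <- concatenate_alignments(genes)
  cp <- codon_partitions(sm)
  expect_equal(nrow(cp), 39)
  expect_true(all(cp$stride == 3))
  # partition tiling: strided column sets cover 1..L exactly once
  cols <- unlist(lapply(seq_len(nrow(cp)), function(i)
    seq(cp$start[i], cp$end[i], by = cp$stride[i])))
  expect_equal(sort(cols), 1:390)
})

test_that("Degen recoding matches hand-derived codons", {
  tab <- degen_table()
  expect_equal(unname(tab[["CTA"]]), "YTN")   # Leu: pos1 C/T, pos3 any
  expect_equal(unname(tab[["ATG"]]), "ATR")   # Met: ATA/ATG under mito code
  expect_equal(unname(tab[["TGG"]]), "TGR")   # Trp: TGA/TGG
  expect_equal(unname(tab[["AGA"]]), "AGN")   # Ser AGN family
  expect_equal(unname(tab[["GGC"]]), "GGN")   # Gly fourfold
})

test_that("Degen table equals the synonymous-component enumeration oracle", {
  code <- mito_code()
  oracle <- degen_component_oracle(code)
  tab <- degen_table(code)
  expect_equal(unname(tab[names(oracle)]), unname(oracle))
})

test_that("Degen recoding is idempotent and never loses the amino acid", {
  code <- mito_code()
  codons <- names(code$table)
  rows <- paste(codons, collapse = "")
  aln <- mito_alignment(c("t1", "t2"), c(rows, rows), coding = TRUE)
  sm <- concatenate_alignments(list(all64 = aln))
  once <- degen_recode(sm, code)
  once$recoding <- "none"
  twice <- degen_recode(once, code)
  expect_equal(twice$rows, once$rows)
  # every expansion set of a recoded sense codon contains the original
  # amino acid, and the original codon itself
  rec <- substring(once$rows[[1]], seq(1, 192, 3), seq(3, 192, 3))
  for (k in seq_along(codons)) {
    aa <- code$table[[codons[k]]]
    if (aa == "*") next
    sets <- lapply(strsplit(rec[k], "")[[1]],
                   function(s) strsplit(Biostrings::IUPAC_CODE_MAP[[s]], "")[[1]])
    expansions <- apply(expand.grid(sets), 1, paste, collapse = "")
    expect_true(codons[k] %in% expansions)
    expect_true(aa %in% unname(code$table[expansions]))
  }
  # gaps and ambiguities propagate as N; non-coding partitions untouched
  g2 <- mito_alignment(c("t1", "t2"), c("AT-GGG", "ATNGGG"), coding = TRUE)
  nc <- mito_alignment(c("t1", "t2"), c("ACGT", "AC-T"))
  sm2 <- degen_recode(concatenate_alignments(list(cod = g2, rrn = nc)))
  expect_equal(substr(sm2$rows[["t1"]], 1, 3), "NNN")
  expect_equal(substr(sm2$rows[["t1"]], 7, 10), "ACGT")
  expect_equal(substr(sm2$rows[["t2"]], 7, 10), "AC-T")
})

test_that("saturation index is 0 for invariant data and ~1 at saturation", {
  inv <- mito_alignment(paste0("t", 1:4), rep(strrep("ACGT", 50), 4))
  expect_equal(saturation_index(inv)$iss_observed, 0)
  # random equal-frequency alignment approaches full saturation
  set.seed(31)
  rows <- vapply(1:8, function(i) random_seq(10000), character(1))
  r <- saturation_index(mito_alignment(paste0("t", 1:8), rows))
  expect_lt(abs(r$iss_observed - 1), 0.02)
  # full-saturation reference is the finite-sample expected site entropy,
  # strictly below the asymptotic 2 bits for 8 sequences
  expect_lt(r$full_saturation_entropy, 2)
  expect_gt(r$full_saturation_entropy, 1.5)
  expect_equal(r$mean_site_entropy, r$iss_observed * r$full_saturation_entropy)
})

test_that("saturation index ignores taxon order and site permutation", {
  set.seed(41)
  rows <- c(random_seq(400), random_seq(400),
            random_seq(400), random_seq(400))
  aln <- mito_alignment(paste0("t", 1:4), rows)
  r1 <- saturation_index(aln)
  r2 <- saturation_index(mito_alignment(paste0("t", 4:1), rev(rows)))
  expect_equal(r1$iss_observed, r2$iss_observed)
  perm <- sample(400)
  rows3 <- vapply(rows, function(s)
    paste(strsplit(s, "")[[1]][perm], collapse = ""), character(1))
  r3 <- saturation_index(mito_alignment(paste0("t", 1:4), unname(rows3)))
  expect_equal(r1$iss_observed, r3$iss_observed)
})

test_that("supermatrix exports round-trip and carry partition lines", {
  genes <- lapply(1:13, function(i) make_aln(c("tax one", "tax_two", "t3"),
                                             30, coding = TRUE, seed = i))
  names(genes) <- paste0("pcg", 1:13)
  sm <- concatenate_alignments(genes)
  prefix <- file.path(withr::local_tempdir(), "mat")
  files <- export_supermatrix(sm, prefix)
  expect_true(file.exists(paste0(prefix, ".phy")))
  back <- read_phylip(paste0(prefix, ".phy"))
  expect_equal(unname(back$rows), unname(sm$rows))
  # sanitized names are mapped
  expect_true(file.exists(paste0(prefix, ".names.tsv")))
  # 39 RAxML partition lines in codon mode
  plines <- readLines(paste0(prefix, ".partitions.txt"))
  expect_length(plines, 39)
  expect_match(plines[1], "^DNA, pcg1_pos1 = 1-30\\\\3$")
  # minimal NEXUS grammar: header, data + sets blocks, matching ENDs
  nex <- readLines(paste0(prefix, ".nex"))
  expect_equal(nex[1], "#NEXUS")
  expect_equal(sum(grepl("^BEGIN", nex)), sum(grepl("^END;", nex)))
  expect_equal(sum(grepl("CHARSET", nex)), 39)
})
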