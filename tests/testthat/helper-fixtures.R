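# shared fixture builders; everything is generated in code

toy_genome <- function(sequence, features, id = "toy", circular = TRUE) {
  mito_genome(id, sequence, features, circular = circular)
}

feat <- function(name, start, end, strand = "J", kind = "other",
                 wrap = FALSE) {
  data.frame(name = name, kind = kind, start = start, end = end,
             strand = strand, anticodon = NA_character_, wrap = wrap,
             stringsAsFactors = FALSE)
}

random_seq <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# a random valid CDS: start codon, stop-free body, TAA stop
random_valid_cds <- function(n_codons,
                             code = mito_code()) {
  stops <- c("TAA", "TAG")
  body <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cod <- random_seq(3)
      if (!cod %in% stops) break
    }
    body[i] <- cod
  }
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

# sequence complementary at every pair of a dot-bracket structure
# (G on the 5' side, C on the 3' side, A at unpaired positions)
seq_for_structure <- function(structure) {
  db <- strsplit(structure, "")[[1L]]
  out <- rep("A", length(db))
  out[db == "("] <- "G"
  out[db == ")"] <- "C"
  paste(out, collapse = "")
}

# Independent oracle for Degen recoding: connected components of the
# graph whose edges are single-position synonymous changes; a codon's
# recoding is the position-wise IUPAC cover of its whole component.
degen_component_oracle <- function(code) {
  codons <- names(code$table)
  acgt <- c("A", "C", "G", "T")
  to_sym <- local({
    cm <- Biostrings::IUPAC_CODE_MAP
    stats::setNames(names(cm), vapply(strsplit(cm, ""), function(s)
      paste(sort(s), collapse = ""), character(1)))
  })
  comp <- stats::setNames(seq_along(codons), codons)
  for (codon in codons) {
    cs <- strsplit(codon, "")[[1]]
    for (p in 1:3) for (b in acgt) {
      mut <- cs; mut[p] <- b
      mc <- paste(mut, collapse = "")
      if (mc != codon && code$table[[mc]] == code$table[[codon]]) {
        old <- comp[[mc]]
        comp[comp == old] <- comp[[codon]]
      }
    }
  }
  vapply(codons, function(codon) {
    members <- codons[comp == comp[[codon]]]
    mm <- do.call(rbind, strsplit(members, ""))
    paste(vapply(1:3, function(p)
      to_sym[[paste(sort(unique(mm[, p])), collapse = "")]],
      character(1)), collapse = "")
  }, character(1))
}

cloverleaf_db <- function() {
  # acceptor stem (7) enclosing DHU (4), anticodon (5) and T-arm (5) hairpins
  paste0("(((((((",
         "..", "((((", ".....", "))))",
         ".", "(((((", ".......", ")))))",
         "..", "(((((", ".....", ")))))",
         ")))))))", "..")
}

no_dhu_db <- function() {
  # DHU arm replaced by an unpaired loop, as in trnS1(AGN)
  paste0("(((((((",
         "...........",
         ".", "(((((", ".......", ")))))",
         "..", "(((((", ".....", ")))))",
         ")))))))", "..")
}
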