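test_that("pairwise stats classify synonymous vs replacement sites", {
  aln0 <- mito_alignment(c("a", "b"), c("ATGAAA", "ATGAAA"),
                         coding = TRUE)
  d0 <- pairwise_stats(aln0, 1, 2)
  expect_equal(c(d0$variable_sites, d0$synonymous, d0$replacement), c(0, 0, 0))
  # ATA vs ATG: Met -> Met, synonymous under the mitochondrial code
  d1 <- pairwise_stats(mito_alignment(c("a", "b"), c("ATA", "ATG"),
                                      coding = TRUE), 1, 2)
  expect_equal(c(d1$variable_sites, d1$synonymous, d1$replacement), c(1, 1, 0))
  # ATT vs ATG: Ile -> Met, replacement
  d2 <- pairwise_stats(mito_alignment(c("a", "b"), c("ATT", "ATG"),
                                      coding = TRUE), 1, 2)
  expect_equal(c(d2$variable_sites, d2$synonymous, d2$replacement), c(1, 0, 1))
  # non-coding alignment counts variable sites only
  d3 <- pairwise_stats(mito_alignment(c("a", "b"), c("ACGT", "ACGA")), 1, 2)
  expect_equal(d3$variable_sites, 1)
  expect_true(is.na(d3$synonymous))
})

test_that("synonymous + replacement equals variable sites on coding pairs", {
  sim <- simulate_genome(genome_spec(seed = 10))
  evo <- evolve_genomes(sim$genome, evolution_spec(seed = 10))
  for (gene in c("cox1", "nad2", "nad5")) {
    aln <- alignment_from_genomes(evo$genomes, gene)
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      d <- pairwise_stats(aln, pair[1], pair[2])
      expect_equal(d$synonymous + d$replacement, d$variable_sites)
      expect_lte(d$variable_sites, d$compared_sites)
    }
  }
})

test_that("pathway counting averages over substitution orderings", {
  # TTA (Leu) vs CTG (Leu): both orderings are fully synonymous
  a <- mito_alignment(c("x", "y"), c("TTA", "CTG"), coding = TRUE)
  dp <- pairwise_stats(a, 1, 2, method = "pathway")
  expect_equal(dp$variable_sites, 2)
  expect_equal(dp$synonymous, 2)
  expect_equal(dp$replacement, 0)
  # single-site differences agree between the two methods
  b <- mito_alignment(c("x", "y"), c("ATAGGA", "ATGGGT"), coding = TRUE)
  expect_equal(pairwise_stats(b, 1, 2, method = "site"),
               pairwise_stats(b, 1, 2, method = "pathway"))
  # pathway counts still sum to the variable-site total
  set.seed(14)
  for (i in 1:10) {
    r1 <- random_valid_cds(20); r2 <- random_valid_cds(20)
    r1 <- substr(r1, 1, nchar(r1) - 3); r2 <- substr(r2, 1, nchar(r2) - 3)
    al <- mito_alignment(c("x", "y"), c(r1, r2), coding = TRUE)
    d <- pairwise_stats(al, 1, 2, method = "pathway")
    expect_equal(d$synonymous + d$replacement, d$variable_sites,
                 tolerance = 1e-9)
  }
})

test_that("nucleotide diversity equals the average pairwise p-distance", {
  expect_equal(nucleotide_diversity(
    mito_alignment(c("a", "b"), c("ACGTACGTAC", "ACGTACGTAC"))), 0)
  # 3 rows of length 10 with pairwise differences 1, 2, 1 -> 4/30
  r1 <- "AAAAAAAAAA"
  r2 <- "AAAAAAAAAT"   # 1 diff vs r1
  r3 <- "AAAAAAAAGT"   # 2 vs r1, 1 vs r2
  aln <- mito_alignment(c("a", "b", "c"), c(r1, r2, r3))
  expect_equal(nucleotide_diversity(aln), (1 / 10 + 2 / 10 + 1 / 10) / 3)
  expect_error(nucleotide_diversity(mito_alignment("a", "ACGT")), "at least 2")
})

test_that("Pi matches hand-summed pairwise distances on tiny alignments", {
  set.seed(8)
  for (i in 1:25) {
    n <- sample(2:5, 1)
    L <- sample(4:10, 1)
    rows <- vapply(seq_len(n), function(k)
      random_seq(L, c(A = .3, C = .2, G = .2, T = .3)), character(1))
    aln <- mito_alignment(paste0("t", 1:n), rows)
    m <- do.call(rbind, strsplit(rows, ""))
    dists <- c()
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      dists <- c(dists, sum(m[a, ] != m[b, ]) / L)
    }
    expect_equal(nucleotide_diversity(aln), mean(dists))
  }
})

test_that("Pi recovers the simulated divergence within binomial error", {
  set.seed(99)
  L <- 4000
  d <- 0.12
  root <- random_seq(L)
  mutate <- function(s, p) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(L) < p)
    for (h in hit) ch[h] <- sample(setdiff(c("A", "C", "G", "T"), ch[h]), 1)
    paste(ch, collapse = "")
  }
  rows <- c(root, mutate(root, d))
  aln <- mito_alignment(c("a", "b"), rows)
  se <- sqrt(d * (1 - d) / L)
  expect_lt(abs(nucleotide_diversity(aln) - d), 3 * se)
})

test_that("sliding windows tile the alignment as the formula predicts", {
  aln <- mito_alignment(c("a", "b", "c"), rep(strrep("ACGTA", 100), 3))
  tr <- sliding_window(aln, 250, 25)
  expect_equal(nrow(tr), floor((500 - 250) / 25) + 1)   # 11 points
  expect_true(all(tr$pi == 0))
  expect_equal(tr$midpoint[1], 125)   # window start (0-based) + window/2
  expect_error(sliding_window(aln, 600, 25), "exceeds")
  # point-count formula on randomized lengths
  set.seed(13)
  for (i in 1:15) {
    L <- sample(120:900, 1)
    w <- sample(50:min(L, 300), 1)
    st <- sample(5:w, 1)
    a2 <- mito_alignment(c("a", "b"),
                         c(random_seq(L), random_seq(L)))
    expect_equal(nrow(sliding_window(a2, w, st)), floor((L - w) / st) + 1)
  }
})

test_that("non-overlapping windows partition the mismatch count", {
  set.seed(17)
  L <- 600; w <- 100
  rows <- c(random_seq(L), random_seq(L))
  aln <- mito_alignment(c("a", "b"), rows)
  tr <- sliding_window(aln, w, w)
  m <- do.call(rbind, strsplit(rows, ""))
  total_mismatch <- sum(m[1, ] != m[2, ])
  expect_equal(sum(tr$pi * w), total_mismatch)
  # and every window's Pi is bounded by the max pairwise distance in it
  expect_true(all(tr$pi <= 1))
})

test_that("pairwise identity counts fully conserved columns, gaps included", {
  expect_equal(pairwise_identity(
    mito_alignment(c("a", "b"), c("ACGT", "ACGT"))), 100)
  expect_equal(pairwise_identity(
    mito_alignment(c("a", "b"), c("AAAA", "AAA-"))), 75)
  # identity degrades monotonically as rows are mutated
  set.seed(23)
  base <- random_seq(300)
  ident <- numeric(4)
  rows <- c(base, base, base)
  for (k in 1:4) {
    ch <- strsplit(rows[3], "")[[1]]
    pos <- sample(300, 15)
    ch[pos] <- vapply(ch[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    rows[3] <- paste(ch, collapse = "")
    ident[k] <- pairwise_identity(mito_alignment(c("a", "b", "c"), rows))
  }
  expect_true(all(diff(ident) <= 0))
})
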