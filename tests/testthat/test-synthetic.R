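test_that("default synthetic genome honours the spec and its truth table", {
  sim <- simulate_genome(genome_spec(seed = 1))
  g <- sim$genome
  expect_s3_class(g, "mito_genome")
  expect_true(nchar(g$sequence) > 14000 && nchar(g$sequence) < 16500)
  # ancestral order, canonical strands
  expect_true(compare_gene_order(
    gene_order(g), ancestral_gene_order()[, c("name", "strand")])$identical)
  # overlaps as specified, including atp8-atp6 at -7
  jx <- junctions(g)
  expect_equal(jx$junctions$gap[jx$junctions$gene_a == "atp8"], -7L)
  expect_equal(jx$overlap_bp, 28L)
  expect_equal(jx$overlap_junctions, 7L)
  # all PCGs translate cleanly, with the configured truncated stops
  ss <- start_stop_report(list(g))
  expect_equal(sort(ss$gene[ss$stop_codon == "T-"]), c("cox2", "nad4"))
  expect_equal(ss$start_codon[ss$gene == "nad5"], "TTG")
  # determinism: same seed, same genome
  sim2 <- simulate_genome(genome_spec(seed = 1))
  expect_identical(sim2$genome$sequence, g$sequence)
  expect_identical(sim2$genome$features, g$features)
})

test_that("whole-genome A+T tracks the requested richness", {
  spec <- genome_spec(seed = 7,
                      at_richness = c(PCG = 0.77, tRNA = 0.77, rRNA = 0.77,
                                      CR = 0.77, spacer = 0.77))
  sim <- simulate_genome(spec)
  at <- base_composition(sim$genome$sequence)$at_percent
  expect_gt(at, 76.0)
  expect_lt(at, 78.0)
})

test_that("with no overlaps, features plus spacers tile the genome exactly", {
  spec <- genome_spec(seed = 5, overlaps = NULL)
  sim <- simulate_genome(spec)
  ft <- sim$genome$features
  jx <- junctions(sim$genome)
  expect_true(all(jx$junctions$gap >= 0))
  expect_equal(sum(ft$end - ft$start) + sum(jx$junctions$gap),
               nchar(sim$genome$sequence))
})

test_that("inconsistent overlap specs are rejected with the junction named", {
  expect_error(genome_spec(overlaps = c("atp8|atp6" = 200L)),
               "atp8\\|atp6")
  expect_error(genome_spec(overlaps = c("trnI|trnQ" = 61L)),
               "trnI\\|trnQ")
  # a coding-coding overlap size with no frame-compatible shared block
  spec <- genome_spec(overlaps = c("atp8|atp6" = 4L))
  expect_error(simulate_genome(spec), "atp8-atp6")
})

test_that("zero branch lengths leave descendants identical to the root", {
  sim <- simulate_genome(genome_spec(seed = 2))
  tr <- mitocomp:::default_tree(0, 0, 0, 0)
  evo <- evolve_genomes(sim$genome, evolution_spec(tree = tr, seed = 1))
  for (g in evo$genomes) expect_identical(g$sequence, sim$genome$sequence)
  expect_equal(nrow(evo$events), 0L)
})

test_that("realized synonymous:replacement ratio matches the spec", {
  sim <- simulate_genome(genome_spec(seed = 3))
  evo <- evolve_genomes(sim$genome, evolution_spec(seed = 2))
  ev <- evo$events[evo$events$class != "noncoding", ]
  expect_gt(nrow(ev), 2000)   # ~1e4 coding sites get multiple thousand events
  ratio <- sum(ev$class == "synonymous") / sum(ev$class == "replacement")
  expect_gt(ratio, 3.2)
  expect_lt(ratio, 4.8)
})

test_that("observed divergence equals realized events when sites are unique", {
  sim <- simulate_genome(genome_spec(seed = 4))
  short <- mitocomp:::default_tree(0.004, 0.004, 0.006, 0.002)
  evo <- evolve_genomes(sim$genome, evolution_spec(tree = short, seed = 6))
  for (gene in c("cox1", "nad5", "cob")) {
    pe <- path_events(evo, "t1", "t2")
    pe <- pe[pe$gene == gene, ]
    # low divergence: every hit site is unique along the path
    expect_false(any(duplicated(pe$pos)))
    aln <- alignment_from_genomes(evo$genomes, gene, strip_stop = FALSE)
    d <- pairwise_stats(mito_alignment(aln$ids[1:2], aln$rows[1:2]), 1, 2)
    expect_equal(d$variable_sites, nrow(pe))
  }
})

test_that("per-gene rate multipliers drive the diversity ranking", {
  sim <- simulate_genome(genome_spec(seed = 9))
  wins <- 0L
  n_seeds <- 50L
  for (s in seq_len(n_seeds)) {
    tr <- mitocomp:::default_tree(0.02, 0.02, 0.03, 0.01)
    evo <- evolve_genomes(sim$genome, evolution_spec(
      tree = tr, per_gene_rate_multipliers = c(cox1 = 0.3, nad2 = 2.0),
      seed = s))
    pi_cox1 <- nucleotide_diversity(alignment_from_genomes(evo$genomes, "cox1"))
    pi_nad2 <- nucleotide_diversity(alignment_from_genomes(evo$genomes, "nad2"))
    if (pi_nad2 > pi_cox1) wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.95 * n_seeds))
})

test_that("a hypervariable block dominates the sliding-window profile", {
  sim <- simulate_genome(genome_spec(seed = 11))
  evo <- evolve_genomes(sim$genome, evolution_spec(
    per_gene_rate_multipliers = c(atp8 = 12, cox1 = 0.05, nad2 = 0.05,
                                  cox2 = 0.05, atp6 = 0.05, cox3 = 0.05,
                                  nad3 = 0.05, nad5 = 0.05, nad4 = 0.05,
                                  nad4l = 0.05, nad6 = 0.05, cob = 0.05,
                                  nad1 = 0.05),
    seed = 3))
  order_names <- ancestral_gene_order()
  pcgs <- order_names$name[order_names$kind == "PCG"]
  alns <- lapply(pcgs, function(g) alignment_from_genomes(evo$genomes, g))
  names(alns) <- pcgs
  sm <- concatenate_alignments(alns)
  aln <- mito_alignment(sm$taxa, sm$rows)
  tr <- sliding_window(aln, 150, 25)
  peak <- tr$midpoint[which.max(tr$pi)]
  atp8_part <- sm$partitions[sm$partitions$name == "atp8", ]
  expect_gte(peak, atp8_part$start - 150)
  expect_lte(peak, atp8_part$end + 150)
})
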