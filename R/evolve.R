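#' Specification for evolving descendant genomes
#'
#' A rooted tree with branch lengths in expected substitutions per site,
#' a synonymous-to-replacement acceptance ratio for protein-coding
#' regions, per-gene rate multipliers (defaults mirror the typical
#' variability ranking of insect mitogenomes: atp8, nad6 and nad2 fast;
#' cox1 and nad4l slow), and a transition bias. No indels are simulated,
#' so descendant sequences stay column-aligned with the root.
#'
#' @param tree Data frame of edges `parent`, `child`, `length`; tips are
#'   taxa. Default: a rooted 3-taxon tree ((t1,t2),t3) with tip-to-tip
#'   distances around 0.12-0.20.
#' @param syn_rep_ratio Ratio of synonymous to replacement substitutions
#'   accepted in coding regions (> 0).
#' @param per_gene_rate_multipliers Named numeric vector of relative
#'   rates (> 0); unnamed genes get 1.
#' @param transition_bias Weight of transitions relative to each
#'   transversion when drawing the new base.
#' @param seed Integer seed.
#' @return Object of class `evolution_spec`.
#' @export
evolution_spec <- function(tree = default_tree(),
                           syn_rep_ratio = 4,
                           per_gene_rate_multipliers = c(atp8 = 2.0,
                                                         nad6 = 1.8,
                                                         nad2 = 1.7,
                                                         cox1 = 0.5,
                                                         nad4l = 0.55),
                           transition_bias = 2,
                           seed = 1L) {
  if (any(tree$length < 0)) stop("negative branch length")
  if (syn_rep_ratio <= 0) stop("syn_rep_ratio must be positive")
  if (any(per_gene_rate_multipliers <= 0)) stop("rate multipliers must be positive")
  structure(list(tree = tree, syn_rep_ratio = syn_rep_ratio,
                 per_gene_rate_multipliers = per_gene_rate_multipliers,
                 transition_bias = transition_bias, seed = as.integer(seed)),
            class = "evolution_spec")
}

default_tree <- function(t1 = 0.06, t2 = 0.06, t3 = 0.10, stem = 0.04) {
  data.frame(parent = c("root", "anc", "anc", "root"),
             child = c("anc", "t1", "t2", "t3"),
             length = c(stem, t1, t2, t3), stringsAsFactors = FALSE)
}

tree_tips <- function(tree) setdiff(tree$child, tree$parent)

# branches from root down to a node
path_to_root <- function(tree, node) {
  path <- character(0)
  while (node != "root") {
    i <- match(node, tree$child)
    if (is.na(i)) stop("node '", node, "' not in tree")
    path <- c(tree$child[i], path)
    node <- tree$parent[i]
  }
  path
}

#' Evolve descendant genomes along a tree
#'
#' Applies per-site substitutions branch by branch. Within protein-coding
#' genes each substitution is synonymous with probability r/(1+r)
#' (r = `syn_rep_ratio`) and the concrete site/base is drawn from the
#' currently available candidates of that class, so the realized
#' synonymous:replacement ratio matches r in expectation and premature
#' stops are never created. Positions shared by two annotated genes
#' (overlaps) are frozen. Annotations carry over unchanged (no indels).
#'
#' @param genome Root [mito_genome()] with PCG annotations.
#' @param espec An [evolution_spec()].
#' @param code A [mito_code()].
#' @return List: `genomes` (named list of tip [mito_genome()]s), `events`
#'   (data frame `branch`, `gene`, `pos` (coding position for PCGs,
#'   J-strand position otherwise), `from`, `to`, `class`), `tree`.
#' @export
evolve_genomes <- function(genome, espec = evolution_spec(),
                           code = mito_code()) {
  with_seed(espec$seed, evolve_impl(genome, espec, code))
}

evolve_impl <- function(genome, espec, code) {
  ft <- genome$features
  L <- genome_length(genome)
  cover <- integer(L)
  for (i in seq_len(nrow(ft))) {
    idx <- ((ft$start[i]:(ft$end[i] - 1L)) %% L) + 1L
    cover[idx] <- cover[idx] + 1L
  }
  frozen <- cover >= 2L

  mult <- function(gene) {
    m <- espec$per_gene_rate_multipliers
    if (gene %in% names(m)) m[[gene]] else 1
  }

  node_seq <- list(root = genome$sequence)
  events <- list()
  # process edges parents-first
  edges <- espec$tree
  done <- "root"
  remaining <- seq_len(nrow(edges))
  while (length(remaining) > 0L) {
    ready <- remaining[edges$parent[remaining] %in% done]
    if (length(ready) == 0L) stop("tree edges do not connect to the root")
    for (e in ready) {
      res <- mutate_branch(node_seq[[edges$parent[e]]], edges$length[e],
                           edges$child[e], ft, frozen, mult, espec, code, L)
      node_seq[[edges$child[e]]] <- res$seq
      events[[length(events) + 1L]] <- res$events
      done <- c(done, edges$child[e])
    }
    remaining <- setdiff(remaining, ready)
  }

  tips <- tree_tips(espec$tree)
  genomes <- lapply(tips, function(t) {
    mito_genome(t, node_seq[[t]], ft, circular = genome$circular)
  })
  names(genomes) <- tips
  ev <- do.call(rbind, events)
  list(genomes = genomes, events = ev, tree = espec$tree)
}

mutate_branch <- function(seq, bl, branch, ft, frozen, mult, espec, code, L) {
  events <- list()
  if (bl > 0) {
    # protein-coding genes, in coding orientation
    for (i in which(ft$kind == "PCG")) {
      f <- ft[i, , drop = FALSE]
      cds <- chars_of(extract_region(seq, f, L))
      gpos <- region_positions(f, L)            # J-strand positions, 5'->3' J
      cpos_of <- if (f$strand == "N") rev(seq_along(gpos)) else seq_along(gpos)
      mutable <- !frozen[gpos][order(cpos_of)]  # indexed by coding position
      rate <- min(1, bl * mult(f$name))
      n_ev <- stats::rbinom(1L, sum(mutable), rate)
      if (n_ev > 0L) {
        res <- mutate_cds(cds, mutable, n_ev, espec, code)
        cds <- res$cds
        if (nrow(res$events) > 0L) {
          res$events$branch <- branch
          res$events$gene <- f$name
          events[[length(events) + 1L]] <- res$events
        }
      }
      seq <- write_region(seq, f, L, paste(cds, collapse = ""))
    }
    # everything outside PCGs: tRNA/rRNA/CR features and intergenic bases
    covered_pcg <- logical(L)
    for (i in which(ft$kind == "PCG")) {
      covered_pcg[region_positions(ft[i, , drop = FALSE], L)] <- TRUE
    }
    chars <- chars_of(seq)
    segments <- non_pcg_segments(ft, L)
    for (snm in names(segments)) {
      pos <- segments[[snm]]
      pos <- pos[!frozen[pos] & !covered_pcg[pos]]
      if (length(pos) == 0L) next
      rate <- min(1, bl * mult(snm))
      n_ev <- stats::rbinom(1L, length(pos), rate)
      if (n_ev == 0L) next
      hit <- sample(pos, n_ev)
      for (p in hit) {
        old <- chars[p]
        if (!old %in% c("A", "C", "G", "T")) next
        new <- draw_base(old, espec$transition_bias)
        chars[p] <- new
        events[[length(events) + 1L]] <- data.frame(
          branch = branch, gene = snm, pos = p, from = old, to = new,
          class = "noncoding", stringsAsFactors = FALSE)
      }
    }
    seq <- paste(chars, collapse = "")
  }
  ev <- if (length(events) > 0L) do.call(rbind, events) else
    data.frame(branch = character(), gene = character(), pos = integer(),
               from = character(), to = character(), class = character(),
               stringsAsFactors = FALSE)
  list(seq = seq, events = ev[, c("branch", "gene", "pos", "from", "to", "class")])
}

chars_of <- function(s) strsplit(s, "")[[1L]]

extract_region <- function(seq, f, L) {
  s <- seq_slice(seq, f$start, f$end, wrap = isTRUE(f$wrap))
  if (identical(f$strand, "N")) revcomp(s) else s
}

# 1-based J-strand positions of a feature, in J order
region_positions <- function(f, L) {
  ((f$start:(f$end - 1L)) %% L) + 1L
}

write_region <- function(seq, f, L, coding) {
  jseq <- if (identical(f$strand, "N")) revcomp(coding) else coding
  pos <- region_positions(f, L)
  chars <- chars_of(seq)
  chars[pos] <- chars_of(jseq)
  paste(chars, collapse = "")
}

non_pcg_segments <- function(ft, L) {
  segs <- list()
  covered <- logical(L)
  for (i in seq_len(nrow(ft))) {
    f <- ft[i, , drop = FALSE]
    pos <- region_positions(f, L)
    if (f$kind != "PCG") segs[[f$name]] <- pos
    covered[pos] <- TRUE
  }
  inter <- which(!covered)
  if (length(inter) > 0L) segs[["intergenic"]] <- inter
  segs
}

transitions <- c(A = "G", G = "A", C = "T", T = "C")

draw_base <- function(old, bias) {
  alts <- setdiff(c("A", "C", "G", "T"), old)
  w <- ifelse(alts == transitions[[old]], bias, 1)
  sample(alts, 1L, prob = w)
}

# apply n_ev substitutions to a coding sequence; each is synonymous with
# probability r/(1+r), drawing site and base from the candidates of that
# class under the current sequence; stops are never created
mutate_cds <- function(cds, mutable, n_ev, espec, code) {
  r <- espec$syn_rep_ratio
  bias <- espec$transition_bias
  events <- list()
  acgt <- c("A", "C", "G", "T")
  n <- length(cds)
  for (k in seq_len(n_ev)) {
    want_syn <- stats::runif(1L) < r / (1 + r)
    placed <- FALSE
    for (try in 1:100) {
      p <- sample.int(n, 1L)
      if (!mutable[p] || !cds[p] %in% acgt) next
      ci <- (p - 1L) %/% 3L
      idx <- ci * 3L + 1:3
      if (any(idx > n)) next                     # truncated trailing codon
      codon <- cds[idx]
      if (!all(codon %in% acgt)) next
      aa <- code$table[paste(codon, collapse = "")]
      if (aa == "*") next                        # never touch the stop
      wp <- p - idx[1L] + 1L
      cand <- setdiff(acgt, cds[p])
      ok <- vapply(cand, function(b) {
        mut <- codon; mut[wp] <- b
        aa2 <- code$table[paste(mut, collapse = "")]
        if (aa2 == "*") return(NA)
        identical(unname(aa2), unname(aa))
      }, logical(1))
      cand <- cand[!is.na(ok) & (ok == want_syn)]
      if (length(cand) == 0L) next
      w <- ifelse(cand == transitions[[cds[p]]], bias, 1)
      new <- if (length(cand) == 1L) cand else sample(cand, 1L, prob = w)
      events[[length(events) + 1L]] <- data.frame(
        pos = p, from = cds[p], to = new,
        class = if (want_syn) "synonymous" else "replacement",
        stringsAsFactors = FALSE)
      cds[p] <- new
      placed <- TRUE
      break
    }
    # if no candidate site found in 100 tries the event is dropped
  }
  ev <- if (length(events) > 0L) do.call(rbind, events) else
    data.frame(pos = integer(), from = character(), to = character(),
               class = character(), stringsAsFactors = FALSE)
  list(cds = cds, events = ev)
}

#' Substitution events along the path between two tips
#'
#' @param evo Result of [evolve_genomes()].
#' @param a,b Tip names.
#' @return Subset of the events table lying on the path a..b (branches in
#'   the symmetric difference of the two root paths).
#' @export
path_events <- function(evo, a, b) {
  pa <- path_to_root(evo$tree, a)
  pb <- path_to_root(evo$tree, b)
  branches <- c(setdiff(pa, pb), setdiff(pb, pa))
  evo$events[evo$events$branch %in% branches, , drop = FALSE]
}

#' Per-gene ungapped alignment from evolved genomes
#'
#' Extracts one gene from each genome (identical coordinates, no indels)
#' and returns the alignment; for coding genes the terminal (possibly
#' truncated) stop is trimmed.
#'
#' @param genomes Named list of [mito_genome()]s sharing annotations.
#' @param gene Gene name.
#' @param strip_stop Trim the stop codon from coding genes (default
#'   `TRUE`).
#' @return A [mito_alignment()].
#' @export
alignment_from_genomes <- function(genomes, gene, strip_stop = TRUE) {
  rows <- vapply(genomes, function(g) extract_gene(g, gene), character(1))
  kind <- genomes[[1L]]$features$kind[genomes[[1L]]$features$name == gene]
  coding <- identical(kind, "PCG")
  if (coding && strip_stop) {
    n <- nchar(rows[1L])
    keep <- if (n %% 3L == 0L) n - 3L else n - n %% 3L
    rows <- substr(rows, 1L, keep)
  }
  mito_alignment(names(genomes), rows, coding = coding)
}
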