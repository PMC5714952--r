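#' Specification for a synthetic insect mitogenome
#'
#' Defines the study conditions the generator emulates: a 15-16 kb
#' circular genome in the ancestral insect gene order with canonical
#' strands, per-gene lengths near those reported for deltocephaline
#' leafhoppers, region-class A+T richness around 76-83%, positive
#' J-strand AT-skew and negative GC-skew, the conserved 1-8 bp gene
#' overlaps (atp8-atp6 7 bp, nad4-nad4l 7 bp, trnW-trnC 8 bp, trnI-trnQ
#' 3 bp, trnR-trnN 1 bp, trnN-trnS1 1 bp, nad6-cob 1 bp), truncated
#' T stops on cox2 and nad4, and an A+T-rich control region.
#'
#' @param gene_lengths Named integer vector overriding default gene
#'   lengths (bp).
#' @param at_richness Named vector of target A+T fractions per region
#'   class (`PCG`, `tRNA`, `rRNA`, `CR`, `spacer`).
#' @param at_skew,gc_skew J-strand skew targets.
#' @param overlaps Named integer vector `"geneA|geneB" = bp` of junction
#'   overlaps; `NULL` or an empty vector disables all overlaps.
#' @param spacers Named integer vector `"geneA|geneB" = bp` of fixed
#'   intergenic spacers; junctions not named in either table abut.
#' @param truncated_stops Genes ending in a truncated T stop.
#' @param cr_length Control-region length (bp).
#' @param trna_length_range Range from which tRNA lengths are drawn.
#' @param seed Integer seed; all randomness flows from it.
#' @return Object of class `genome_spec`.
#' @export
genome_spec <- function(gene_lengths = NULL,
                        at_richness = c(PCG = 0.760, tRNA = 0.770,
                                        rRNA = 0.800, CR = 0.830,
                                        spacer = 0.800),
                        at_skew = 0.08, gc_skew = -0.16,
                        overlaps = default_overlaps(),
                        spacers = default_spacers(),
                        truncated_stops = c("cox2", "nad4"),
                        cr_length = 847L,
                        trna_length_range = c(61L, 71L),
                        seed = 1L) {
  lens <- default_gene_lengths()
  if (!is.null(gene_lengths)) lens[names(gene_lengths)] <- gene_lengths
  if (any(lens <= 0L)) stop("gene lengths must be positive")
  if (any(at_richness <= 0 | at_richness >= 1)) {
    stop("at_richness targets must lie in (0, 1)")
  }
  if (is.null(overlaps)) overlaps <- integer(0)
  tmpl <- ancestral_gene_order()
  for (j in names(overlaps)) {
    gg <- strsplit(j, "|", fixed = TRUE)[[1L]]
    flank_len <- vapply(gg, function(g) {
      if (g %in% names(lens)) lens[[g]]
      else if (g == "CR") as.integer(cr_length)
      else as.integer(trna_length_range[1L])
    }, integer(1))
    if (any(overlaps[[j]] >= flank_len)) {
      stop("overlap at junction ", j, " not shorter than both flanking genes")
    }
    if (!all(gg %in% tmpl$name)) stop("unknown junction ", j)
  }
  structure(list(gene_lengths = lens, at_richness = at_richness,
                 at_skew = at_skew, gc_skew = gc_skew,
                 overlaps = overlaps, spacers = spacers,
                 truncated_stops = truncated_stops,
                 cr_length = as.integer(cr_length),
                 trna_length_range = as.integer(trna_length_range),
                 seed = as.integer(seed)),
            class = "genome_spec")
}

default_gene_lengths <- function() {
  c(nad2 = 975L, cox1 = 1536L, cox2 = 682L, atp8 = 153L, atp6 = 654L,
    cox3 = 780L, nad3 = 354L, nad5 = 1668L, nad4 = 1309L, nad4l = 273L,
    nad6 = 477L, cob = 1137L, nad1 = 933L,
    rrnL = 1199L, rrnS = 739L)
}

default_overlaps <- function() {
  c("trnI|trnQ" = 3L, "trnW|trnC" = 8L, "atp8|atp6" = 7L,
    "trnR|trnN" = 1L, "trnN|trnS1" = 1L, "nad4|nad4l" = 7L,
    "nad6|cob" = 1L)
}

default_spacers <- function() {
  c("trnY|cox1" = 26L, "nad4l|trnT" = 2L, "trnP|nad6" = 2L)
}

default_start_codons <- function() {
  c(nad2 = "ATA", cox1 = "ATG", cox2 = "ATA", atp8 = "ATT", atp6 = "ATG",
    cox3 = "ATG", nad3 = "ATT", nad5 = "TTG", nad4 = "ATG", nad4l = "ATT",
    nad6 = "ATA", cob = "ATG", nad1 = "ATA")
}

# base sampling probabilities on the J strand for a region class
class_probs <- function(spec, class) {
  t <- spec$at_richness[[class]]
  c(A = t * (1 + spec$at_skew) / 2, T = t * (1 - spec$at_skew) / 2,
    G = (1 - t) * (1 + spec$gc_skew) / 2, C = (1 - t) * (1 - spec$gc_skew) / 2)
}

random_bases <- function(n, probs) {
  if (n == 0L) return("")
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# Rejecting stop codons (TAA/TAG) depletes A/T-rich codons, so sampling
# bases at the target A+T fraction undershoots it. Solve for the base-level
# fraction whose stop-conditioned expectation hits the target (exact 64-codon
# enumeration; skews held fixed).
stop_adjusted_probs <- function(probs, code) {
  t0 <- probs[["A"]] + probs[["T"]]
  s_at <- (probs[["A"]] - probs[["T"]]) / t0
  gc <- probs[["G"]] + probs[["C"]]
  s_gc <- if (gc > 0) (probs[["G"]] - probs[["C"]]) / gc else 0
  at_given_nonstop <- function(t) {
    p <- c(A = t * (1 + s_at) / 2, T = t * (1 - s_at) / 2,
           G = (1 - t) * (1 + s_gc) / 2, C = (1 - t) * (1 - s_gc) / 2)
    codons <- names(code$table)
    cp <- vapply(strsplit(codons, ""), function(b) prod(p[b]), numeric(1))
    at <- vapply(strsplit(codons, ""), function(b) sum(b %in% c("A", "T")),
                 numeric(1))
    keep <- !codons %in% stop_codons(code)
    sum(cp[keep] * at[keep]) / (3 * sum(cp[keep]))
  }
  t_adj <- tryCatch(
    stats::uniroot(function(t) at_given_nonstop(t) - t0,
                   interval = c(max(t0 - 0.08, 0.02), min(t0 + 0.08, 0.98)),
                   tol = 1e-6)$root,
    error = function(e) t0)
  c(A = t_adj * (1 + s_at) / 2, T = t_adj * (1 - s_at) / 2,
    G = (1 - t_adj) * (1 + s_gc) / 2, C = (1 - t_adj) * (1 - s_gc) / 2)
}

# a valid coding sequence: given start codon, total length (mod 3 = 0 for
# complete TAA stop, = 1 for truncated T), internal codons free of stops
random_cds <- function(length, start_codon, probs, truncated, code) {
  probs <- stop_adjusted_probs(probs, code)
  n_body <- if (truncated) (length - 1L) %/% 3L - 1L else length %/% 3L - 2L
  if (n_body < 0L) stop("coding gene too short")
  bases <- matrix(sample(names(probs), 3L * max(n_body, 1L), replace = TRUE,
                         prob = probs), ncol = 3L)
  codons <- apply(bases, 1L, paste, collapse = "")
  if (n_body == 0L) codons <- character(0) else codons <- codons[seq_len(n_body)]
  bad <- which(codons %in% stop_codons(code))
  while (length(bad) > 0L) {
    codons[bad] <- apply(matrix(sample(names(probs), 3L * length(bad),
                                       replace = TRUE, prob = probs),
                                ncol = 3L), 1L, paste, collapse = "")
    bad <- which(codons %in% stop_codons(code))
  }
  tail_nt <- if (truncated) "T" else "TAA"
  paste0(start_codon, paste(codons, collapse = ""), tail_nt)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Simulate an annotated mitogenome with known truth
#'
#' Generates a circular genome honouring the gene order, strands,
#' overlaps (shared bases chosen to satisfy both genes' reading frames),
#' truncated stops and per-region composition targets of its
#' [genome_spec()], together with a truth table recording every feature,
#' junction gap and composition target for downstream assertions.
#'
#' @param spec A [genome_spec()].
#' @param code A [mito_code()].
#' @return List: `genome` (a [mito_genome()]) and `truth` (list with
#'   `features`, `junctions`, `targets`, `seed`).
#' @export
simulate_genome <- function(spec = genome_spec(), code = mito_code()) {
  with_seed(spec$seed, simulate_genome_impl(spec, code))
}

simulate_genome_impl <- function(spec, code) {
  tmpl <- ancestral_gene_order()
  n <- nrow(tmpl)
  starts_tab <- default_start_codons()

  lens <- integer(n)
  gseq <- character(n)
  for (i in seq_len(n)) {
    nm <- tmpl$name[i]; kind <- tmpl$kind[i]; strand <- tmpl$strand[i]
    if (kind == "PCG") {
      len <- spec$gene_lengths[[nm]]
      probs <- class_probs(spec, "PCG")
      if (strand == "N") {
        # coding-strand probabilities complemented so the J-strand
        # composition matches the class target
        probs <- c(A = probs[["T"]], T = probs[["A"]],
                   G = probs[["C"]], C = probs[["G"]])
      }
      cds <- random_cds(len, starts_tab[[nm]], probs,
                        truncated = nm %in% spec$truncated_stops, code)
      gseq[i] <- if (strand == "N") revcomp(cds) else cds
      lens[i] <- len
    } else if (kind == "tRNA") {
      len <- sample(spec$trna_length_range[1L]:spec$trna_length_range[2L], 1L)
      gseq[i] <- random_bases(len, class_probs(spec, "tRNA"))
      lens[i] <- len
    } else if (kind == "rRNA") {
      len <- spec$gene_lengths[[nm]]
      gseq[i] <- random_bases(len, class_probs(spec, "rRNA"))
      lens[i] <- len
    } else {                                   # control region
      len <- spec$cr_length
      gseq[i] <- random_bases(len, class_probs(spec, "CR"))
      lens[i] <- len
    }
  }

  # junction gaps (junction i sits after gene i); the CR-trnI junction
  # (wrap) always abuts
  gaps <- integer(n)
  for (i in seq_len(n - 1L)) {
    key <- paste(tmpl$name[i], tmpl$name[i + 1L], sep = "|")
    gaps[i] <- if (key %in% names(spec$overlaps)) -spec$overlaps[[key]]
               else if (key %in% names(spec$spacers)) spec$spacers[[key]]
               else 0L
  }

  # resolve overlap constraints between protein-coding neighbours
  for (i in which(gaps < 0L)) {
    o <- -gaps[i]
    a <- i; b <- i + 1L
    a_pcg <- tmpl$kind[a] == "PCG"; b_pcg <- tmpl$kind[b] == "PCG"
    if (a_pcg && b_pcg) {
      res <- resolve_pcg_overlap(gseq[a], gseq[b], tmpl$strand[a],
                                 tmpl$strand[b], o,
                                 paste(tmpl$name[a], tmpl$name[b], sep = "-"))
      gseq[a] <- res$a; gseq[b] <- res$b
    } else if (b_pcg && !a_pcg) {
      # downstream gene owns the shared bases; rewrite upstream tail
      la <- nchar(gseq[a])
      gseq[a] <- paste0(substr(gseq[a], 1L, la - o), substr(gseq[b], 1L, o))
    } else {
      # upstream owns (PCG tail is a valid prefix for an unconstrained
      # downstream gene); rewrite downstream head
      la <- nchar(gseq[a])
      gseq[b] <- paste0(substr(gseq[a], la - o + 1L, la),
                        substr(gseq[b], o + 1L, nchar(gseq[b])))
    }
  }

  # assemble the J strand; downstream copy of shared bases is dropped
  genome_seq <- gseq[1L]
  starts <- integer(n); starts[1L] <- 0L
  for (i in 2:n) {
    g <- gaps[i - 1L]
    cur <- nchar(genome_seq)
    if (g >= 0L) {
      spacer <- random_bases(g, class_probs(spec, "spacer"))
      starts[i] <- cur + g
      genome_seq <- paste0(genome_seq, spacer, gseq[i])
    } else {
      o <- -g
      if (substr(genome_seq, cur - o + 1L, cur) !=
          substr(gseq[i], 1L, o)) {
        stop("spec error: unresolved frame conflict at junction ",
             tmpl$name[i - 1L], "-", tmpl$name[i])
      }
      starts[i] <- cur - o
      genome_seq <- paste0(genome_seq, substr(gseq[i], o + 1L, nchar(gseq[i])))
    }
  }

  features <- data.frame(name = tmpl$name, kind = tmpl$kind,
                         start = starts, end = starts + nchar(gseq),
                         strand = tmpl$strand, anticodon = NA_character_,
                         wrap = FALSE, stringsAsFactors = FALSE)
  id <- sprintf("synmt_seed%d", spec$seed)
  genome <- mito_genome(id, genome_seq, features, circular = TRUE)

  # internal consistency: every PCG must translate cleanly
  for (i in which(features$kind == "PCG")) {
    f <- features[i, , drop = FALSE]
    cds <- extract_gene(genome, f)
    translate_cds(cds, code, complete_trailing = TRUE)
  }

  junction_truth <- data.frame(
    gene_a = tmpl$name, gene_b = tmpl$name[c(2:n, 1L)],
    gap = c(gaps[seq_len(n - 1L)], 0L), stringsAsFactors = FALSE)

  list(genome = genome,
       truth = list(features = features, junctions = junction_truth,
                    targets = list(at_richness = spec$at_richness,
                                   at_skew = spec$at_skew,
                                   gc_skew = spec$gc_skew),
                    seed = spec$seed))
}

# joint tail/head construction for overlapping protein-coding genes on
# the same strand; supports the biologically observed 1 bp and 7 bp
# patterns (shared ATGATAA block, or a shared A between a TAA stop and
# an ATN start)
resolve_pcg_overlap <- function(sa, sb, strand_a, strand_b, o, junction) {
  if (strand_a != strand_b) {
    stop("spec error: overlap between opposite-strand coding genes at ",
         junction)
  }
  if (strand_a == "J") {
    if (o == 1L) {
      la <- nchar(sa)
      if (substr(sa, la, la) != "A" || substr(sb, 1L, 1L) != "A") {
        stop("spec error: 1 bp coding overlap needs TAA stop meeting an ",
             "A-initial start codon at ", junction)
      }
      return(list(a = sa, b = sb))
    }
    if (o == 7L) {
      sa <- force_tail_atgataa(sa)
      sb <- paste0("ATGATAA", substr(sb, 8L, nchar(sb)))
      return(list(a = sa, b = sb))
    }
  } else {
    # N strand: work in coding orientation; upstream-in-J gene 'a' has its
    # coding start in the shared block, downstream-in-J gene 'b' its stop
    ca <- revcomp(sa); cb <- revcomp(sb)
    if (o == 7L) {
      cb <- force_tail_atgataa(cb)
      ca <- paste0("ATGATAA", substr(ca, 8L, nchar(ca)))
      return(list(a = revcomp(ca), b = revcomp(cb)))
    }
  }
  stop("spec error: unsupported coding-gene overlap of ", o, " bp at ",
       junction)
}

# rewrite the final 7 coding bases to ATGATAA, keeping the frame stop-free
force_tail_atgataa <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("cannot place 7 bp shared block on a truncated gene")
  head <- substr(cds, 1L, n - 7L)
  # the leading A of the block is the 3rd base of codon (n-8..n-6); avoid
  # creating an internal TAA stop there
  pre <- substr(cds, n - 8L, n - 7L)
  if (pre == "TA") head <- paste0(substr(head, 1L, n - 9L), "CA")
  paste0(head, "ATGATAA")
}
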