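#' Ancestral insect mitochondrial gene order
#'
#' The 37-gene arrangement typified by *Drosophila yakuba*, read along the
#' majority (J) strand starting from trnI, with the control region last.
#' Strand "N" marks minority-strand genes (4 PCGs: nad5, nad4, nad4l,
#' nad1; 8 tRNAs: Q, C, Y, F, H, P, L1, V; both rRNAs).
#'
#' @return Data frame with columns `name`, `kind`, `strand` (38 rows, the
#'   37 genes plus `CR`).
#' @export
ancestral_gene_order <- function() {
  spec <- c(
    "trnI:tRNA:J",  "trnQ:tRNA:N",  "trnM:tRNA:J",  "nad2:PCG:J",
    "trnW:tRNA:J",  "trnC:tRNA:N",  "trnY:tRNA:N",  "cox1:PCG:J",
    "trnL2:tRNA:J", "cox2:PCG:J",   "trnK:tRNA:J",  "trnD:tRNA:J",
    "atp8:PCG:J",   "atp6:PCG:J",   "cox3:PCG:J",   "trnG:tRNA:J",
    "nad3:PCG:J",   "trnA:tRNA:J",  "trnR:tRNA:J",  "trnN:tRNA:J",
    "trnS1:tRNA:J", "trnE:tRNA:J",  "trnF:tRNA:N",  "nad5:PCG:N",
    "trnH:tRNA:N",  "nad4:PCG:N",   "nad4l:PCG:N",  "trnT:tRNA:J",
    "trnP:tRNA:N",  "nad6:PCG:J",   "cob:PCG:J",    "trnS2:tRNA:J",
    "nad1:PCG:N",   "trnL1:tRNA:N", "rrnL:rRNA:N",  "trnV:tRNA:N",
    "rrnS:rRNA:N",  "CR:control_region:J")
  parts <- do.call(rbind, strsplit(spec, ":"))
  data.frame(name = parts[, 1L], kind = parts[, 2L], strand = parts[, 3L],
             stringsAsFactors = FALSE)
}

#' Gene order of an annotated genome
#'
#' Features sorted along the J strand and rotation-normalized to begin at
#' trnI when present (otherwise at the alphabetically first gene), so two
#' rotations of the same circular genome compare equal.
#'
#' @param genome A [mito_genome()].
#' @return Object of class `gene_order`: data frame `name`, `strand`.
#' @export
gene_order <- function(genome) {
  ft <- genome$features[order(genome$features$start), , drop = FALSE]
  ord <- data.frame(name = ft$name, strand = ft$strand, stringsAsFactors = FALSE)
  anchor <- if ("trnI" %in% ord$name) match("trnI", ord$name) else which.min(ord$name)
  if (length(anchor) == 1L && anchor > 1L) {
    idx <- c(anchor:nrow(ord), seq_len(anchor - 1L))
    ord <- ord[idx, , drop = FALSE]
  }
  rownames(ord) <- NULL
  class(ord) <- c("gene_order", class(ord))
  ord
}

#' Compare two gene orders
#'
#' Rotation-normalized, symmetric comparison; reports the differing
#' entries.
#'
#' @param a,b `gene_order` objects (or data frames with `name`, `strand`).
#' @return List with `identical` (logical) and `diff` (data frame of
#'   positions where the two orders disagree).
#' @export
compare_gene_order <- function(a, b) {
  if (nrow(a) != nrow(b)) {
    return(list(identical = FALSE,
                diff = data.frame(position = NA_integer_,
                                  a = paste0(nrow(a), " genes"),
                                  b = paste0(nrow(b), " genes"))))
  }
  ea <- paste(a$name, a$strand)
  eb <- paste(b$name, b$strand)
  mism <- which(ea != eb)
  list(identical = length(mism) == 0L,
       diff = data.frame(position = mism, a = ea[mism], b = eb[mism],
                         stringsAsFactors = FALSE))
}

#' Gene-junction census: overlaps and intergenic spacers
#'
#' Walks consecutive features around the circle (n features give n
#' junctions) and reports the signed gap at each: negative = overlap,
#' positive = intergenic spacer, zero = abutting. Strand is ignored
#' (coordinate arithmetic only), so overlaps spanning opposite strands
#' such as trnW-trnC are counted. Junctions flanking the control region
#' are listed but excluded from the spacer totals, which follow the
#' convention of reporting spacers excluding the control region.
#'
#' @param genome A [mito_genome()].
#' @return Object of class `junction_report`: list with `junctions`
#'   (data frame `gene_a`, `gene_b`, `gap`) and totals `overlap_bp`,
#'   `overlap_junctions`, `spacer_bp`, `spacer_count`.
#' @export
junctions <- function(genome) {
  ft <- genome$features[order(genome$features$start), , drop = FALSE]
  n <- nrow(ft)
  if (n < 2L) stop("need at least two features for a junction census")
  L <- genome_length(genome)
  # containment check (one feature entirely inside another)
  for (i in seq_len(n - 1L)) {
    inside <- ft$start > ft$start[i] & ft$end < ft$end[i]
    if (any(inside)) {
      stop("containment error: feature '", ft$name[which(inside)[1L]],
           "' lies inside '", ft$name[i], "'")
    }
  }
  nxt <- c(2:n, 1L)
  gap <- integer(n)
  for (i in seq_len(n)) {
    j <- nxt[i]
    g <- ft$start[j] - ft$end[i]
    if (i == n) g <- g + L          # wrap across the origin
    gap[i] <- g
  }
  jx <- data.frame(gene_a = ft$name, gene_b = ft$name[nxt], gap = gap,
                   stringsAsFactors = FALSE)
  is_cr_flank <- ft$kind == "control_region" | ft$kind[nxt] == "control_region"
  ov <- jx$gap < 0L
  sp <- jx$gap > 0L & !is_cr_flank
  structure(list(junctions = jx,
                 overlap_bp = -sum(jx$gap[ov]),
                 overlap_junctions = sum(ov),
                 spacer_bp = sum(jx$gap[sp]),
                 spacer_count = sum(sp)),
            class = "junction_report")
}

#' @export
print.junction_report <- function(x, ...) {
  cat("Junction census:", nrow(x$junctions), "junctions\n")
  cat(" overlaps:", x$overlap_bp, "bp over", x$overlap_junctions, "junctions\n")
  cat(" spacers (excl. CR):", x$spacer_bp, "bp over", x$spacer_count, "spacers\n")
  invisible(x)
}

#' Locate the control region
#'
#' Returns the unannotated interval between the end of rrnS and the start
#' of trnI along the J strand, wrapping the origin if needed.
#'
#' @param genome A [mito_genome()].
#' @return List `start`, `end` (0-based half-open, end may exceed genome
#'   length when wrapped), `length`, `wrap`.
#' @export
locate_control_region <- function(genome) {
  ft <- genome$features
  for (anchor in c("rrnS", "trnI")) {
    if (!anchor %in% ft$name) {
      stop("cannot locate control region: missing anchor gene '", anchor, "'")
    }
  }
  L <- genome_length(genome)
  start <- ft$end[ft$name == "rrnS"] %% L
  end <- ft$start[ft$name == "trnI"]
  wrap <- end <= start
  if (wrap) end <- end + L
  len <- end - start
  if (len < 50L) {
    warning("control region interval is only ", len, " bp")
  }
  list(start = start, end = end, length = len, wrap = wrap)
}

#' tRNA base-pair census from a dot-bracket structure
#'
#' Classifies every paired position of a tRNA secondary structure as
#' Watson-Crick (A-U, G-C), G-U wobble, or a mismatch (A-A, U-U, A-G,
#' A-C, other). Helices (stems) are counted by decomposing the pair list
#' into runs of stacked pairs; a canonical cloverleaf has four (acceptor,
#' DHU, anticodon, T-Psi-C), and the DHU-arm flag is false when the
#' structure has fewer than four.
#'
#' @param trna_seq Nucleotide string (DNA or RNA alphabet).
#' @param structure Dot-bracket string of the same length.
#' @return Object of class `trna_census`: list with `pairs` (data frame
#'   `pos5`, `pos3`, `bases`, `class`), counts `wc`, `gu`, `mismatch`
#'   (named vector by type), `n_stems`, `n_hairpins`, and `arms` (logical
#'   flags `acceptor`, `DHU`, `anticodon`, `TPsiC`).
#' @export
trna_pair_census <- function(trna_seq, structure) {
  s <- chartr("Tt", "Uu", toupper(trna_seq))
  if (nchar(s) != nchar(structure)) {
    stop("sequence and structure lengths differ (", nchar(s), " vs ",
         nchar(structure), ")")
  }
  db <- strsplit(structure, "")[[1L]]
  if (!all(db %in% c("(", ")", "."))) stop("structure error: invalid characters")
  stack <- integer(0)
  p5 <- integer(0); p3 <- integer(0)
  for (i in seq_along(db)) {
    if (db[i] == "(") {
      stack <- c(stack, i)
    } else if (db[i] == ")") {
      if (length(stack) == 0L) stop("structure error: unbalanced ')' at ", i)
      p5 <- c(p5, stack[length(stack)])
      p3 <- c(p3, i)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0L) stop("structure error: unmatched '(' at ", stack[1L])
  ord <- order(p5)
  p5 <- p5[ord]; p3 <- p3[ord]
  chars <- strsplit(s, "")[[1L]]
  classify <- function(a, b) {
    pair <- paste0(sort(c(a, b)), collapse = "-")
    if (pair %in% c("A-U", "C-G")) "WC"
    else if (pair == "G-U") "GU"
    else if (pair %in% c("A-A", "U-U", "A-G", "A-C")) pair
    else "other"
  }
  cls <- mapply(classify, chars[p5], chars[p3])
  pairs <- data.frame(pos5 = p5, pos3 = p3,
                      bases = paste0(chars[p5], "-", chars[p3]),
                      class = cls, stringsAsFactors = FALSE)
  # stem decomposition: pair k extends the current stem if it stacks on
  # the previous pair (i+1, j-1)
  n_stems <- 0L
  if (length(p5) > 0L) {
    n_stems <- 1L
    if (length(p5) > 1L) {
      for (k in 2:length(p5)) {
        stacked <- (p5[k] == p5[k - 1L] + 1L) && (p3[k] == p3[k - 1L] - 1L)
        if (!stacked) n_stems <- n_stems + 1L
      }
    }
  }
  # hairpin stems: innermost pairs enclosing no other pair
  n_hairpins <- 0L
  for (k in seq_along(p5)) {
    enclosed <- p5 > p5[k] & p3 < p3[k]
    if (!any(enclosed)) n_hairpins <- n_hairpins + 1L
  }
  mismatch_types <- c("A-A", "U-U", "A-G", "A-C", "other")
  mism <- vapply(mismatch_types, function(t) sum(cls == t), integer(1))
  structure(list(pairs = pairs,
                 wc = sum(cls == "WC"),
                 gu = sum(cls == "GU"),
                 mismatch = mism,
                 n_stems = n_stems,
                 n_hairpins = n_hairpins,
                 arms = c(acceptor = n_stems >= 1L,
                          DHU = n_stems >= 4L,
                          anticodon = n_hairpins >= 2L,
                          TPsiC = n_hairpins >= 2L)),
            class = "trna_census")
}

#' @export
print.trna_census <- function(x, ...) {
  cat("tRNA pairing:", x$wc, "Watson-Crick,", x$gu, "G-U wobble,",
      sum(x$mismatch), "mismatched pairs;", x$n_stems, "stems\n")
  invisible(x)
}
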