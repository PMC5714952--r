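#' Base composition of a nucleotide sequence
#'
#' Exact A/C/G/T counts (N excluded from counts but included in `length`),
#' A+T percentage and AT/GC strand skews. Skews follow the usual
#' definitions AT-skew = (A - T)/(A + T), GC-skew = (G - C)/(G + C); a
#' degenerate denominator yields `NA`.
#'
#' @param seq Nucleotide string.
#' @param region Label for the `region` column of the result.
#' @return One-row data frame of class `composition_summary` with columns
#'   `region`, `length`, `A`, `C`, `G`, `T`, `at_percent`, `at_skew`,
#'   `gc_skew` (full precision; round only when reporting).
#' @export
#' @examples
#' base_composition("AATGC")
base_composition <- function(seq, region = "custom") {
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("empty sequence")
  counts <- base_counts(seq)
  A <- counts[["A"]]; C <- counts[["C"]]; G <- counts[["G"]]; T <- counts[["T"]]
  denom <- A + C + G + T
  out <- data.frame(
    region = region, length = nchar(seq),
    A = A, C = C, G = G, T = T,
    at_percent = if (denom > 0L) 100 * (A + T) / denom else NA_real_,
    at_skew = if (A + T > 0L) (A - T) / (A + T) else NA_real_,
    gc_skew = if (G + C > 0L) (G - C) / (G + C) else NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("composition_summary", class(out))
  out
}

base_counts <- function(seq) {
  chars <- strsplit(seq, "")[[1L]]
  vapply(c("A", "C", "G", "T"), function(b) sum(chars == b), integer(1))
}

#' AT and GC skew of a sequence
#'
#' @param seq Nucleotide string.
#' @return Named numeric vector `c(at_skew, gc_skew)`; `NA` components for
#'   degenerate denominators (e.g. a sequence with no G or C).
#' @export
#' @examples
#' skew("AATGC")   # (2-1)/3 = 0.333..., (1-1)/2 = 0
skew <- function(seq) {
  s <- base_composition(seq)
  c(at_skew = s$at_skew, gc_skew = s$gc_skew)
}

region_classes <- c("whole", "PCGs", "rrnL", "rrnS", "tRNAs", "CR")

#' Per-region composition summary of an annotated mitogenome
#'
#' Computes a composition row for the whole molecule, the concatenated
#' protein-coding genes, each rRNA, the concatenated tRNAs and the control
#' region. By default member sequences are taken in deposited-strand (J)
#' orientation in genome order, so the strand-asymmetry of the molecule is
#' preserved in the concatenations; set `coding_orientation = TRUE` to use
#' each gene's coding strand instead.
#'
#' @param genome A [mito_genome()].
#' @param coding_orientation Concatenate genes on their coding strand.
#' @return Data frame with one row per available region class; region
#'   classes with no annotated members are omitted with a warning.
#' @export
region_composition <- function(genome, coding_orientation = FALSE) {
  ft <- genome$features
  grab <- function(rows) {
    paste(vapply(rows, function(i) {
      f <- ft[i, , drop = FALSE]
      if (coding_orientation) extract_gene(genome, f)
      else seq_slice(genome$sequence, f$start, f$end, wrap = isTRUE(f$wrap))
    }, character(1)), collapse = "")
  }
  members <- list(
    whole = NULL,
    PCGs  = which(ft$kind == "PCG"),
    rrnL  = which(ft$name == "rrnL"),
    rrnS  = which(ft$name == "rrnS"),
    tRNAs = which(ft$kind == "tRNA"),
    CR    = which(ft$kind == "control_region"))
  out <- list()
  for (rg in names(members)) {
    if (rg == "whole") {
      out[[rg]] <- base_composition(genome$sequence, region = "whole")
    } else if (length(members[[rg]]) == 0L) {
      warning("no annotated members for region class '", rg,
              "' in genome ", genome$id, "; summary omitted")
    } else {
      out[[rg]] <- base_composition(grab(members[[rg]]), region = rg)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pooled A+T content by codon position
#'
#' Pools all first, second and third codon positions across a set of
#' protein-coding sequences (coding orientation, stop codons already
#' excluded) and returns the A+T percentage at each position.
#'
#' @param pcgs List (or character vector) of coding sequences, each of
#'   length divisible by 3.
#' @return Numeric vector `c(pos1, pos2, pos3)` of A+T percentages.
#' @export
codon_position_at <- function(pcgs) {
  pcgs <- toupper(unlist(pcgs, use.names = FALSE))
  bad <- which(nchar(pcgs) %% 3L != 0L)
  if (length(bad) > 0L) {
    stop("frame error: sequence ", bad[1L], " has length ",
         nchar(pcgs[bad[1L]]), ", not divisible by 3")
  }
  pos_at <- function(offset) {
    chars <- unlist(lapply(pcgs, function(s) {
      idx <- seq(offset, nchar(s), by = 3L)
      strsplit(s, "")[[1L]][idx]
    }))
    chars <- chars[chars %in% c("A", "C", "G", "T")]
    100 * mean(chars %in% c("A", "T"))
  }
  c(pos1 = pos_at(1L), pos2 = pos_at(2L), pos3 = pos_at(3L))
}
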