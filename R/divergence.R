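#' Construct a multiple alignment object
#'
#' @param ids Sequence identifiers.
#' @param rows Equal-length strings over A, C, G, T, N, `-`.
#' @param coding Is this an in-frame protein-coding alignment?
#' @param frame_offset 0-2; column at which codon position 1 starts
#'   (coding alignments only).
#' @return Object of class `mito_alignment`.
#' @export
mito_alignment <- function(ids, rows, coding = FALSE, frame_offset = 0L) {
  rows <- toupper(rows)
  if (length(ids) != length(rows)) stop("ids and rows differ in length")
  if (length(unique(nchar(rows))) != 1L) stop("alignment rows differ in length")
  if (any(grepl("[^ACGTN-]", rows))) {
    stop("alignment contains characters outside {A,C,G,T,N,-}")
  }
  if (anyDuplicated(ids)) stop("duplicate sequence ids in alignment")
  structure(list(ids = as.character(ids),
                 rows = stats::setNames(rows, ids),
                 coding = isTRUE(coding),
                 frame_offset = as.integer(frame_offset)),
            class = "mito_alignment")
}

#' Read a FASTA alignment
#'
#' @param path FASTA file of equal-length (aligned) sequences.
#' @param coding Mark the alignment as protein-coding.
#' @return A [mito_alignment()].
#' @export
read_alignment <- function(path, coding = FALSE) {
  x <- Biostrings::readDNAStringSet(path)
  mito_alignment(names(x), as.character(x), coding = coding)
}

alignment_length <- function(aln) nchar(aln$rows[[1L]])

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln$rows), ""))
}

#' @export
print.mito_alignment <- function(x, ...) {
  cat("Alignment:", length(x$ids), "sequences x", alignment_length(x),
      "columns", if (x$coding) "(coding)" else "", "\n")
  invisible(x)
}

#' Pairwise divergence with synonymous/replacement classification
#'
#' Counts variable sites between two alignment rows over the mutually
#' resolved columns (both bases in A/C/G/T). For coding alignments each
#' differing site is classified: substituting the second row's base into
#' the first row's codon (other positions held fixed) either preserves
#' the encoded amino acid (synonymous) or changes it (replacement), so
#' synonymous + replacement = variable sites. The alternative
#' `method = "pathway"` averages synonymous/replacement step counts over
#' all orderings of the within-codon differences (minimal mutational
#' pathways), giving possibly fractional counts.
#'
#' @param aln A coding [mito_alignment()] with stops stripped, or any
#'   alignment with `coding = FALSE` (no classification).
#' @param i,j Row indices or ids.
#' @param code A [mito_code()].
#' @param method `"site"` (default) or `"pathway"`.
#' @return One-row data frame of class `divergence_pair`: `variable_sites`,
#'   `synonymous`, `replacement`, `compared_sites`.
#' @export
pairwise_stats <- function(aln, i, j, code = mito_code(),
                           method = c("site", "pathway")) {
  method <- match.arg(method)
  ri <- strsplit(get_row(aln, i), "")[[1L]]
  rj <- strsplit(get_row(aln, j), "")[[1L]]
  L <- length(ri)
  acgt <- c("A", "C", "G", "T")
  if (!aln$coding) {
    ok <- ri %in% acgt & rj %in% acgt
    vs <- sum(ok & ri != rj)
    return(div_pair(vs, NA_real_, NA_real_, sum(ok)))
  }
  off <- aln$frame_offset
  usable <- L - off
  ncod <- usable %/% 3L
  if (ncod == 0L) stop("frame error: no complete codons in alignment")
  syn <- 0; rep_ <- 0; vs <- 0L; compared <- 0L
  for (k in seq_len(ncod)) {
    idx <- off + (k - 1L) * 3L + 1:3
    ci <- ri[idx]; cj <- rj[idx]
    if (!all(ci %in% acgt) || !all(cj %in% acgt)) next   # codon-wise deletion
    compared <- compared + 3L
    d <- which(ci != cj)
    if (length(d) == 0L) next
    vs <- vs + length(d)
    if (method == "site") {
      for (p in d) {
        mut <- ci; mut[p] <- cj[p]
        same <- code$table[paste(ci, collapse = "")] ==
                code$table[paste(mut, collapse = "")]
        if (same) syn <- syn + 1 else rep_ <- rep_ + 1
      }
    } else {
      sr <- pathway_counts(ci, cj, code)
      syn <- syn + sr[1L]; rep_ <- rep_ + sr[2L]
    }
  }
  div_pair(vs, syn, rep_, compared)
}

div_pair <- function(vs, syn, rep_, compared) {
  out <- data.frame(variable_sites = vs, synonymous = syn,
                    replacement = rep_, compared_sites = compared)
  class(out) <- c("divergence_pair", class(out))
  out
}

get_row <- function(aln, i) {
  if (is.character(i)) {
    if (!i %in% aln$ids) stop("no row '", i, "' in alignment")
    aln$rows[[i]]
  } else {
    aln$rows[[as.integer(i)]]
  }
}

# average syn/rep step counts over all orderings of the differing
# positions; pathways passing through a stop codon are discarded
pathway_counts <- function(ci, cj, code) {
  d <- which(ci != cj)
  perms <- permutations(d)
  tot_syn <- 0; tot_rep <- 0; n_valid <- 0L
  for (ord in perms) {
    cur <- ci
    syn <- 0L; rep_ <- 0L; valid <- TRUE
    for (p in ord) {
      aa_from <- code$table[paste(cur, collapse = "")]
      cur[p] <- cj[p]
      aa_to <- code$table[paste(cur, collapse = "")]
      if (aa_to == "*" || aa_from == "*") { valid <- FALSE; break }
      if (aa_from == aa_to) syn <- syn + 1L else rep_ <- rep_ + 1L
    }
    if (valid) {
      tot_syn <- tot_syn + syn; tot_rep <- tot_rep + rep_
      n_valid <- n_valid + 1L
    }
  }
  if (n_valid == 0L) return(c(0, length(d)))   # all paths blocked: call all replacement
  c(tot_syn / n_valid, tot_rep / n_valid)
}

permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (k in seq_along(v)) {
    for (rest in permutations(v[-k])) out[[length(out) + 1L]] <- c(v[k], rest)
  }
  out
}

#' Nucleotide diversity (Pi)
#'
#' Average pairwise per-site p-distance over all unordered row pairs,
#' each pair computed on its mutually resolved columns (pairwise
#' deletion; `deletion = "complete"` drops any column with a gap or
#' ambiguity in any row first).
#'
#' @param aln A [mito_alignment()] with at least two rows.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return Pi in [0, 1] (`NaN` if no pair has resolved columns).
#' @export
nucleotide_diversity <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  n <- length(aln$ids)
  if (n < 2L) stop("nucleotide diversity needs at least 2 sequences")
  m <- aln_matrix(aln)
  acgt <- c("A", "C", "G", "T")
  if (deletion == "complete") {
    keep <- apply(matrix(m %in% acgt, nrow = nrow(m)), 2L, all)
    m <- m[, keep, drop = FALSE]
  }
  dists <- c()
  for (a in 1:(n - 1L)) for (b in (a + 1L):n) {
    ok <- m[a, ] %in% acgt & m[b, ] %in% acgt
    nv <- sum(ok)
    dists <- c(dists, if (nv == 0L) NA_real_ else sum(m[a, ok] != m[b, ok]) / nv)
  }
  mean(dists, na.rm = TRUE)
}

#' Sliding-window nucleotide diversity
#'
#' Computes Pi in windows of `window` alignment columns advanced by
#' `step`, the convention of sliding-window diversity scans (defaults
#' 250 bp / 25 bp). Window positions are alignment coordinates (gaps
#' occupy columns but are excluded from each window's Pi).
#'
#' @param aln A [mito_alignment()].
#' @param window Window width in columns (default 250).
#' @param step Step size in columns (default 25).
#' @return Object of class `diversity_track`: data frame `start`, `end`
#'   (1-based inclusive columns), `midpoint`, `pi`; the number of rows is
#'   `floor((L - window)/step) + 1`.
#' @export
sliding_window <- function(aln, window = 250L, step = 25L) {
  L <- alignment_length(aln)
  if (window > L) stop("window (", window, ") exceeds alignment length (", L, ")")
  if (step <= 0L || window <= 0L) stop("window and step must be positive")
  starts <- seq(1L, L - window + 1L, by = step)
  m <- aln_matrix(aln)
  acgt <- c("A", "C", "G", "T")
  n <- nrow(m)
  pis <- vapply(starts, function(s) {
    cols <- s:(s + window - 1L)
    sub <- m[, cols, drop = FALSE]
    dists <- c()
    for (a in 1:(n - 1L)) for (b in (a + 1L):n) {
      ok <- sub[a, ] %in% acgt & sub[b, ] %in% acgt
      nv <- sum(ok)
      dists <- c(dists, if (nv == 0L) NA_real_ else sum(sub[a, ok] != sub[b, ok]) / nv)
    }
    mean(dists, na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(start = starts, end = starts + window - 1L,
                    midpoint = starts - 1L + window / 2,
                    pi = pis)
  class(out) <- c("diversity_track", class(out))
  out
}

#' Per-gene nucleotide diversity
#'
#' @param alignments Named list of [mito_alignment()] objects.
#' @return Named numeric vector of Pi values.
#' @export
per_gene_pi <- function(alignments) {
  vapply(alignments, nucleotide_diversity, numeric(1))
}

#' Pairwise identity of an alignment
#'
#' Percentage of columns at which all rows are identical; gaps count as
#' characters.
#'
#' @param aln A [mito_alignment()] with at least two rows.
#' @return Identity percentage in [0, 100].
#' @export
pairwise_identity <- function(aln) {
  if (length(aln$ids) < 2L) stop("pairwise identity needs at least 2 sequences")
  m <- aln_matrix(aln)
  ident <- vapply(seq_len(ncol(m)), function(c) length(unique(m[, c])) == 1L,
                  logical(1))
  100 * mean(ident)
}
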