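#' Classify a gene's start and stop codons
#'
#' The start codon is read verbatim from the first three bases. The stop
#' is classified from the length mod 3 and the terminal bases: complete
#' TAA/TAG stops for in-frame genes, truncated `"T-"` (length = 1 mod 3,
#' final base T) or `"TA-"` (length = 2 mod 3, final bases TA) stops
#' completed by polyadenylation.
#'
#' @param gene Gene name for the report.
#' @param cds Nucleotide string in coding orientation.
#' @param code A [mito_code()].
#' @return One-row data frame: `gene`, `start_codon`, `stop_codon`,
#'   `length`.
#' @export
#' @examples
#' detect_start_stop("toy", "ATGAAAT")   # truncated stop "T-"
detect_start_stop <- function(gene, cds, code = mito_code()) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 4L) stop("coding sequence of '", gene, "' too short (", n, " nt)")
  start <- substr(cds, 1L, 3L)
  rem <- n %% 3L
  stop_cod <- if (rem == 0L) {
    last <- substr(cds, n - 2L, n)
    if (!last %in% stop_codons(code)) {
      stop("annotation inconsistency in '", gene, "': in-frame length but ",
           "final codon ", last, " is not a stop")
    }
    last
  } else if (rem == 1L) {
    if (substr(cds, n, n) != "T") {
      stop("annotation inconsistency in '", gene, "': length = 1 mod 3 but ",
           "final base is not T")
    }
    "T-"
  } else {
    if (substr(cds, n - 1L, n) != "TA") {
      stop("annotation inconsistency in '", gene, "': length = 2 mod 3 but ",
           "final bases are not TA")
    }
    "TA-"
  }
  data.frame(gene = gene, start_codon = start, stop_codon = stop_cod,
             length = n, stringsAsFactors = FALSE)
}

#' Count non-stop codons across protein-coding genes
#'
#' Counts every codon of every gene excluding the (possibly truncated)
#' terminal stop; start codons are included (a flag excludes them). Codons
#' containing an ambiguous base are skipped and tallied.
#'
#' @param pcgs Named list of coding sequences (coding orientation).
#' @param code A [mito_code()].
#' @param include_start Count the initiation codon (default `TRUE`).
#' @return Object of class `codon_usage`: list with `counts` (named
#'   integer vector over the 62 sense codons), `total_nonstop`,
#'   `skipped_ambiguous`, `missing` (sense codons with zero count),
#'   `start_stop` (per-gene report) and `rscu` (`NULL` until [rscu()]).
#' @export
count_codons <- function(pcgs, code = mito_code(), include_start = TRUE) {
  if (is.null(names(pcgs))) names(pcgs) <- paste0("gene", seq_along(pcgs))
  sense <- sense_codons(code)
  counts <- stats::setNames(integer(length(sense)), sense)
  skipped <- 0L
  reports <- list()
  for (g in names(pcgs)) {
    cds <- toupper(pcgs[[g]])
    reports[[g]] <- detect_start_stop(g, cds, code)
    n <- nchar(cds)
    rem <- n %% 3L
    # drop the stop: 3 bases when complete, 1-2 trailing bases when truncated
    keep <- if (rem == 0L) n - 3L else n - rem
    if (keep < 3L) next
    codons <- substring(cds, seq(1L, keep - 2L, by = 3L), seq(3L, keep, by = 3L))
    if (!include_start) codons <- codons[-1L]
    ok <- codons %in% names(code$table)
    skipped <- skipped + sum(!ok)
    codons <- codons[ok]
    internal_stop <- codons %in% stop_codons(code)
    if (any(internal_stop)) {
      stop("premature stop codon inside '", g, "' at codon index ",
           which(internal_stop)[1L])
    }
    tab <- table(codons)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  # skipped ambiguous codons still occupy codon slots, so the total keeps
  # the length bookkeeping sum(floor(len/3) - [stop complete])
  structure(list(counts = counts,
                 total_nonstop = sum(counts) + skipped,
                 skipped_ambiguous = skipped,
                 missing = names(counts)[counts == 0L],
                 start_stop = do.call(rbind, reports),
                 rscu = NULL,
                 code_id = code$id),
            class = "codon_usage")
}

#' Non-stop codon total from printed gene lengths and stop annotations
#'
#' The bookkeeping identity used for published per-gene tables: each gene
#' contributes `floor(length/3)` codons, minus one when its stop codon is
#' complete (TAA/TAG); genes with truncated stops (`"T-"`, `"TA-"`)
#' contribute all their full codons.
#'
#' @param lengths Integer vector of gene lengths in bp.
#' @param stops Character vector of stop annotations (`"TAA"`, `"TAG"`,
#'   `"T-"`, `"TA-"`), same length as `lengths`.
#' @return Total number of non-stop codons.
#' @export
nonstop_codon_total <- function(lengths, stops) {
  if (length(lengths) != length(stops)) stop("lengths and stops differ in length")
  complete <- stops %in% c("TAA", "TAG")
  truncated <- stops %in% c("T-", "TA-")
  if (!all(complete | truncated)) {
    stop("unknown stop annotation: ", stops[!(complete | truncated)][1L])
  }
  mod <- lengths %% 3L
  if (any(complete & mod != 0L)) stop("complete stop on a gene length not divisible by 3")
  if (any(stops == "T-" & mod != 1L) || any(stops == "TA-" & mod != 2L)) {
    stop("truncated stop inconsistent with gene length mod 3")
  }
  sum(lengths %/% 3L - as.integer(complete))
}

#' Relative synonymous codon usage
#'
#' For amino acid a with synonymous family F (stop codons excluded; under
#' the invertebrate mitochondrial code Met = {ATA, ATG} and
#' Trp = {TGA, TGG} are two-codon families),
#' RSCU(c) = count(c) * |F| / sum of counts over F. Members of a family
#' with zero total get `NA`.
#'
#' @param usage A `codon_usage` object from [count_codons()].
#' @param code A [mito_code()].
#' @return The `codon_usage` object with its `rscu` slot filled.
#' @export
#' @examples
#' cu <- count_codons(list(g = "ATGTTTTTTTTCTAA"))
#' rscu(cu)$rscu[c("TTT", "TTC")]   # Phe family: 1.5, 0.5
rscu <- function(usage, code = mito_code()) {
  counts <- usage$counts
  fam <- split(names(counts), code$table[names(counts)])
  vals <- stats::setNames(rep(NA_real_, length(counts)), names(counts))
  for (f in fam) {
    tot <- sum(counts[f])
    if (tot > 0L) vals[f] <- counts[f] * length(f) / tot
  }
  usage$rscu <- vals
  usage
}

#' @export
print.codon_usage <- function(x, ...) {
  cat("Codon usage over", length(x$counts), "sense codons;",
      x$total_nonstop, "non-stop codons counted\n")
  if (length(x$missing) > 0L) {
    cat("Missing codons:", paste(x$missing, collapse = ", "), "\n")
  }
  if (x$skipped_ambiguous > 0L) {
    cat(x$skipped_ambiguous, "codons skipped (ambiguous bases)\n")
  }
  invisible(x)
}

#' Codon usage as a tidy table
#'
#' @param usage A `codon_usage` object (after [rscu()] for RSCU values).
#' @param code A [mito_code()].
#' @return Data frame: `codon`, `aa`, `family_size`, `count`, `rscu`.
#' @export
codon_usage_table <- function(usage, code = mito_code()) {
  codons <- names(usage$counts)
  aa <- unname(code$table[codons])
  fam_size <- as.integer(table(aa)[aa])
  data.frame(codon = codons, aa = aa, family_size = fam_size,
             count = unname(usage$counts),
             rscu = if (is.null(usage$rscu)) NA_real_ else unname(usage$rscu),
             stringsAsFactors = FALSE)
}
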