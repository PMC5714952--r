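#' Invertebrate mitochondrial genetic code
#'
#' Returns the genetic code used throughout the package: NCBI translation
#' table 5 (invertebrate mitochondrial), under which ATA encodes Met,
#' AGA/AGG encode Ser, TGA encodes Trp, and the only stop codons are TAA
#' and TAG.
#'
#' @param id Biostrings genetic-code identifier. Defaults to `"SGC4"`,
#'   the invertebrate mitochondrial table.
#' @return An object of class `mito_code`: a list with `id`, `table`
#'   (named character vector of 64 codon -> one-letter amino acid, `*` for
#'   stop) and `starts` (recognised initiation codons).
#' @export
#' @examples
#' code <- mito_code()
#' code$table[c("ATA", "TGA", "AGA")]
mito_code <- function(id = "SGC4") {
  tab <- Biostrings::getGeneticCode(id)
  structure(
    list(
      id = id,
      table = stats::setNames(as.character(tab), names(tab)),
      starts = c("ATG", "ATA", "ATT", "ATC", "TTG", "GTG")
    ),
    class = "mito_code"
  )
}

#' @export
print.mito_code <- function(x, ...) {
  cat("Genetic code:", x$id, "\n")
  cat("Stop codons:", paste(names(x$table)[x$table == "*"], collapse = ", "), "\n")
  cat("Start codons:", paste(x$starts, collapse = ", "), "\n")
  invisible(x)
}

stop_codons <- function(code) names(code$table)[code$table == "*"]

sense_codons <- function(code) names(code$table)[code$table != "*"]

#' Translate a mitochondrial coding sequence
#'
#' Codon-by-codon translation under a mitochondrial genetic code, with
#' support for the truncated stop codons (T or TA) common at insect
#' mitochondrial gene ends, which are completed to TAA by
#' post-transcriptional polyadenylation.
#'
#' @param cds Nucleotide string in coding orientation (length >= 3).
#' @param code A [mito_code()] object.
#' @param complete_trailing If `TRUE` and the length mod 3 is 1 or 2, a
#'   trailing `T` or `TA` is completed to a TAA stop before translation and
#'   reported via the `truncated_stop` attribute (`"T-"` or `"TA-"`).
#' @return Amino-acid string (terminal stop, if any, is not included).
#'   Attributes: `stop_codon` (the stop as written in the DNA, `"T-"`/
#'   `"TA-"` when truncated, `NA` when the final codon is not a stop) and
#'   `truncated_stop` (logical).
#' @export
#' @examples
#' translate_cds("ATATGA")                     # "MW": ATA = Met, TGA = Trp
#' translate_cds("ATGT", complete_trailing = TRUE)
translate_cds <- function(cds, code = mito_code(), complete_trailing = FALSE) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 3L) stop("coding sequence shorter than one codon (", n, " nt)")
  rem <- n %% 3L
  truncated <- NA_character_
  if (rem != 0L) {
    if (!complete_trailing) {
      stop("sequence length ", n, " is not a multiple of 3; ",
           "set complete_trailing = TRUE for truncated stop codons")
    }
    tail_nt <- substr(cds, n - rem + 1L, n)
    if (rem == 1L && tail_nt == "T") {
      truncated <- "T-"
    } else if (rem == 2L && tail_nt == "TA") {
      truncated <- "TA-"
    } else {
      stop("trailing bases '", tail_nt, "' are inconsistent with a ",
           "truncated TAA stop codon")
    }
    cds <- paste0(substr(cds, 1L, n - rem), "TAA")
    n <- nchar(cds)
  }
  codons <- substring(cds, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  aa <- unname(code$table[codons])
  aa[is.na(aa)] <- "X"   # codons containing N or other ambiguity
  ncod <- length(aa)
  internal_stop <- which(aa[-ncod] == "*")
  if (length(internal_stop) > 0L) {
    stop("premature stop codon at codon index ", internal_stop[1L],
         " (", codons[internal_stop[1L]], ")")
  }
  stop_cod <- NA_character_
  if (aa[ncod] == "*") {
    stop_cod <- if (!is.na(truncated)) truncated else codons[ncod]
    aa <- aa[-ncod]
  } else if (!is.na(truncated)) {
    stop("internal error: completed codon did not translate to stop")
  }
  structure(paste(aa, collapse = ""),
            stop_codon = stop_cod,
            truncated_stop = !is.na(truncated))
}
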