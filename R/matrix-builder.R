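#' Concatenate per-gene alignments into a supermatrix
#'
#' Rows are assembled gene by gene in the given order; taxa absent from a
#' gene are filled with `-` across that gene's span. The partition map
#' records each gene span (1-based inclusive matrix coordinates) and
#' whether it is protein-coding (codon-position subpartitions are derived
#' on demand, e.g. for exports).
#'
#' @param gene_alignments Named, ordered list of [mito_alignment()]s.
#' @param taxa Optional character vector fixing taxon order; defaults to
#'   order of first appearance across genes.
#' @return Object of class `super_matrix`: list with `taxa`, `rows`
#'   (named character vector), `partitions` (data frame `name`, `start`,
#'   `end`, `coding`), `recoding` (`"none"` or `"degen"`).
#' @export
concatenate_alignments <- function(gene_alignments, taxa = NULL) {
  if (length(gene_alignments) == 0L) stop("no alignments to concatenate")
  if (is.null(names(gene_alignments))) {
    names(gene_alignments) <- paste0("gene", seq_along(gene_alignments))
  }
  for (g in names(gene_alignments)) {
    if (anyDuplicated(gene_alignments[[g]]$ids)) {
      stop("duplicate taxon in alignment '", g, "'")
    }
  }
  if (is.null(taxa)) {
    taxa <- unique(unlist(lapply(gene_alignments, function(a) a$ids)))
  }
  rows <- stats::setNames(rep("", length(taxa)), taxa)
  parts <- list()
  pos <- 0L
  for (g in names(gene_alignments)) {
    a <- gene_alignments[[g]]
    len <- alignment_length(a)
    fill <- strrep("-", len)
    piece <- stats::setNames(rep(fill, length(taxa)), taxa)
    hit <- intersect(taxa, a$ids)
    piece[hit] <- unname(a$rows[hit])
    rows <- paste0(rows, piece)
    names(rows) <- taxa
    parts[[g]] <- data.frame(name = g, start = pos + 1L, end = pos + len,
                             coding = a$coding, stringsAsFactors = FALSE)
    pos <- pos + len
  }
  structure(list(taxa = taxa, rows = rows,
                 partitions = do.call(rbind, parts), recoding = "none"),
            class = "super_matrix")
}

#' @export
print.super_matrix <- function(x, ...) {
  cat("Supermatrix:", length(x$taxa), "taxa x", nchar(x$rows[[1L]]),
      "sites;", nrow(x$partitions), "gene partitions; recoding:",
      x$recoding, "\n")
  invisible(x)
}

#' Codon-position partition table
#'
#' Expands the gene-level partition map: each coding gene yields three
#' codon-position subpartitions; non-coding genes stay whole.
#'
#' @param sm A `super_matrix`.
#' @return Data frame `name`, `start`, `end`, `stride` (3 for codon
#'   subpartitions, 1 otherwise), `codon_position` (1-3 or `NA`).
#' @export
codon_partitions <- function(sm) {
  out <- list()
  for (i in seq_len(nrow(sm$partitions))) {
    p <- sm$partitions[i, ]
    if (p$coding) {
      for (cp in 1:3) {
        out[[length(out) + 1L]] <- data.frame(
          name = sprintf("%s_pos%d", p$name, cp),
          start = p$start + cp - 1L, end = p$end, stride = 3L,
          codon_position = cp, stringsAsFactors = FALSE)
      }
    } else {
      out[[length(out) + 1L]] <- data.frame(
        name = p$name, start = p$start, end = p$end, stride = 1L,
        codon_position = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

## ---- Degen recoding --------------------------------------------------------

iupac_symbol <- local({
  map <- NULL
  function(bases) {
    if (is.null(map)) {
      cm <- Biostrings::IUPAC_CODE_MAP
      map <<- stats::setNames(names(cm), vapply(strsplit(cm, ""), function(s)
        paste(sort(s), collapse = ""), character(1)))
    }
    key <- paste(sort(unique(bases)), collapse = "")
    sym <- unname(map[key])
    if (is.na(sym)) stop("no IUPAC symbol for base set {", key, "}")
    sym
  }
})

iupac_expand <- function(sym) {
  if (sym %in% c("-", "?")) return(c("A", "C", "G", "T"))
  set <- Biostrings::IUPAC_CODE_MAP[[sym]]
  if (is.null(set)) stop("unknown IUPAC symbol '", sym, "'")
  strsplit(set, "")[[1L]]
}

# Degen recoding of one codon (possibly containing IUPAC symbols or
# gaps). One sweep expands the codon over all resolutions; position p of
# the result is the IUPAC symbol covering, across resolutions, every
# base that preserves that resolution's amino acid when substituted at
# p. Sweeps repeat until a fixed point: this closes chains of
# single-step synonymous changes, so e.g. TTA (Leu) -> YTR -> YTN, the
# recoding shared by the whole leucine family (a pos-1 C/T exchange
# between TTA and CTA is synonymous, which merges the TTR and CTN
# families exactly as the classic Degen recoding does). Codons
# containing a gap become NNN.
degen_codon <- function(codon, code, cache = NULL) {
  if (!is.null(cache) && !is.null(cache[[codon]])) return(cache[[codon]])
  cur <- codon
  repeat {
    nxt <- degen_sweep(cur, code)
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  assign_cache(cache, codon, cur)
}

degen_sweep <- function(codon, code) {
  chars <- strsplit(codon, "")[[1L]]
  if (any(chars == "-")) return("NNN")
  sets <- lapply(chars, iupac_expand)
  expansions <- expand.grid(sets, stringsAsFactors = FALSE)
  acgt <- c("A", "C", "G", "T")
  out_sets <- list(character(0), character(0), character(0))
  for (r in seq_len(nrow(expansions))) {
    cod <- unlist(expansions[r, ], use.names = FALSE)
    aa <- code$table[paste(cod, collapse = "")]
    for (p in 1:3) {
      keep <- vapply(acgt, function(b) {
        mut <- cod; mut[p] <- b
        identical(unname(code$table[paste(mut, collapse = "")]), unname(aa))
      }, logical(1))
      out_sets[[p]] <- union(out_sets[[p]], acgt[keep])
    }
  }
  paste(vapply(out_sets, iupac_symbol, character(1)), collapse = "")
}

assign_cache <- function(cache, key, value) {
  if (!is.null(cache)) cache[[key]] <- value
  value
}

#' Degen-recode the coding partitions of a supermatrix
#'
#' Replaces each codon position with the IUPAC degenerate symbol covering
#' exactly the bases that encode the same amino acid (the other two
#' positions held at their observed states), so synonymous differences
#' become invisible while non-synonymous signal is retained. The recoding
#' is derived algorithmically from the genetic-code table, treats the
#' AGN- and TCN-serine families separately, propagates gaps/ambiguities
#' as N, leaves non-coding partitions untouched, and is idempotent.
#'
#' @param sm A `super_matrix` with `recoding = "none"`.
#' @param code A [mito_code()].
#' @return The recoded `super_matrix` (`recoding = "degen"`).
#' @export
degen_recode <- function(sm, code = mito_code()) {
  if (!identical(sm$recoding, "none")) stop("matrix is already recoded")
  cache <- new.env(parent = emptyenv())
  rows <- sm$rows
  for (i in seq_len(nrow(sm$partitions))) {
    p <- sm$partitions[i, ]
    if (!p$coding) next
    len <- p$end - p$start + 1L
    if (len %% 3L != 0L) {
      stop("frame error: coding partition '", p$name,
           "' has length ", len, ", not divisible by 3")
    }
    for (t in seq_along(rows)) {
      seg <- substr(rows[[t]], p$start, p$end)
      codons <- substring(seg, seq(1L, len - 2L, 3L), seq(3L, len, 3L))
      rec <- vapply(codons, degen_codon, character(1), code = code,
                    cache = cache, USE.NAMES = FALSE)
      substr(rows[[t]], p$start, p$end) <- paste(rec, collapse = "")
    }
  }
  sm$rows <- rows
  sm$recoding <- "degen"
  sm
}

#' Degen lookup table for fully resolved codons
#'
#' @param code A [mito_code()].
#' @return Named character vector: codon -> degenerate recoding.
#' @export
degen_table <- function(code = mito_code()) {
  codons <- names(code$table)
  stats::setNames(vapply(codons, degen_codon, character(1), code = code),
                  codons)
}

## ---- substitution saturation ----------------------------------------------

#' Entropy-based substitution-saturation index
#'
#' The observed saturation index: the mean per-site Shannon entropy of
#' base frequencies (non-gap states at the site) divided by the entropy
#' expected at full substitution saturation. Because each site carries
#' only as many states as there are sequences, the plug-in site entropy
#' is downward-biased in finite samples, so the full-saturation
#' reference is the exact expectation of the plug-in entropy when the
#' site's bases are drawn i.i.d. from the matrix-wide base frequencies
#' (computed from the binomial marginals at each site's non-gap depth).
#' Values near 0 indicate an invariant alignment; values near 1 indicate
#' site compositions indistinguishable from random draws from the pooled
#' composition. Critical values for hypothesis tests require tree-shape
#' simulations and are not computed here.
#'
#' @param x A `super_matrix` or [mito_alignment()].
#' @return Object of class `saturation_result`: `iss_observed`,
#'   `mean_site_entropy` and `full_saturation_entropy` (bits), `n_taxa`,
#'   `n_sites`, `skipped_columns`.
#' @export
saturation_index <- function(x) {
  rows <- x$rows
  m <- do.call(rbind, strsplit(unname(rows), ""))
  if (nrow(m) < 4L) warning("fewer than 4 taxa; saturation index is unstable")
  acgt <- c("A", "C", "G", "T")
  entropy <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  stats_by_site <- vapply(seq_len(ncol(m)), function(cix) {
    col <- m[, cix]
    col <- col[col %in% acgt]
    if (length(col) == 0L) return(c(NA_real_, 0))
    c(entropy(table(col) / length(col)), length(col))
  }, numeric(2))
  keep <- !is.na(stats_by_site[1L, ])
  skipped <- sum(!keep)
  site_H <- stats_by_site[1L, keep]
  depth <- stats_by_site[2L, keep]
  pooled <- m[m %in% acgt]
  q <- as.numeric(table(factor(pooled, levels = acgt))) / length(pooled)
  # E[plug-in entropy] of an i.i.d. multinomial(n, q) sample, exact via
  # binomial marginals (entropy is additive over base categories)
  expected_H <- function(n) {
    k <- 1:n
    sum(vapply(q, function(qb) {
      if (qb == 0) return(0)
      -sum(stats::dbinom(k, n, qb) * (k / n) * log2(k / n))
    }, numeric(1)))
  }
  depths <- sort(unique(depth))
  eH <- stats::setNames(vapply(depths, expected_H, numeric(1)),
                        as.character(depths))
  full_H <- mean(eH[as.character(depth)])
  structure(list(iss_observed = mean(site_H) / full_H,
                 mean_site_entropy = mean(site_H),
                 full_saturation_entropy = full_H,
                 n_taxa = nrow(m), n_sites = ncol(m),
                 skipped_columns = skipped),
            class = "saturation_result")
}

#' @export
print.saturation_result <- function(x, ...) {
  cat(sprintf("Observed Iss = %.4f (mean site entropy %.4f / full-saturation entropy %.4f bits; %d taxa, %d sites)\n",
              x$iss_observed, x$mean_site_entropy, x$full_saturation_entropy,
              x$n_taxa, x$n_sites))
  cat("Critical values (Iss.c) require tree-shape simulation and are not computed.\n")
  invisible(x)
}

## ---- exports ---------------------------------------------------------------

sanitize_taxa <- function(taxa) {
  clean <- gsub("[^A-Za-z0-9_.]", "_", taxa)
  clean <- make.unique(clean, sep = "_")
  stats::setNames(clean, taxa)
}

#' Export a supermatrix for phylogenetic inference
#'
#' Writes relaxed PHYLIP (`<prefix>.phy`), NEXUS with a sets block of
#' charsets (`<prefix>.nex`) and a RAxML-style partition file
#' (`<prefix>.partitions.txt`) with codon-position lines
#' (`DNA, gene_pos1 = start-end\\3`). Taxon names containing characters
#' outside `[A-Za-z0-9_.]` are sanitized; when any name changes a
#' `<prefix>.names.tsv` mapping file is written.
#'
#' @param sm A `super_matrix`.
#' @param prefix Output path prefix.
#' @param by_codon Emit codon-position subpartitions for coding genes
#'   (default `TRUE`).
#' @return Character vector of the files written, invisibly.
#' @export
export_supermatrix <- function(sm, prefix, by_codon = TRUE) {
  nm <- sanitize_taxa(sm$taxa)
  files <- character(0)
  L <- nchar(sm$rows[[1L]])
  # relaxed PHYLIP
  phy <- paste0(prefix, ".phy")
  con <- file(phy, "w")
  writeLines(sprintf("%d %d", length(sm$taxa), L), con)
  for (t in sm$taxa) writeLines(paste(nm[[t]], sm$rows[[t]]), con)
  close(con)
  files <- c(files, phy)
  # partitions
  parts <- if (by_codon) codon_partitions(sm) else
    cbind(sm$partitions, stride = 1L)
  ptxt <- paste0(prefix, ".partitions.txt")
  lines <- vapply(seq_len(nrow(parts)), function(i) {
    p <- parts[i, ]
    rng <- if (p$stride == 3L) sprintf("%d-%d\\3", p$start, p$end)
           else sprintf("%d-%d", p$start, p$end)
    sprintf("DNA, %s = %s", p$name, rng)
  }, character(1))
  writeLines(lines, ptxt)
  files <- c(files, ptxt)
  # NEXUS with sets block
  nex <- paste0(prefix, ".nex")
  con <- file(nex, "w")
  writeLines("#NEXUS", con)
  writeLines("BEGIN DATA;", con)
  writeLines(sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(sm$taxa), L), con)
  writeLines("  FORMAT DATATYPE=DNA MISSING=N GAP=-;", con)
  writeLines("  MATRIX", con)
  for (t in sm$taxa) writeLines(sprintf("    %s %s", nm[[t]], sm$rows[[t]]), con)
  writeLines("  ;", con)
  writeLines("END;", con)
  writeLines("BEGIN SETS;", con)
  for (i in seq_len(nrow(parts))) {
    p <- parts[i, ]
    rng <- if (p$stride == 3L) sprintf("%d-%d\\3", p$start, p$end)
           else sprintf("%d-%d", p$start, p$end)
    writeLines(sprintf("  CHARSET %s = %s;", p$name, rng), con)
  }
  writeLines("END;", con)
  close(con)
  files <- c(files, nex)
  if (any(nm != names(nm))) {
    mapf <- paste0(prefix, ".names.tsv")
    utils::write.table(data.frame(original = names(nm), sanitized = unname(nm)),
                       mapf, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, mapf)
  }
  invisible(files)
}

#' Read a relaxed-PHYLIP matrix
#'
#' Re-imports files written by [export_supermatrix()] (one sequence per
#' line, whitespace-separated name and row).
#'
#' @param path `.phy` file path.
#' @return A `super_matrix` with a single full-length partition.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  body <- lines[-1L][nzchar(trimws(lines[-1L]))]
  if (length(body) != hdr[1L]) stop("PHYLIP header declares ", hdr[1L],
                                    " taxa but ", length(body), " rows found")
  parts <- strsplit(trimws(body), "\\s+")
  taxa <- vapply(parts, `[[`, character(1), 1L)
  rows <- vapply(parts, `[[`, character(1), 2L)
  if (any(nchar(rows) != hdr[2L])) stop("row length disagrees with header")
  structure(list(taxa = taxa, rows = stats::setNames(rows, taxa),
                 partitions = data.frame(name = "all", start = 1L,
                                         end = hdr[2L], coding = FALSE,
                                         stringsAsFactors = FALSE),
                 recoding = "none"),
            class = "super_matrix")
}
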