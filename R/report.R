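fmt_num <- function(x, digits) {
  ifelse(is.na(x), "NA", formatC(round(x, digits), format = "f",
                                 digits = digits))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  path
}

#' Composition/skew table for a set of genomes
#'
#' One row per genome x region class with length, A+T% (1 decimal) and
#' AT/GC skews (3 decimals), the usual layout of mitogenome composition
#' tables.
#'
#' @param genomes List of [mito_genome()]s.
#' @return Data frame (character-formatted numeric columns, rounded at
#'   this reporting layer only).
#' @export
composition_report <- function(genomes) {
  rows <- lapply(genomes, function(g) {
    rc <- region_composition(g)
    data.frame(genome = g$id, region = rc$region, length = rc$length,
               at_percent = fmt_num(rc$at_percent, 1),
               at_skew = fmt_num(rc$at_skew, 3),
               gc_skew = fmt_num(rc$gc_skew, 3),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Start/stop codon table for a set of genomes
#'
#' @param genomes List of [mito_genome()]s.
#' @param code A [mito_code()].
#' @return Data frame `genome`, `gene`, `start_codon`, `stop_codon`,
#'   `length`.
#' @export
start_stop_report <- function(genomes, code = mito_code()) {
  rows <- lapply(genomes, function(g) {
    pcg <- g$features[g$features$kind == "PCG", , drop = FALSE]
    recs <- lapply(seq_len(nrow(pcg)), function(i) {
      detect_start_stop(pcg$name[i],
                        extract_gene(g, pcg[i, , drop = FALSE]), code)
    })
    cbind(genome = g$id, do.call(rbind, recs))
  })
  do.call(rbind, rows)
}

pcg_coding_seqs <- function(genome) {
  pcg <- genome$features[genome$features$kind == "PCG", , drop = FALSE]
  seqs <- lapply(seq_len(nrow(pcg)), function(i) {
    extract_gene(genome, pcg[i, , drop = FALSE])
  })
  stats::setNames(seqs, pcg$name)
}

#' One-command comparative report
#'
#' Runs the whole comparative workflow on one or more annotated genomes:
#' composition/skew (table1.tsv), start/stop codons (table3.tsv), RSCU
#' (rscu.tsv), junction census (junctions.tsv), and - when at least two
#' genomes and a directory of per-gene FASTA alignments are supplied -
#' per-gene divergence (divergence.tsv), sliding-window Pi
#' (pi_windows.tsv) and pairwise identity (identity.tsv), plus a JSON
#' manifest with versions, seed and collected warnings. Per-genome stage
#' errors are collected; the call fails only if every stage fails.
#'
#' @param genbank_paths Character vector of GenBank flat files.
#' @param out_dir Output directory (created if needed).
#' @param alignments_dir Optional directory of per-gene FASTA alignments
#'   (`<gene>.fasta`, taxa = genome ids).
#' @param window,step Sliding-window parameters (bp).
#' @param seed Seed recorded in the manifest (the report itself is
#'   deterministic).
#' @return Invisibly, the list of files written.
#' @export
mito_report <- function(genbank_paths, out_dir, alignments_dir = NULL,
                        window = 250L, step = 25L, seed = NULL) {
  if (length(genbank_paths) == 0L) stop("usage error: no input genomes")
  if (window <= 0L || step <= 0L || step > window) {
    stop("usage error: need 0 < step <= window")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  errors_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, conditionMessage(w))

  genomes <- list()
  for (p in genbank_paths) {
    g <- tryCatch(withCallingHandlers(read_genbank(p), warning = function(w) {
      note(w); invokeRestart("muffleWarning")
    }), error = function(e) {
      errors_log <<- c(errors_log, paste0(p, ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(g)) genomes[[g$id]] <- g
  }
  if (length(genomes) == 0L) {
    stop("all stages failed: no genome could be parsed (",
         paste(errors_log, collapse = "; "), ")")
  }

  files <- character(0)
  run_stage <- function(fname, expr) {
    res <- tryCatch(withCallingHandlers(expr, warning = function(w) {
      note(w); invokeRestart("muffleWarning")
    }), error = function(e) {
      errors_log <<- c(errors_log, paste0(fname, ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      files <<- c(files, write_tsv(res, file.path(out_dir, fname)))
    }
  }

  run_stage("table1.tsv", composition_report(genomes))
  run_stage("table3.tsv", start_stop_report(genomes))
  run_stage("rscu.tsv", {
    rows <- lapply(genomes, function(g) {
      cu <- rscu(count_codons(pcg_coding_seqs(g)))
      cbind(genome = g$id, codon_usage_table(cu))
    })
    tab <- do.call(rbind, rows)
    tab$rscu <- fmt_num(tab$rscu, 2)
    tab
  })
  run_stage("junctions.tsv", {
    rows <- lapply(genomes, function(g) {
      jx <- junctions(g)
      cbind(genome = g$id, jx$junctions)
    })
    do.call(rbind, rows)
  })

  if (length(genomes) >= 2L && !is.null(alignments_dir)) {
    alns <- load_gene_alignments(alignments_dir)
    run_stage("divergence.tsv", divergence_report(alns))
    run_stage("pi_windows.tsv", {
      conc <- concatenate_alignments(alns)
      aln <- mito_alignment(conc$taxa, conc$rows)
      tr <- sliding_window(aln, window, step)
      data.frame(midpoint = tr$midpoint, pi = fmt_num(tr$pi, 2))
    })
    run_stage("identity.tsv", {
      data.frame(gene = names(alns),
                 identity_percent = fmt_num(
                   vapply(alns, pairwise_identity, numeric(1)), 1))
    })
  }

  manifest <- list(
    package = "mitocomp",
    version = as.character(utils::packageVersion("mitocomp")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    inputs = genbank_paths,
    genomes = names(genomes),
    files = basename(files),
    warnings = warnings_log,
    errors = errors_log)
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  files <- c(files, mf)
  if (length(errors_log) > 0L && length(files) <= 1L) {
    stop("all stages failed: ", paste(errors_log, collapse = "; "))
  }
  invisible(files)
}

#' Load a directory of per-gene FASTA alignments
#'
#' @param dir Directory containing `<gene>.fasta` / `.fa` files. Coding
#'   status is inferred from the canonical gene name.
#' @return Named list of [mito_alignment()]s in file order.
#' @export
load_gene_alignments <- function(dir) {
  paths <- list.files(dir, pattern = "\\.(fasta|fa)$", full.names = TRUE)
  if (length(paths) == 0L) stop("no FASTA alignments found in ", dir)
  pcg_names <- c("nad2", "cox1", "cox2", "atp8", "atp6", "cox3", "nad3",
                 "nad5", "nad4", "nad4l", "nad6", "cob", "nad1")
  alns <- lapply(paths, function(p) {
    gene <- tools::file_path_sans_ext(basename(p))
    read_alignment(p, coding = gene %in% pcg_names)
  })
  stats::setNames(alns, tools::file_path_sans_ext(basename(paths)))
}

divergence_report <- function(alns) {
  rows <- list()
  for (g in names(alns)) {
    a <- alns[[g]]
    n <- length(a$ids)
    if (n < 2L) next
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      d <- pairwise_stats(a, i, j)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, pair = paste(a$ids[i], a$ids[j], sep = "-"),
        variable_sites = d$variable_sites, synonymous = d$synonymous,
        replacement = d$replacement, compared_sites = d$compared_sites,
        stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, pair = "all", variable_sites = NA_integer_,
      synonymous = NA_real_, replacement = NA_real_,
      compared_sites = NA_integer_, stringsAsFactors = FALSE)
    rows[[length(rows)]]$variable_sites <- NA_integer_
  }
  out <- do.call(rbind, rows)
  # append per-gene Pi as its own column on the "all" rows
  pis <- vapply(names(alns), function(g) {
    if (length(alns[[g]]$ids) >= 2L) nucleotide_diversity(alns[[g]]) else NA_real_
  }, numeric(1))
  out$pi <- NA_character_
  out$pi[out$pair == "all"] <- fmt_num(pis[out$gene[out$pair == "all"]], 2)
  out
}
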