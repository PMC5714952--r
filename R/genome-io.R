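#' Construct an annotated mitochondrial genome object
#'
#' The central container of the package: a (usually circular) nucleotide
#' sequence plus an ordered table of gene features. Coordinates are stored
#' 0-based half-open internally; GenBank 1-based inclusive coordinates are
#' converted at the I/O boundary. A feature spanning the sequence origin
#' carries `wrap = TRUE` and an `end` exceeding the genome length, so each
#' gene remains a single feature.
#'
#' @param id Accession-like identifier.
#' @param sequence Nucleotide string over A, C, G, T, N.
#' @param features Data frame with columns `name`, `kind` (one of `"PCG"`,
#'   `"tRNA"`, `"rRNA"`, `"control_region"`, `"other"`), `start`, `end`
#'   (0-based half-open), `strand` (`"J"` majority / `"N"` minority) and
#'   optionally `anticodon`, `wrap`.
#' @param circular Logical; circular molecule (default `TRUE`).
#' @return Object of class `mito_genome`.
#' @export
mito_genome <- function(id, sequence, features = NULL, circular = TRUE) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty genome sequence")
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  L <- nchar(sequence)
  if (is.null(features)) {
    features <- data.frame(name = character(), kind = character(),
                           start = integer(), end = integer(),
                           strand = character(), anticodon = character(),
                           wrap = logical(), stringsAsFactors = FALSE)
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features) > 0L) {
    if (is.null(features$anticodon)) features$anticodon <- NA_character_
    if (is.null(features$wrap)) features$wrap <- FALSE
    features$start <- as.integer(features$start)
    features$end <- as.integer(features$end)
    bad_kind <- setdiff(features$kind,
                        c("PCG", "tRNA", "rRNA", "control_region", "other"))
    if (length(bad_kind) > 0L) stop("unknown feature kind: ", bad_kind[1L])
    if (any(features$start < 0L | features$start >= L)) {
      stop("feature start outside [0, genome length)")
    }
    if (any(features$end <= features$start)) stop("feature end <= start")
    over <- features$end > L & !features$wrap
    if (any(over)) {
      stop("feature '", features$name[which(over)[1L]],
           "' extends past the genome end without a wrap flag")
    }
    if (any(features$wrap & !circular)) {
      stop("wrap-flagged feature on a linear molecule")
    }
    if (any(features$end - features$start > L)) {
      stop("feature longer than the genome")
    }
    len <- features$end - features$start
    if (any(features$kind == "PCG" & len < 4L)) {
      stop("protein-coding feature shorter than 4 nt")
    }
    if (any(features$kind == "tRNA" & (len < 55L | len > 80L))) {
      stop("tRNA feature length outside [55, 80] nt")
    }
    dup <- features$name[duplicated(features$name)]
    if (length(dup) > 0L) {
      stop("annotation conflict: duplicate canonical gene name '", dup[1L], "'")
    }
    features <- features[order(features$start), , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(id = id, sequence = sequence, circular = circular,
                 features = features),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat("Mitochondrial genome", x$id, "-", nchar(x$sequence), "bp,",
      if (x$circular) "circular" else "linear", "\n")
  cat(nrow(x$features), "annotated features\n")
  invisible(x)
}

genome_length <- function(genome) nchar(genome$sequence)

feature_lengths <- function(genome) {
  with(genome$features, stats::setNames(end - start, name))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substring of a circular sequence, 0-based half-open; end may exceed L
# only when wrap is TRUE
seq_slice <- function(sequence, start, end, wrap = FALSE) {
  L <- nchar(sequence)
  if (start < 0L || start >= L) stop("slice start out of bounds")
  if (end <= start) stop("slice end <= start")
  if (end > L) {
    if (!wrap) stop("slice extends past sequence end without wrap flag")
    paste0(substr(sequence, start + 1L, L), substr(sequence, 1L, end - L))
  } else {
    substr(sequence, start + 1L, end)
  }
}

#' Extract a gene sequence in coding orientation
#'
#' J-strand features are returned verbatim; N-strand features are
#' reverse-complemented; origin-spanning features are stitched across
#' position zero.
#'
#' @param genome A [mito_genome()].
#' @param feature A gene name, a feature row index, or a one-row slice of
#'   `genome$features`.
#' @return Nucleotide string in coding orientation.
#' @export
extract_gene <- function(genome, feature) {
  f <- resolve_feature(genome, feature)
  s <- seq_slice(genome$sequence, f$start, f$end, wrap = isTRUE(f$wrap))
  if (identical(f$strand, "N")) revcomp(s) else s
}

resolve_feature <- function(genome, feature) {
  ft <- genome$features
  if (is.character(feature) && length(feature) == 1L) {
    i <- match(feature, ft$name)
    if (is.na(i)) stop("no feature named '", feature, "' in genome ", genome$id)
    ft[i, , drop = FALSE]
  } else if (is.numeric(feature) && length(feature) == 1L) {
    if (feature < 1L || feature > nrow(ft)) stop("feature index out of range")
    ft[feature, , drop = FALSE]
  } else if (is.data.frame(feature) && nrow(feature) == 1L) {
    feature
  } else {
    stop("feature must be a name, an index, or a one-row data frame")
  }
}

## ---- gene-name canonicalization -------------------------------------------

aa3_to_1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
              Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
              Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
              Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

#' Gene-name synonym table
#'
#' Loads the editable alias -> canonical-name table shipped with the
#' package (lower-cased aliases for common GenBank spellings of insect
#' mitochondrial genes).
#'
#' @param path Optional path to a user-supplied two-column TSV
#'   (`alias`, `canonical`).
#' @return Named character vector mapping lower-case alias to canonical name.
#' @export
gene_synonyms <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gene_synonyms.tsv", package = "mitocomp")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$canonical, tolower(tab$alias))
}

#' Canonicalize a gene label
#'
#' Maps heterogeneous GenBank gene/product labels to the canonical names
#' used throughout the package (nad1..nad6, nad4l, cox1..cox3, cob, atp6,
#' atp8, rrnL, rrnS, trnA..trnV with trnL1/trnL2 and trnS1/trnS2, CR).
#'
#' @param label Raw label (e.g. `"ND2"`, `"COI"`, `"tRNA-Ser(AGN)"`).
#' @param anticodon Optional anticodon trinucleotide (DNA alphabet), used
#'   to resolve the two serine/leucine tRNA families when the label alone
#'   is ambiguous.
#' @param synonyms Synonym map from [gene_synonyms()].
#' @return Canonical name, or `NA_character_` if unrecognised.
#' @export
canonicalize_gene_name <- function(label, anticodon = NA_character_,
                                   synonyms = gene_synonyms()) {
  lab <- tolower(trimws(label))
  if (!is.na(syn <- unname(synonyms[lab]))) return(syn)
  # already-canonical tRNA spellings: trnA, trnS1, ...
  if (grepl("^trn[a-z][12]?$", lab)) {
    base <- paste0("trn", toupper(substr(lab, 4L, 4L)), substring(lab, 5L))
    return(base)
  }
  # tRNA-Xyz and tRNA-Ser(AGN) style labels
  m <- regmatches(lab, regexec("^trna[-_ ]?([a-z]{3})\\s*(\\(([a-z]{3})\\))?$", lab))[[1L]]
  if (length(m) > 0L) {
    aa3 <- paste0(toupper(substr(m[2L], 1L, 1L)), substr(m[2L], 2L, 3L))
    aa1 <- unname(aa3_to_1[aa3])
    if (is.na(aa1)) return(NA_character_)
    if (!aa1 %in% c("L", "S")) return(paste0("trn", aa1))
    fam <- toupper(m[4L])
    if (nzchar(fam) && !is.na(fam)) {
      fam <- chartr("U", "T", fam)
      if (aa1 == "S" && fam == "AGN") return("trnS1")
      if (aa1 == "S" && fam == "TCN") return("trnS2")
      if (aa1 == "L" && fam == "CTN") return("trnL1")
      if (aa1 == "L" && fam == "TTR") return("trnL2")
    }
    return(trna_family_from_anticodon(aa1, anticodon))
  }
  NA_character_
}

trna_family_from_anticodon <- function(aa1, anticodon) {
  if (is.na(anticodon)) return(NA_character_)
  ac <- chartr("U", "T", toupper(anticodon))
  if (aa1 == "S") {
    if (ac %in% c("TCT", "GCT")) return("trnS1")
    if (ac == "TGA") return("trnS2")
  }
  if (aa1 == "L") {
    if (ac == "TAG") return("trnL1")
    if (ac == "TAA") return("trnL2")
  }
  NA_character_
}

## ---- GenBank flat-file I/O -------------------------------------------------

#' Read an annotated mitogenome from a GenBank flat file
#'
#' A minimal parser for single-record GenBank flat files carrying CDS,
#' tRNA, rRNA and D-loop/misc features, sufficient for deposited insect
#' mitogenomes. Gene labels are canonicalized via
#' [canonicalize_gene_name()]; when no control-region feature is annotated
#' but rrnS and trnI are present, the unannotated span between them is
#' labelled `CR` if at least 50 bp.
#'
#' @param path Path to a `.gb` file.
#' @param synonyms Synonym map, see [gene_synonyms()].
#' @return A [mito_genome()].
#' @export
read_genbank <- function(path, synonyms = gene_synonyms()) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[1L], "LOCUS")) {
    stop("malformed GenBank record at line 1: missing LOCUS line in ", path)
  }
  locus <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  id <- locus[2L]
  circular <- any(tolower(locus) == "circular")
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc_line) > 0L) {
    acc <- strsplit(trimws(acc_line[1L]), "\\s+")[[1L]]
    if (length(acc) >= 2L) id <- acc[2L]
  }

  feat_start <- grep("^FEATURES", lines)
  origin_start <- grep("^ORIGIN", lines)
  if (length(origin_start) == 0L) {
    stop("malformed GenBank record: no ORIGIN section in ", path)
  }
  seq_lines <- lines[(origin_start[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  features <- parse_genbank_features(
    lines, feat_start, origin_start, synonyms, path, nchar(sequence)
  )
  g <- mito_genome(id, sequence, features, circular = circular)
  autolabel_control_region(g)
}

parse_genbank_features <- function(lines, feat_start, origin_start,
                                   synonyms, path, seqlen) {
  empty <- data.frame(name = character(), kind = character(),
                      start = integer(), end = integer(),
                      strand = character(), anticodon = character(),
                      wrap = logical(), stringsAsFactors = FALSE)
  if (length(feat_start) == 0L) return(empty)
  body <- lines[(feat_start[1L] + 1L):(origin_start[1L] - 1L)]
  lineno <- (feat_start[1L] + 1L):(origin_start[1L] - 1L)
  is_key <- grepl("^ {2,8}\\S", body)
  idx <- which(is_key)
  if (length(idx) == 0L) return(empty)

  out <- list()
  for (k in seq_along(idx)) {
    first <- idx[k]
    last <- if (k < length(idx)) idx[k + 1L] - 1L else length(body)
    chunk <- body[first:last]
    key <- sub("^\\s*(\\S+).*$", "\\1", chunk[1L])
    if (!key %in% c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")) next
    # location may continue over lines until the first qualifier
    qual_at <- grep("^\\s{10,}/", chunk)
    loc_end <- if (length(qual_at) > 0L) qual_at[1L] - 1L else length(chunk)
    loc <- gsub("\\s", "", paste(
      c(sub("^\\s*\\S+\\s*", "", chunk[1L]), if (loc_end >= 2L) chunk[2:loc_end]),
      collapse = ""))
    pos <- tryCatch(parse_gb_location(loc),
                    error = function(e) stop("malformed location at line ",
                                             lineno[first], " of ", path, ": ",
                                             conditionMessage(e)))
    if (isTRUE(pos$wrap)) {
      if (!is.null(pos$head_to) && pos$head_to != seqlen) {
        stop("malformed location at line ", lineno[first], " of ", path,
             ": join does not span the origin")
      }
      pos$end <- seqlen + pos$tail
    }
    quals <- parse_gb_qualifiers(chunk[seq_len(length(chunk)) >= loc_end + 1L])
    label <- quals[["gene"]] %||% quals[["product"]] %||% quals[["note"]]
    anticodon <- extract_anticodon(quals[["anticodon"]] %||% quals[["note"]])
    kind <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                   "D-loop" = "control_region", misc_feature = "other")
    if (key == "misc_feature" &&
        !is.null(label) && grepl("control region|a\\+t-rich", tolower(label))) {
      kind <- "control_region"
    }
    name <- if (kind == "control_region") "CR" else if (is.null(label)) {
      NA_character_
    } else {
      canonicalize_gene_name(label, anticodon, synonyms)
    }
    if (is.na(name)) {
      name <- if (is.null(label)) paste0("feat", k) else label
    }
    out[[length(out) + 1L]] <- data.frame(
      name = name, kind = kind, start = pos$start, end = pos$end,
      strand = if (pos$complement) "N" else "J",
      anticodon = anticodon %||% NA_character_, wrap = pos$wrap,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1L])) b else a

# 1-based inclusive GenBank location -> 0-based half-open with wrap flag
parse_gb_location <- function(loc) {
  complement <- FALSE
  if (grepl("^complement\\(", loc)) {
    complement <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1L]]
    if (length(parts) != 2L) stop("unsupported join with ", length(parts), " segments")
    a <- parse_simple_span(parts[1L])
    b <- parse_simple_span(parts[2L])
    if (b$from != 1L) stop("join is not an origin-spanning pair")
    # span runs a$from..end-of-molecule then 1..b$to; caller's genome length
    # is unknown here, so encode as wrap with end = length + b$to later:
    return(list(start = a$from - 1L, end = NA_integer_, wrap = TRUE,
                tail = b$to, head_to = a$to, complement = complement))
  }
  s <- parse_simple_span(loc)
  list(start = s$from - 1L, end = s$to, wrap = FALSE, complement = complement)
}

parse_simple_span <- function(x) {
  m <- regmatches(x, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", x))[[1L]]
  if (length(m) == 0L) stop("cannot parse span '", x, "'")
  list(from = as.integer(m[2L]), to = as.integer(m[3L]))
}

parse_gb_qualifiers <- function(chunk) {
  if (length(chunk) == 0L) return(list())
  txt <- trimws(chunk)
  starts <- grep("^/", txt)
  quals <- list()
  for (k in seq_along(starts)) {
    last <- if (k < length(starts)) starts[k + 1L] - 1L else length(txt)
    piece <- paste(txt[starts[k]:last], collapse = " ")
    m <- regmatches(piece, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?', piece))[[1L]]
    if (length(m) > 0L) quals[[m[2L]]] <- m[3L]
  }
  quals
}

extract_anticodon <- function(x) {
  if (is.null(x)) return(NA_character_)
  m <- regmatches(x, regexec("seq:([acgtu]{3})", tolower(x)))[[1L]]
  if (length(m) > 0L) return(chartr("u", "t", toupper(m[2L])))
  m <- regmatches(x, regexec("anticodon[: ]*([ACGTUacgtu]{3})", x))[[1L]]
  if (length(m) > 0L) return(chartr("U", "T", toupper(m[2L])))
  NA_character_
}

# fix wrap features whose end could not be resolved before sequence length
# was known, then label the CR if absent
autolabel_control_region <- function(g) {
  L <- genome_length(g)
  ft <- g$features
  if (nrow(ft) > 0L && anyNA(ft$end)) {
    stop("internal error: unresolved wrap coordinates")
  }
  if (nrow(ft) == 0L) return(g)
  if (!"control_region" %in% ft$kind &&
      all(c("rrnS", "trnI") %in% ft$name)) {
    rs <- ft[ft$name == "rrnS", ]
    ti <- ft[ft$name == "trnI", ]
    cr_start <- rs$end %% L
    cr_end <- ti$start
    wrap <- cr_end <= cr_start
    if (wrap) cr_end <- cr_end + L
    if (cr_end - cr_start >= 50L) {
      ft <- rbind(ft, data.frame(
        name = "CR", kind = "control_region", start = cr_start,
        end = cr_end, strand = "J", anticodon = NA_character_,
        wrap = wrap, stringsAsFactors = FALSE))
      g <- mito_genome(g$id, g$sequence, ft, circular = g$circular)
    }
  }
  g
}

#' Write a mito_genome as a GenBank flat file
#'
#' Inverse of [read_genbank()] for round-tripping annotated genomes
#' (synthetic fixtures in particular). Coordinates are emitted 1-based
#' inclusive; origin-spanning features become `join()` locations.
#'
#' @param genome A [mito_genome()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  L <- genome_length(genome)
  con <- file(path, "w")
  on.exit(close(con))
  topo <- if (genome$circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s UNK",
                     genome$id, L, topo), con)
  writeLines(sprintf("ACCESSION   %s", genome$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  ft <- genome$features
  for (i in seq_len(nrow(ft))) {
    f <- ft[i, ]
    key <- switch(f$kind, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  control_region = "D-loop", other = "misc_feature")
    loc <- if (isTRUE(f$wrap)) {
      sprintf("join(%d..%d,1..%d)", f$start + 1L, L, f$end - L)
    } else {
      sprintf("%d..%d", f$start + 1L, f$end)
    }
    if (identical(f$strand, "N")) loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-16s%s", key, loc), con)
    if (f$kind != "control_region") {
      writeLines(sprintf('                     /gene="%s"', f$name), con)
    }
    if (!is.na(f$anticodon)) {
      writeLines(sprintf('                     /note="anticodon:%s"', f$anticodon), con)
    }
  }
  writeLines("ORIGIN", con)
  starts <- seq(1L, L, by = 60L)
  for (s in starts) {
    block <- substr(genome$sequence, s, min(s + 59L, L))
    chunks <- substring(block, seq(1L, nchar(block), 10L),
                        pmin(seq(10L, nchar(block) + 9L, 10L), nchar(block)))
    writeLines(sprintf("%9d %s", s, tolower(paste(chunks, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Export per-gene sequences as FASTA
#'
#' Writes each annotated gene in coding orientation with headers
#' `<genome_id>|<gene>|<strand>`.
#'
#' @param genome A [mito_genome()].
#' @param path Output FASTA path.
#' @param genes Optional character vector restricting which genes to write.
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(genome, path, genes = NULL) {
  ft <- genome$features
  if (!is.null(genes)) ft <- ft[ft$name %in% genes, , drop = FALSE]
  seqs <- vapply(seq_len(nrow(ft)), function(i) {
    extract_gene(genome, ft[i, , drop = FALSE])
  }, character(1))
  names(seqs) <- sprintf("%s|%s|%s", genome$id, ft$name, ft$strand)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Rotate the origin of a circular genome
#'
#' Returns an equivalent genome whose sequence starts `offset` bases
#' further along the J strand; feature coordinates are renumbered and
#' wrap flags adjusted. Useful for testing rotation invariance of
#' downstream statistics.
#'
#' @param genome A circular [mito_genome()].
#' @param offset Rotation in bp (0 <= offset < genome length).
#' @return A [mito_genome()].
#' @export
rotate_genome <- function(genome, offset) {
  if (!genome$circular) stop("cannot rotate a linear molecule")
  L <- genome_length(genome)
  offset <- as.integer(offset %% L)
  if (offset == 0L) return(genome)
  seq2 <- paste0(substr(genome$sequence, offset + 1L, L),
                 substr(genome$sequence, 1L, offset))
  ft <- genome$features
  if (nrow(ft) > 0L) {
    len <- ft$end - ft$start
    ft$start <- (ft$start - offset) %% L
    ft$end <- ft$start + len
    ft$wrap <- ft$end > L
  }
  mito_genome(genome$id, seq2, ft, circular = TRUE)
}
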