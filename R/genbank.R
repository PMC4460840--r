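#' Read an annotated mitogenome from a GenBank flat file
#'
#' Parses one or more GenBank records (LOCUS/FEATURES/ORIGIN) into a
#' [mito_genome()]. Gene, CDS, tRNA, rRNA, D-loop and misc_feature entries are
#' mapped onto the canonical vocabulary via [normalize_gene_name()] (using the
#' `/anticodon` qualifier to split serine/leucine isoacceptors where needed);
#' unmappable names are preserved as `noncoding` features with a warning.
#' Topology is taken from the LOCUS line (`circular` keyword), defaulting to
#' linear. GenBank 1-based inclusive locations (including origin-wrapping
#' `join(x..N,1..y)` locations on circular records) are converted to the
#' package's 0-based half-open coordinates.
#'
#' @param path Path to a GenBank flat file with >= 1 record.
#' @param label Genome label; defaults to the first record's LOCUS name.
#' @param extra_aliases Optional alias data.frame passed to
#'   [normalize_gene_name()].
#' @return A `mito_genome` with one chromosome per record.
#' @export
read_genbank <- function(path, label = NULL, extra_aliases = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("read_genbank: empty file: ", path)
  ends <- grep("^//\\s*$", lines)
  if (!length(ends)) {
    if (!any(grepl("^LOCUS", lines))) stop("read_genbank: not a GenBank file")
    ends <- length(lines)
  }
  starts <- c(1L, head(ends, -1L) + 1L)
  chroms <- list()
  for (i in seq_along(ends)) {
    chunk <- lines[starts[i]:ends[i]]
    chunk <- chunk[!grepl("^//\\s*$", chunk)]
    if (!any(nzchar(trimws(chunk)))) next
    chroms[[length(chroms) + 1L]] <- parse_genbank_record(chunk, extra_aliases)
  }
  if (!length(chroms)) stop("read_genbank: no records in ", path)
  if (is.null(label)) label <- chroms[[1]]$record$id
  mito_genome(label, chroms)
}

parse_genbank_record <- function(lines, extra_aliases = NULL) {
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("read_genbank: record without LOCUS line")
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  id <- toks[2]
  topology <- if (any(tolower(toks) == "circular")) "circular" else "linear"

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("read_genbank: record without ORIGIN section")
  seq_lines <- lines[(ori[1] + 1L):length(lines)]
  residues <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(residues)) stop("read_genbank: empty sequence in record ", id)
  record <- sequence_record(id, residues, topology)
  len <- nchar(residues)

  fstart <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fstart)) {
    fend <- ori[1] - 1L
    flines <- lines[(fstart[1] + 1L):fend]
    # a new feature starts at column 6 with a key; qualifiers are indented
    key_idx <- grep("^ {5}\\S", flines)
    for (j in seq_along(key_idx)) {
      from <- key_idx[j]
      to <- if (j < length(key_idx)) key_idx[j + 1L] - 1L else length(flines)
      block <- flines[from:to]
      head_toks <- strsplit(trimws(block[1]), "\\s+")[[1]]
      key <- head_toks[1]
      if (key == "source") next
      loc <- paste0(head_toks[-1], collapse = "")
      # location may continue on following lines before the first qualifier
      k <- 2L
      while (k <= length(block) && !grepl("^\\s+/", block[k])) {
        loc <- paste0(loc, trimws(block[k])); k <- k + 1L
      }
      quals <- parse_qualifiers(block[seq_len(length(block)) >= k])
      f <- genbank_feature(key, loc, quals, len, topology, extra_aliases)
      if (!is.null(f)) feats[[length(feats) + 1L]] <- f
    }
    feats <- drop_redundant_gene_keys(feats)
  }
  chromosome(record, feats)
}

parse_qualifiers <- function(lines) {
  txt <- paste(trimws(lines), collapse = " ")
  out <- list()
  m <- gregexpr('/([A-Za-z_]+)=("([^"]*)"|[^ /]+)', txt)[[1]]
  if (m[1] == -1) return(out)
  for (i in seq_along(m)) {
    piece <- substr(txt, m[i], m[i] + attr(m, "match.length")[i] - 1L)
    key <- sub("^/([A-Za-z_]+)=.*$", "\\1", piece)
    val <- sub("^/[A-Za-z_]+=", "", piece)
    val <- gsub('^"|"$', "", val)
    out[[key]] <- val
  }
  out
}

parse_gb_location <- function(loc, len, topology) {
  strand <- "J"
  x <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", x)) {
    strand <- "N"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  if (grepl("^join\\(", x)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", x)
    parts <- strsplit(inner, ",")[[1]]
    rng <- lapply(parts, parse_gb_span)
    if (length(rng) == 2L && rng[[1]]$to == len && rng[[2]]$from == 1L &&
        topology == "circular") {
      return(list(start = rng[[1]]$from - 1L, end = rng[[2]]$to,
                  strand = strand))
    }
    # non-wrap joins collapsed to their envelope
    return(list(start = min(vapply(rng, `[[`, numeric(1), "from")) - 1L,
                end = max(vapply(rng, `[[`, numeric(1), "to")),
                strand = strand))
  }
  sp <- parse_gb_span(x)
  list(start = sp$from - 1L, end = sp$to, strand = strand)
}

parse_gb_span <- function(x) {
  x <- gsub("[<>]", "", x)
  if (grepl("\\.\\.", x)) {
    ab <- as.integer(strsplit(x, "\\.\\.")[[1]])
    list(from = ab[1], to = ab[2])
  } else {
    v <- as.integer(x)
    list(from = v, to = v)
  }
}

genbank_feature <- function(key, loc, quals, len, topology, extra_aliases) {
  known <- c("gene", "CDS", "tRNA", "rRNA", "D-loop", "misc_feature")
  if (!key %in% known) return(NULL)
  pos <- parse_gb_location(loc, len, topology)
  raw <- quals$gene %||% quals$product %||% quals$note %||%
    if (key == "D-loop") "control region" else NA_character_
  if (is.na(raw)) raw <- "unnamed"
  anticodon <- NULL
  if (!is.null(quals$anticodon)) {
    m <- regmatches(quals$anticodon,
                    regexpr("seq:[A-Za-z]+", quals$anticodon))
    if (length(m)) anticodon <- sub("seq:", "", m)
  }
  canon <- normalize_gene_name(raw, anticodon = anticodon,
                               extra = extra_aliases)
  if (is.na(canon)) {
    if (key != "misc_feature") {
      warning("read_genbank: unmappable feature name '", raw,
              "' kept as noncoding", call. = FALSE)
    }
    f <- gene_feature(raw, pos$strand, pos$start, pos$end, kind = "noncoding")
  } else {
    f <- gene_feature(canon, pos$strand, pos$start, pos$end)
  }
  attr(f, "gb_key") <- key
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 'gene' entries that duplicate a typed feature (CDS/tRNA/rRNA) of the same
# name are dropped; remaining 'gene' entries stand for themselves.
drop_redundant_gene_keys <- function(feats) {
  if (!length(feats)) return(feats)
  keys <- vapply(feats, function(f) attr(f, "gb_key") %||% "", character(1))
  names <- vapply(feats, `[[`, character(1), "name")
  keep <- vapply(seq_along(feats), function(i) {
    if (keys[i] != "gene") return(TRUE)
    !any(keys != "gene" & names == names[i])
  }, logical(1))
  feats[keep]
}

#' Write a mitogenome as a GenBank flat file
#'
#' One record per chromosome. Features are emitted under their kind-specific
#' key (CDS for protein genes, tRNA, rRNA, D-loop for the control region,
#' misc_feature for noncoding) with a `/gene` qualifier, converting internal
#' 0-based half-open intervals to 1-based inclusive locations; features that
#' wrap the origin of a circular record become `join(x..N,1..y)` locations.
#' The emitted file re-reads (with [read_genbank()]) to a field-equal genome.
#'
#' @param genome A `mito_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  stopifnot(inherits(genome, "mito_genome"))
  out <- character(0)
  for (ch in genome$chromosomes) {
    out <- c(out, format_genbank_record(ch, genome$label))
  }
  writeLines(out, path)
  invisible(path)
}

format_genbank_record <- function(ch, label) {
  rec <- ch$record
  len <- nchar(rec$residues)
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     %-8s INV 01-JAN-2026",
            rec$id, len, rec$topology),
    sprintf("DEFINITION  %s %s.", label, rec$id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", len)
  )
  for (f in ch$features) {
    key <- switch(f$kind, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  control = "D-loop", noncoding = "misc_feature")
    loc <- if (feature_wraps(f)) {
      sprintf("join(%d..%d,1..%d)", f$start + 1L, len, f$end)
    } else {
      sprintf("%d..%d", f$start + 1L, f$end)
    }
    if (f$strand == "N") loc <- sprintf("complement(%s)", loc)
    lines <- c(lines,
               sprintf("     %-15s %s", key, loc),
               sprintf("                     /gene=\"%s\"", f$name))
  }
  lines <- c(lines, "ORIGIN")
  seq <- tolower(rec$residues)
  for (pos in seq(1L, len, by = 60L)) {
    chunk <- substr(seq, pos, min(pos + 59L, len))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", pos, paste(groups, collapse = " ")))
  }
  c(lines, "//")
}

#' FASTA and feature-table input/output
#'
#' FASTA carries sequence only; annotations travel in a tab-separated
#' side-channel table with columns `chromosome, name, kind, strand, start,
#' end` (0-based half-open coordinates, `start > end` = origin wrap).
#'
#' @param path File path.
#' @param topology Topology to assign to every FASTA record.
#' @return `read_fasta()`: list of `sequence_record`s.
#' @export
read_fasta <- function(path, topology = "linear") {
  set <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(set), function(i) {
    sequence_record(strsplit(names(set)[i], "\\s+")[[1]][1],
                    as.character(set[[i]]), topology)
  })
}

#' @rdname read_fasta
#' @param records List of `sequence_record`s (or a `mito_genome`).
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "mito_genome")) {
    records <- lapply(records$chromosomes, `[[`, "record")
  }
  if (inherits(records, "sequence_record")) records <- list(records)
  set <- Biostrings::DNAStringSet(vapply(records, `[[`, character(1),
                                         "residues"))
  names(set) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname read_fasta
#' @param genome A `mito_genome`.
#' @export
write_feature_table <- function(genome, path) {
  df <- genome_features(genome)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_fasta
#' @param fasta_path,table_path Paths to the FASTA file and its feature table.
#' @param label Genome label.
#' @export
read_fasta_genome <- function(fasta_path, table_path, label = NULL,
                              topology = "circular") {
  recs <- read_fasta(fasta_path, topology)
  tab <- utils::read.table(table_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  chroms <- lapply(recs, function(r) {
    rows <- tab[tab$chromosome == r$id, , drop = FALSE]
    feats <- lapply(seq_len(nrow(rows)), function(i) {
      gene_feature(rows$name[i], rows$strand[i], rows$start[i], rows$end[i],
                   kind = rows$kind[i])
    })
    chromosome(r, feats)
  })
  if (is.null(label)) label <- recs[[1]]$id
  mito_genome(label, chroms)
}
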