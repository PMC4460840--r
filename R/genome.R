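#' Annotated mitochondrial sequence containers
#'
#' `sequence_record()` holds a DNA sequence plus its topology;
#' `gene_feature()` is one annotated gene on a chromosome; `chromosome()`
#' couples a record with its ordered features; `mito_genome()` is a named set
#' of one or more chromosomes (one for the usual unipartite animal mitogenome,
#' two or more for multipartite genomes such as the thrips mini-circle
#' architecture).
#'
#' Coordinates are 0-based half-open throughout. On a circular record a
#' feature may wrap the sequence origin; this is encoded as `start > end`,
#' meaning the feature runs `start..length-1` then `0..end-1`. GenBank
#' input/output converts to and from 1-based inclusive (join) locations.
#'
#' @param id Record identifier.
#' @param residues DNA string over the IUPAC alphabet (A,C,G,T,N plus
#'   ambiguity codes); case-insensitive, stored upper-case.
#' @param topology `"circular"` or `"linear"`.
#' @return `sequence_record()`: an object of class `sequence_record`.
#' @export
sequence_record <- function(id, residues, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L)
  residues <- toupper(as.character(residues))
  if (nchar(residues) < 1L) stop("sequence_record: empty sequence")
  if (grepl("[^ACGTNRYSWKMBDHV]", residues)) {
    bad <- unique(strsplit(gsub("[ACGTNRYSWKMBDHV]", "", residues), "")[[1]])
    stop("sequence_record: non-IUPAC characters in sequence: ",
         paste(bad, collapse = " "))
  }
  structure(list(id = id, residues = residues, topology = topology),
            class = "sequence_record")
}

#' @rdname sequence_record
#' @param name Canonical gene token (see [mito_genes()]), `"control_region"`,
#'   or any other token (treated as `noncoding`).
#' @param strand `"J"` (majority-coding) or `"N"` (minority-coding).
#' @param start,end 0-based half-open interval; `start > end` encodes an
#'   origin-wrapping feature on a circular record.
#' @param kind Feature kind; derived from `name` when `NULL`.
#' @export
gene_feature <- function(name, strand, start, end, kind = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!strand %in% c("J", "N")) {
    stop("gene_feature: strand must be 'J' or 'N', got '", strand, "'")
  }
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end < 0L) {
    stop("gene_feature: invalid interval [", start, ", ", end, ")")
  }
  if (start == end) stop("gene_feature: empty interval not allowed")
  if (is.null(kind)) kind <- gene_kind(name)
  if (!kind %in% c("PCG", "tRNA", "rRNA", "control", "noncoding")) {
    stop("gene_feature: unknown kind '", kind, "'")
  }
  structure(list(name = name, kind = kind, strand = strand,
                 start = start, end = end),
            class = "gene_feature")
}

feature_wraps <- function(feature) feature$start > feature$end

feature_length <- function(feature, seq_length) {
  if (feature_wraps(feature)) seq_length - feature$start + feature$end
  else feature$end - feature$start
}

#' @rdname sequence_record
#' @param record A `sequence_record`.
#' @param features List of `gene_feature` objects; re-sorted by start.
#' @export
chromosome <- function(record, features = list()) {
  stopifnot(inherits(record, "sequence_record"))
  len <- nchar(record$residues)
  for (f in features) {
    stopifnot(inherits(f, "gene_feature"))
    if (f$start > len || f$end > len) {
      stop("chromosome: feature '", f$name, "' outside sequence [0, ", len, "]")
    }
    if (feature_wraps(f) && record$topology != "circular") {
      stop("chromosome: feature '", f$name,
           "' wraps the origin but topology is linear")
    }
  }
  if (length(features)) {
    features <- features[order(vapply(features, `[[`, integer(1), "start"))]
  }
  structure(list(record = record, features = features), class = "chromosome")
}

#' @rdname sequence_record
#' @param label Genome label (e.g. a cryptic-species name).
#' @param chromosomes List of `chromosome` objects.
#' @export
mito_genome <- function(label, chromosomes) {
  stopifnot(is.character(label), length(label) == 1L)
  if (inherits(chromosomes, "chromosome")) chromosomes <- list(chromosomes)
  stopifnot(length(chromosomes) >= 1L,
            all(vapply(chromosomes, inherits, logical(1), "chromosome")))
  structure(list(label = label, chromosomes = chromosomes),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat("mito_genome '", x$label, "': ", length(x$chromosomes),
      " chromosome(s)\n", sep = "")
  for (ch in x$chromosomes) {
    cat("  ", ch$record$id, ": ", nchar(ch$record$residues), " bp, ",
        ch$record$topology, ", ", length(ch$features), " features\n", sep = "")
  }
  cp <- genome_completeness(x)
  cat(if (cp$complete) "  all 37 canonical genes present\n"
      else paste0("  missing: ", paste(cp$missing, collapse = ", "), "\n"))
  invisible(x)
}

#' Completeness over the 37 canonical genes
#'
#' A multipartite genome is complete when each canonical gene is present on at
#' least one chromosome; paralogous duplicates (e.g. a control region and
#' trnS1 carried by both chromosomes of a bipartite genome) are allowed.
#'
#' @param genome A `mito_genome`.
#' @return List with `complete` (logical), `missing` (character) and `counts`
#'   (named integer vector of gene copy numbers).
#' @export
genome_completeness <- function(genome) {
  present <- unlist(lapply(genome$chromosomes, function(ch) {
    vapply(ch$features, `[[`, character(1), "name")
  }))
  counts <- table(factor(present, levels = union(mito_genes(), unique(present))))
  missing <- setdiff(mito_genes(), present)
  list(complete = length(missing) == 0L, missing = missing,
       counts = c(counts))
}

#' All features of a genome as a data.frame
#' @param genome A `mito_genome`.
#' @return data.frame with chromosome, name, kind, strand, start, end.
#' @export
genome_features <- function(genome) {
  do.call(rbind, lapply(genome$chromosomes, function(ch) {
    if (!length(ch$features)) return(NULL)
    data.frame(
      chromosome = ch$record$id,
      name = vapply(ch$features, `[[`, character(1), "name"),
      kind = vapply(ch$features, `[[`, character(1), "kind"),
      strand = vapply(ch$features, `[[`, character(1), "strand"),
      start = vapply(ch$features, `[[`, integer(1), "start"),
      end = vapply(ch$features, `[[`, integer(1), "end"),
      stringsAsFactors = FALSE
    )
  }))
}

#' Reverse complement of a DNA string
#' @param x DNA string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Extract the (possibly wrapping) plus-strand segment of a feature.
segment_seq <- function(record, start, end) {
  len <- nchar(record$residues)
  if (start < end) {
    substr(record$residues, start + 1L, end)
  } else {
    if (record$topology != "circular") stop("wrapping segment on linear record")
    paste0(substr(record$residues, start + 1L, len),
           substr(record$residues, 1L, end))
  }
}

#' Sequence of an annotated feature
#'
#' Returns the feature's sequence read 5'-to-3' on its coding strand:
#' N-strand features are reverse-complemented.
#'
#' @param chrom A `chromosome`.
#' @param feature A `gene_feature` on that chromosome.
#' @return DNA string.
#' @export
feature_seq <- function(chrom, feature) {
  s <- segment_seq(chrom$record, feature$start, feature$end)
  if (feature$strand == "N") revcomp(s) else s
}

#' A+T content of a sequence
#'
#' Percentage of A and T among unambiguous bases; IUPAC ambiguity codes and N
#' are excluded from both numerator and denominator.
#'
#' @param record A `sequence_record` (or plain DNA string).
#' @param interval Optional 0-based half-open `c(start, end)`; `start > end`
#'   wraps the origin on circular records. `NULL` = whole sequence.
#' @return Percent A+T in `[0, 100]`.
#' @export
at_content <- function(record, interval = NULL) {
  if (is.character(record)) {
    record <- sequence_record("x", record, "linear")
  }
  s <- if (is.null(interval)) record$residues
       else segment_seq(record, interval[1], interval[2])
  n <- nchar(s)
  counts <- vapply(c("A", "C", "G", "T"), function(b) {
    lengths(regmatches(s, gregexpr(b, s, fixed = TRUE)))
  }, numeric(1))
  total <- sum(counts)
  if (total == 0) stop("at_content: no unambiguous bases in effective sequence")
  100 * (counts[["A"]] + counts[["T"]]) / total
}

#' Rotate a circular chromosome to a new origin
#'
#' Shifts the sequence origin by `offset` bases; features are re-mapped (and
#' may gain or lose origin wrap). A rotated chromosome represents the same
#' circular molecule.
#'
#' @param chrom A `chromosome` with circular topology.
#' @param offset New origin, 0-based position on the current sequence.
#' @return Rotated `chromosome`.
#' @export
rotate_chromosome <- function(chrom, offset) {
  rec <- chrom$record
  if (rec$topology != "circular") stop("rotate_chromosome: record is linear")
  len <- nchar(rec$residues)
  offset <- ((offset %% len) + len) %% len
  if (offset == 0) return(chrom)
  newseq <- paste0(substr(rec$residues, offset + 1L, len),
                   substr(rec$residues, 1L, offset))
  shift <- function(p) ((p - offset) %% len + len) %% len
  feats <- lapply(chrom$features, function(f) {
    gene_feature(f$name, f$strand, shift(f$start), shift(f$end), kind = f$kind)
  })
  chromosome(sequence_record(rec$id, newseq, "circular"), feats)
}
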