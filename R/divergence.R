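#' Paired column alignment of a homologous gene
#'
#' Holds one pairwise alignment as two equal-length gapped strings. Invariants:
#' no column may be gap-gap, and removing gaps reconstructs the two input
#' sequences.
#'
#' @param gene Gene token.
#' @param a,b Gapped strings of equal length (gap character `-`).
#' @param kind Feature kind (`"PCG"`, `"tRNA"`, `"rRNA"`, `"control"`,
#'   `"noncoding"`).
#' @return Object of class `homolog_alignment`.
#' @export
homolog_alignment <- function(gene, a, b, kind = "PCG") {
  if (nchar(a) != nchar(b)) {
    stop("homolog_alignment: rows differ in length")
  }
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (any(ca == "-" & cb == "-")) {
    stop("homolog_alignment: gap-gap column")
  }
  structure(list(gene = gene, a = a, b = b, kind = kind),
            class = "homolog_alignment")
}

#' Trim non-overlapping tRNA alignment termini
#'
#' Terminal columns belonging to leading or trailing gap runs (overhangs where
#' one sequence extends past the other) are removed before scoring tRNA
#' divergence; interior columns are untouched. Non-tRNA alignments are
#' returned unchanged with a warning.
#'
#' @param aln A `homolog_alignment` with `kind == "tRNA"`.
#' @return Trimmed `homolog_alignment`.
#' @export
trim_trna_termini <- function(aln) {
  if (!identical(aln$kind, "tRNA")) {
    warning("trim_trna_termini: non-tRNA alignment left unchanged")
    return(aln)
  }
  ca <- strsplit(aln$a, "")[[1]]
  cb <- strsplit(aln$b, "")[[1]]
  gapped <- ca == "-" | cb == "-"
  n <- length(gapped)
  from <- 1L
  while (from <= n && gapped[from]) from <- from + 1L
  to <- n
  while (to >= from && gapped[to]) to <- to - 1L
  if (from > to) stop("trim_trna_termini: alignment has no overlapping core")
  homolog_alignment(aln$gene,
                    paste(ca[from:to], collapse = ""),
                    paste(cb[from:to], collapse = ""),
                    kind = aln$kind)
}

#' Divergence of one homolog alignment
#'
#' Implements the counting rule used for the cryptic-species comparison:
#' every mismatch column is one difference and every maximal gap run (indel)
#' is one difference regardless of its length. The denominator is the number
#' of effective columns: total columns minus gap columns plus one per indel
#' event, so that a k-base indel contributes exactly one difference over one
#' effective column and the percentage is stable under indel length.
#'
#' @param aln A `homolog_alignment` (tRNAs should be pre-trimmed with
#'   [trim_trna_termini()]).
#' @return A `divergence_result` with fields `gene`, `kind`, `substitutions`,
#'   `indel_events`, `effective_columns`, `percent`.
#' @export
homolog_divergence <- function(aln) {
  ca <- strsplit(aln$a, "")[[1]]
  cb <- strsplit(aln$b, "")[[1]]
  gapped <- ca == "-" | cb == "-"
  subs <- sum(!gapped & ca != cb)
  runs <- count_runs(gapped)
  eff <- length(ca) - runs$total + runs$n_runs
  if (eff == 0) stop("homolog_divergence: zero effective columns")
  divergence_result(aln$gene, aln$kind, subs, runs$n_runs, eff)
}

#' @rdname homolog_divergence
#' @param gene,kind Homolog identity.
#' @param substitutions,indel_events,effective_columns Integer counts.
#' @export
divergence_result <- function(gene, kind, substitutions, indel_events,
                              effective_columns) {
  percent <- 100 * (substitutions + indel_events) / effective_columns
  stopifnot(percent >= 0, percent <= 100)
  structure(list(gene = gene, kind = kind,
                 substitutions = as.integer(substitutions),
                 indel_events = as.integer(indel_events),
                 effective_columns = as.integer(effective_columns),
                 percent = percent),
            class = "divergence_result")
}

#' Aggregate divergence over homologs
#'
#' `pooled` (the default) divides total differences by total effective
#' columns, weighting each homolog by its aligned length; `mean` is the
#' unweighted average of the per-homolog percentages.
#'
#' @param results List of `divergence_result`s.
#' @param mode `"pooled"` or `"mean"`.
#' @return Percent divergence.
#' @export
aggregate_divergence <- function(results, mode = c("pooled", "mean")) {
  mode <- match.arg(mode)
  if (!length(results)) stop("aggregate_divergence: empty result list")
  if (mode == "mean") {
    return(mean(vapply(results, `[[`, numeric(1), "percent")))
  }
  diffs <- vapply(results, function(r) r$substitutions + r$indel_events,
                  numeric(1))
  eff <- vapply(results, `[[`, integer(1), "effective_columns")
  100 * sum(diffs) / sum(eff)
}

#' Divergence between paralogous copies of a feature
#'
#' For features duplicated within one genome (e.g. the control region and
#' trnS1 carried by both chromosomes of a bipartite genome), aligns the two
#' copies and applies the homolog divergence statistic. When copies sit on
#' different chromosomes, the two from different chromosomes are compared
#' (larger chromosome's copy first).
#'
#' @param genome A `mito_genome`.
#' @param feature Feature token occurring >= 2 times.
#' @param scoring An [align_scoring()].
#' @return A `divergence_result`.
#' @export
paralog_divergence <- function(genome, feature, scoring = align_scoring()) {
  hits <- list()
  for (ch in genome$chromosomes) {
    for (f in ch$features) {
      if (f$name == feature) hits[[length(hits) + 1L]] <- list(ch = ch, f = f)
    }
  }
  if (length(hits) < 2L) {
    stop("paralog_divergence: feature '", feature,
         "' has fewer than two copies")
  }
  sizes <- vapply(hits, function(h) nchar(h$ch$record$residues), numeric(1))
  ord <- order(-sizes)
  hits <- hits[ord]
  kind <- hits[[1]]$f$kind
  aln <- align_homologs(feature_seq(hits[[1]]$ch, hits[[1]]$f),
                        feature_seq(hits[[2]]$ch, hits[[2]]$f),
                        kind = kind, gene = feature, scoring = scoring)
  if (identical(kind, "tRNA")) aln <- trim_trna_termini(aln)
  homolog_divergence(aln)
}

#' Divergence of one named homolog between two genomes
#'
#' Extracts the homolog (preferring the copy on the largest chromosome when
#' duplicated), aligns, trims tRNA termini, and applies the divergence
#' statistic.
#'
#' @param a,b `mito_genome`s.
#' @param gene Gene token present in both.
#' @param scoring An [align_scoring()].
#' @return A `divergence_result`.
#' @export
gene_divergence <- function(a, b, gene, scoring = align_scoring()) {
  sa <- primary_copy_seq(a, gene)
  sb <- primary_copy_seq(b, gene)
  if (is.null(sa) || is.null(sb)) {
    stop("gene_divergence: '", gene, "' absent from ",
         if (is.null(sa)) a$label else b$label)
  }
  kind <- gene_kind(gene)
  aln <- align_homologs(sa, sb, kind = kind, gene = gene, scoring = scoring)
  if (identical(kind, "tRNA")) aln <- trim_trna_termini(aln)
  homolog_divergence(aln)
}

# Sequence of a gene's primary copy: the one on the largest chromosome.
primary_copy_seq <- function(genome, gene) {
  best <- NULL; best_size <- -1
  for (ch in genome$chromosomes) {
    size <- nchar(ch$record$residues)
    for (f in ch$features) {
      if (f$name == gene && size > best_size) {
        best <- list(ch = ch, f = f); best_size <- size
      }
    }
  }
  if (is.null(best)) NULL else feature_seq(best$ch, best$f)
}
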