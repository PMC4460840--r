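#' Full comparison of two annotated mitogenomes
#'
#' Assembles the comparison-table view of two genomes: one row per canonical
#' homolog (37 genes plus the control region) in the anchor-linearized order
#' of genome A, with strands in both genomes and percent divergence under the
#' indel-collapse statistic; noncoding features are matched by best alignment
#' identity and marked non-homologous below the identity floor rather than
#' scored. Aggregates (all homologs and protein-coding only, both pooled and
#' mean), the classified rearrangement events, a paralog section for
#' duplicated features, per-chromosome A+T contents and a chromosome
#' inventory complete the report.
#'
#' @param a,b `mito_genome`s passing the completeness check.
#' @param anchor Anchor gene for linearization.
#' @param scoring An [align_scoring()].
#' @param identity_floor Percent alignment identity below which noncoding
#'   features are declared non-homologous (default 50).
#' @return Object of class `comparison_report`: list with `homologs`,
#'   `aggregates`, `events`, `paralogs`, `at_table`, `inventory`, `labels`.
#' @export
compare_genomes <- function(a, b, anchor = "cox1",
                            scoring = align_scoring(),
                            identity_floor = 50) {
  for (g in list(a, b)) {
    cp <- genome_completeness(g)
    if (!cp$complete) {
      stop("compare_genomes: genome '", g$label, "' missing: ",
           paste(cp$missing, collapse = ", "))
    }
  }
  order_a <- extract_order(a, anchor = anchor, include_noncoding = TRUE)
  order_a_red <- reduce_paralogs(order_a)

  rows <- list()
  results <- list()
  seen <- character(0)
  for (ch in order_a_red$chromosomes) {
    for (i in seq_along(ch$genes)) {
      g <- ch$genes[i]
      if (g %in% seen) next
      seen <- c(seen, g)
      strand_a <- if (ch$signs[i] > 0) "J" else "N"
      if (gene_kind(g) == "noncoding") {
        m <- match_noncoding(a, b, g, scoring)
        matched <- m$identity >= identity_floor
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, kind = "noncoding", strand_a = strand_a,
          gene_b = if (matched) m$name else "",
          strand_b = if (matched) m$strand else "",
          percent = NA_real_,
          note = if (matched) "homologous" else "Non-homologous",
          stringsAsFactors = FALSE)
        next
      }
      strand_b <- gene_strand(b, g) %||% ""
      res <- gene_divergence(a, b, g, scoring = scoring)
      results[[g]] <- res
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, kind = res$kind, strand_a = strand_a, gene_b = g,
        strand_b = strand_b, percent = res$percent, note = "",
        stringsAsFactors = FALSE)
    }
  }
  # noncoding features of B with no counterpart among A's rows
  fb <- genome_features(b)
  for (nb in fb$name[fb$kind == "noncoding"]) {
    if (nb %in% unlist(lapply(rows, `[[`, "gene_b"))) next
    m <- match_noncoding(b, a, nb, scoring)
    if (m$identity < identity_floor) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = nb, kind = "noncoding", strand_a = "",
        gene_b = nb, strand_b = fb$strand[fb$name == nb][1],
        percent = NA_real_, note = "Non-homologous", stringsAsFactors = FALSE)
    }
  }
  homologs <- do.call(rbind, rows)
  scored <- results[!vapply(results, is.null, logical(1))]
  pcg <- scored[vapply(scored, function(r) r$kind == "PCG", logical(1))]
  aggregates <- data.frame(
    set = c("all_homologs", "all_homologs", "pcg", "pcg"),
    mode = c("pooled", "mean", "pooled", "mean"),
    percent = c(aggregate_divergence(scored, "pooled"),
                aggregate_divergence(scored, "mean"),
                aggregate_divergence(pcg, "pooled"),
                aggregate_divergence(pcg, "mean")),
    stringsAsFactors = FALSE)

  events <- classify_events(extract_order(a, anchor = anchor),
                            extract_order(b, anchor = anchor))

  paralogs <- list()
  for (g in list(a, b)) {
    counts <- table(genome_features(g)$name)
    for (f in names(counts)[counts > 1L]) {
      pd <- paralog_divergence(g, f, scoring = scoring)
      paralogs[[length(paralogs) + 1L]] <- data.frame(
        genome = g$label, feature = f, percent = pd$percent,
        stringsAsFactors = FALSE)
    }
  }
  paralogs <- if (length(paralogs)) do.call(rbind, paralogs)
              else data.frame(genome = character(0), feature = character(0),
                              percent = numeric(0), stringsAsFactors = FALSE)

  at_table <- do.call(rbind, lapply(list(a, b), function(g) {
    rows <- lapply(g$chromosomes, function(ch) {
      data.frame(genome = g$label, chromosome = ch$record$id,
                 at_percent = at_content(ch$record), stringsAsFactors = FALSE)
    })
    whole <- sequence_record("all", paste(vapply(g$chromosomes, function(ch) {
      ch$record$residues
    }, character(1)), collapse = ""))
    rbind(do.call(rbind, rows),
          data.frame(genome = g$label, chromosome = "(genome)",
                     at_percent = at_content(whole), stringsAsFactors = FALSE))
  }))

  inventory <- do.call(rbind, lapply(list(a, b), function(g) {
    do.call(rbind, lapply(g$chromosomes, function(ch) {
      data.frame(genome = g$label, chromosome = ch$record$id,
                 length_bp = nchar(ch$record$residues),
                 topology = ch$record$topology,
                 n_features = length(ch$features), stringsAsFactors = FALSE)
    }))
  }))

  structure(list(labels = c(a = a$label, b = b$label), homologs = homologs,
                 aggregates = aggregates, events = events,
                 paralogs = paralogs, at_table = at_table,
                 inventory = inventory),
            class = "comparison_report")
}

gene_strand <- function(genome, gene) {
  feats <- genome_features(genome)
  hit <- feats[feats$name == gene, , drop = FALSE]
  if (!nrow(hit)) return(NULL)
  hit$strand[1]
}

# Best alignment identity of a noncoding feature of A against any noncoding
# feature of B (percent of alignment columns that match).
match_noncoding <- function(a, b, name, scoring) {
  fa <- genome_features(a)
  row <- fa[fa$name == name, , drop = FALSE][1, ]
  cha <- Filter(function(ch) ch$record$id == row$chromosome, a$chromosomes)[[1]]
  fobj <- Filter(function(f) f$name == name, cha$features)[[1]]
  seq_a <- feature_seq(cha, fobj)
  best <- list(identity = 0, name = NULL, strand = NULL)
  for (ch in b$chromosomes) {
    for (f in ch$features) {
      if (f$kind != "noncoding") next
      aln <- align_homologs(seq_a, feature_seq(ch, f), kind = "noncoding",
                            gene = name, scoring = scoring)
      ca <- strsplit(aln$a, "")[[1]]
      cb <- strsplit(aln$b, "")[[1]]
      ident <- 100 * sum(ca == cb & ca != "-") / length(ca)
      if (ident > best$identity) {
        best <- list(identity = ident, name = f$name, strand = f$strand)
      }
    }
  }
  best
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Comparison of", x$labels["a"], "vs", x$labels["b"], "\n")
  scored <- x$homologs[!is.na(x$homologs$percent), ]
  cat(" ", nrow(scored), "scored homologs;",
      sum(x$homologs$note == "Non-homologous"), "non-homologous regions\n")
  for (i in seq_len(nrow(x$aggregates))) {
    cat(sprintf("  %s (%s): %.2f%%\n", x$aggregates$set[i],
                x$aggregates$mode[i], x$aggregates$percent[i]))
  }
  cat("  events:\n")
  for (ev in x$events) { cat("   - "); print(ev) }
  invisible(x)
}

#' Write a comparison report as TSV (plus JSON events)
#'
#' `write_report_tsv()` writes the per-homolog table with aggregate rows
#' appended in a byte-stable column order; `write_events_json()` serializes
#' the event list.
#'
#' @param report A `comparison_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  h <- report$homologs
  h$percent <- ifelse(is.na(h$percent), h$note, sprintf("%.2f", h$percent))
  out <- h[, c("gene", "strand_a", "strand_b", "percent")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", paste0("strand_", report$labels["a"]),
                     paste0("strand_", report$labels["b"]), "percent"),
                   collapse = "\t"), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  for (i in seq_len(nrow(report$aggregates))) {
    writeLines(sprintf("# %s_%s\t\t\t%.2f", report$aggregates$set[i],
                       report$aggregates$mode[i],
                       report$aggregates$percent[i]), con)
  }
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
write_events_json <- function(report, path) {
  evs <- lapply(report$events, function(ev) {
    list(kind = ev$kind, genes = ev$genes,
         duplicated = ev$evidence$duplicated %||% character(0))
  })
  jsonlite::write_json(evs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
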