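#' Signed gene orders and adjacency algebra
#'
#' A `gene_order` is the currency of rearrangement analysis: for each
#' chromosome, an ordered vector of gene tokens with signs (+1 = J
#' majority-coding strand, -1 = N minority-coding strand), linearized from the
#' circular molecule at an anchor gene.
#'
#' @param chromosomes List of `list(id =, genes =, signs =)` entries, one per
#'   chromosome; `genes` a character vector, `signs` +1/-1 of equal length.
#' @return Object of class `gene_order`.
#' @export
gene_order <- function(chromosomes) {
  for (ch in chromosomes) {
    stopifnot(is.character(ch$genes), length(ch$genes) >= 1L,
              length(ch$signs) == length(ch$genes),
              all(ch$signs %in% c(-1L, 1L)))
  }
  structure(list(chromosomes = chromosomes), class = "gene_order")
}

#' @rdname gene_order
#' @param tokens Character vector of signed tokens, e.g.
#'   `c("cox1", "-trnF", "nad2")`; a leading `-` marks the N strand.
#' @param id Chromosome identifier.
#' @export
order_from_tokens <- function(tokens, id = "chr") {
  signs <- ifelse(startsWith(tokens, "-"), -1L, 1L)
  genes <- sub("^[+-]", "", tokens)
  gene_order(list(list(id = id, genes = genes, signs = signs)))
}

order_genes <- function(order) {
  unlist(lapply(order$chromosomes, `[[`, "genes"))
}

#' @export
print.gene_order <- function(x, ...) {
  for (ch in x$chromosomes) {
    toks <- paste0(ifelse(ch$signs < 0, "-", ""), ch$genes)
    cat(ch$id, ": ", paste(toks, collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

flip_circle <- function(ch) {
  list(id = ch$id, genes = rev(ch$genes), signs = rev(-ch$signs))
}

rotate_circle <- function(ch, idx) {
  n <- length(ch$genes)
  if (idx == 1L) return(ch)
  ord <- c(idx:n, seq_len(idx - 1L))
  list(id = ch$id, genes = ch$genes[ord], signs = ch$signs[ord])
}

normalize_circle <- function(ch, anchor) {
  target <- if (anchor %in% ch$genes) anchor else sort(ch$genes)[1]
  idx <- match(target, ch$genes)
  if (ch$signs[idx] < 0) {
    ch <- flip_circle(ch)
    idx <- match(target, ch$genes)
  }
  rotate_circle(ch, idx)
}

#' Extract the anchored, signed gene order of a genome
#'
#' Each circular chromosome is rotated so the anchor gene (default cox1, the
#' conventional start of mitogenome linearizations) comes first with + sign,
#' flipping the whole chromosome when the anchor lies on the N strand.
#' Chromosomes lacking the anchor (e.g. a mini-circle) are normalized the same
#' way on their lexicographically smallest gene.
#'
#' @param genome A `mito_genome`.
#' @param anchor Anchor gene token; must be present somewhere in the genome.
#' @param include_noncoding Keep features of kind `noncoding`? Default drops
#'   them (species-specific non-homologous regions are not part of the
#'   canonical order).
#' @return A `gene_order`.
#' @export
extract_order <- function(genome, anchor = "cox1", include_noncoding = FALSE) {
  present <- unlist(lapply(genome$chromosomes, function(ch) {
    vapply(ch$features, `[[`, character(1), "name")
  }))
  if (!anchor %in% present) {
    stop("extract_order: anchor '", anchor, "' absent from genome")
  }
  chroms <- lapply(genome$chromosomes, function(ch) {
    feats <- ch$features
    if (!include_noncoding) {
      feats <- Filter(function(f) f$kind != "noncoding", feats)
    }
    if (!length(feats)) return(NULL)
    entry <- list(
      id = ch$record$id,
      genes = vapply(feats, `[[`, character(1), "name"),
      signs = ifelse(vapply(feats, `[[`, character(1), "strand") == "J",
                     1L, -1L)
    )
    if (ch$record$topology == "circular") normalize_circle(entry, anchor)
    else entry
  })
  gene_order(Filter(Negate(is.null), chroms))
}

# Reduce paralogs to their home chromosome: a duplicated gene keeps only the
# copy on the chromosome carrying the most genes (the copy embedded in the
# larger conserved context); within-chromosome duplicates keep the first.
reduce_paralogs <- function(order) {
  sizes <- vapply(order$chromosomes, function(ch) length(ch$genes), integer(1))
  home_rank <- order(-sizes)
  counts <- table(order_genes(order))
  dups <- names(counts)[counts > 1L]
  if (!length(dups)) return(order)
  seen <- character(0)
  chroms <- list()
  for (i in home_rank) {
    ch <- order$chromosomes[[i]]
    keep <- !(ch$genes %in% dups & (ch$genes %in% seen |
                                      duplicated(ch$genes)))
    seen <- c(seen, intersect(unique(ch$genes), dups))
    if (any(keep)) {
      chroms[[length(chroms) + 1L]] <-
        list(id = ch$id, genes = ch$genes[keep], signs = ch$signs[keep],
             pos = i)
    }
  }
  chroms <- chroms[order(vapply(chroms, `[[`, integer(1), "pos"))]
  gene_order(lapply(chroms, function(ch) ch[c("id", "genes", "signs")]))
}

adjacency_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

oriented_key <- function(a, sa, b, sb) {
  fwd <- paste0(ifelse(sa < 0, "-", "+"), a, ">", ifelse(sb < 0, "-", "+"), b)
  rev <- paste0(ifelse(sb < 0, "+", "-"), b, ">", ifelse(sa < 0, "+", "-"), a)
  min(fwd, rev)
}

#' Adjacency (gene-boundary) set of a gene order
#'
#' Each circular chromosome of n (paralog-reduced) genes contributes its n
#' gene boundaries, with the circular closure included. Strand-blind
#' adjacencies ignore orientation (used for shared-boundary/block analysis);
#' oriented adjacencies retain signs and are invariant under reading
#' direction. Paralogous duplicates are first reduced to their home
#' chromosome so a recently duplicated feature (e.g. a mini-circle's control
#' region copy) does not fabricate breakpoints.
#'
#' @param order A `gene_order`.
#' @param oriented Retain signs?
#' @return Character vector of unique adjacency keys.
#' @export
adjacency_set <- function(order, oriented = FALSE) {
  order <- reduce_paralogs(order)
  keys <- character(0)
  for (ch in order$chromosomes) {
    n <- length(ch$genes)
    if (n < 2L) next
    nxt <- c(2:n, 1L)
    for (i in seq_len(n)) {
      j <- nxt[i]
      keys <- c(keys,
                if (oriented) {
                  oriented_key(ch$genes[i], ch$signs[i],
                               ch$genes[j], ch$signs[j])
                } else {
                  adjacency_key(ch$genes[i], ch$genes[j])
                })
    }
  }
  unique(keys)
}

adjacency_partners <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- list()
  for (p in parts) {
    out[[p[1]]] <- c(out[[p[1]]], p[2])
    out[[p[2]]] <- c(out[[p[2]]], p[1])
  }
  lapply(out, unique)
}

remove_genes_from_order <- function(order, genes) {
  chroms <- list()
  for (ch in order$chromosomes) {
    keep <- !(ch$genes %in% genes)
    if (any(keep)) {
      chroms[[length(chroms) + 1L]] <-
        list(id = ch$id, genes = ch$genes[keep], signs = ch$signs[keep])
    }
  }
  gene_order(chroms)
}

sign_of <- function(order, gene) {
  for (ch in order$chromosomes) {
    i <- match(gene, ch$genes)
    if (!is.na(i)) return(ch$signs[i])
  }
  NA_integer_
}
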