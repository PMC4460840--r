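#' Rearrangement event
#'
#' One inferred evolutionary event separating two gene orders: an inversion
#' (gene in place, strand flipped), a translocation (gene or contiguous run
#' moved), a fragmentation (fission of genes onto a separate chromosome), or a
#' duplication (feature present more than once in one genome, reported as a
#' sub-event of fragmentation when the extra copies ride the new chromosome).
#'
#' @param kind `"inversion"`, `"translocation"`, `"fragmentation"` or
#'   `"duplication"`.
#' @param genes Character vector of gene tokens involved.
#' @param evidence Optional list (e.g. adjacencies gained/lost, duplicated
#'   features).
#' @return Object of class `rearrangement_event`.
#' @export
rearrangement_event <- function(kind, genes, evidence = list()) {
  stopifnot(kind %in% c("inversion", "translocation", "fragmentation",
                        "duplication"))
  structure(list(kind = kind, genes = sort(genes), evidence = evidence),
            class = "rearrangement_event")
}

#' @export
print.rearrangement_event <- function(x, ...) {
  cat(x$kind, "(", paste(x$genes, collapse = ", "), ")", sep = "")
  if (!is.null(x$evidence$duplicated) && length(x$evidence$duplicated)) {
    cat(" + duplication(", paste(x$evidence$duplicated, collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Classify rearrangement events between two gene orders
#'
#' Infers the minimal set of events in the restricted taxonomy appropriate to
#' highly rearranged insect mitogenomes:
#'
#' * **inversion** — a gene whose two strand-blind gene boundaries are
#'   conserved but whose sign differs between the orders;
#' * **fragmentation** — genes residing on a chromosome of one order that is
#'   absent from the other, with features duplicated onto the new chromosome
#'   reported as a duplication sub-event;
#' * **translocation** — a gene (or contiguous run) whose removal from both
#'   orders makes the remaining strand-blind adjacency sets equal.
#'
#' Inversions are preferred, then fewest moved genes, with alphabetical
#' tie-breaking. Both orders must cover the same gene set (paralogous extra
#' copies aside); an orphan gene in only one order is an error.
#'
#' @param orderA,orderB `gene_order`s (anchor-normalized as by
#'   [extract_order()]).
#' @return List of `rearrangement_event`s (empty when the orders agree).
#' @export
classify_events <- function(orderA, orderB) {
  gA <- order_genes(orderA); gB <- order_genes(orderB)
  orphans <- c(setdiff(gA, gB), setdiff(gB, gA))
  if (length(orphans)) {
    stop("classify_events: gene(s) present in only one order: ",
         paste(sort(unique(orphans)), collapse = ", "))
  }
  events <- list()

  # duplications: copy-number gains in either direction
  cA <- table(gA); cB <- table(gB)
  genes_all <- sort(unique(c(gA, gB)))
  nA <- as.integer(cA[genes_all]); nA[is.na(nA)] <- 0L
  nB <- as.integer(cB[genes_all]); nB[is.na(nB)] <- 0L
  dup_genes <- genes_all[nA != nB]
  dup_dir <- ifelse(nB[nA != nB] > nA[nA != nB], "B", "A")

  redA <- reduce_paralogs(orderA)
  redB <- reduce_paralogs(orderB)

  # fragmentation: chromosomes of the fissioned order with no counterpart
  frag_moved <- character(0)
  if (length(redA$chromosomes) != length(redB$chromosomes)) {
    direction <- if (length(redB$chromosomes) > length(redA$chromosomes)) "B"
                 else "A"
    more <- if (direction == "B") redB else redA
    # the main chromosomes pair up by shared gene content; extras are fission
    # products
    sizes <- vapply(more$chromosomes, function(ch) length(ch$genes),
                    integer(1))
    n_keep <- min(length(redA$chromosomes), length(redB$chromosomes))
    extra_idx <- order(-sizes)[-seq_len(n_keep)]
    for (i in extra_idx) {
      moved <- more$chromosomes[[i]]$genes
      frag_moved <- c(frag_moved, moved)
      events[[length(events) + 1L]] <- rearrangement_event(
        "fragmentation", moved,
        evidence = list(duplicated = dup_genes, direction = direction,
                        chromosome = more$chromosomes[[i]]$id))
    }
  } else if (length(dup_genes)) {
    events[[length(events) + 1L]] <- rearrangement_event(
      "duplication", dup_genes, evidence = list(direction = dup_dir))
  }

  # compare the remaining (shared) chromosome content
  redA <- remove_genes_from_order(redA, frag_moved)
  redB <- remove_genes_from_order(redB, frag_moved)

  adjA <- adjacency_set(redA); adjB <- adjacency_set(redB)

  # translocations: greedy removal minimizing the residual adjacency
  # symmetric difference; ties broken alphabetically
  workA <- redA; workB <- redB
  moved <- character(0)
  repeat {
    sa <- adjacency_set(workA); sb <- adjacency_set(workB)
    d <- union(setdiff(sa, sb), setdiff(sb, sa))
    if (!length(d)) break
    cands <- sort(unique(unlist(strsplit(d, "|", fixed = TRUE))))
    resid <- function(genes) {
      saa <- adjacency_set(remove_genes_from_order(workA, genes))
      sbb <- adjacency_set(remove_genes_from_order(workB, genes))
      length(union(setdiff(saa, sbb), setdiff(sbb, saa)))
    }
    best <- NULL; best_d <- length(d)
    for (g in cands) {
      dd <- resid(g)
      if (dd < best_d) { best <- g; best_d <- dd }
    }
    if (is.null(best) && length(cands) >= 2L) {
      # two genes that exchanged places leave no single removal productive;
      # try candidate pairs before giving up
      pairs <- utils::combn(cands, 2L, simplify = FALSE)
      for (p in pairs) {
        dd <- resid(p)
        if (dd < best_d) { best <- p; best_d <- dd }
      }
    }
    if (is.null(best)) {
      warning("classify_events: unresolved adjacency differences: ",
              paste(d, collapse = ", "))
      break
    }
    moved <- c(moved, best)
    workA <- remove_genes_from_order(workA, best)
    workB <- remove_genes_from_order(workB, best)
  }

  # inversions: once translocated genes are set aside the residual orders
  # share every strand-blind boundary, so a gene in place with a flipped
  # sign is an inversion (both its boundaries are conserved)
  for (g in sort(intersect(order_genes(workA), order_genes(workB)))) {
    sA <- sign_of(workA, g); sB <- sign_of(workB, g)
    if (!is.na(sA) && !is.na(sB) && sA != sB) {
      events[[length(events) + 1L]] <- rearrangement_event(
        "inversion", g,
        evidence = list(from = if (sA > 0) "J" else "N",
                        to = if (sB > 0) "J" else "N"))
    }
  }

  events <- c(events, merge_translocation_runs(moved, adjA, adjB))
  events
}

# Translocated genes that were adjacent in both source orders moved as one
# contiguous run and are reported as a single event.
merge_translocation_runs <- function(moved, adjA, adjB) {
  if (!length(moved)) return(list())
  conserved <- intersect(adjA, adjB)
  runs <- as.list(moved)
  merged <- TRUE
  while (merged && length(runs) > 1L) {
    merged <- FALSE
    for (i in seq_along(runs)) {
      for (j in seq_along(runs)) {
        if (i == j) next
        key_mat <- outer(runs[[i]], runs[[j]], Vectorize(adjacency_key))
        if (any(key_mat %in% conserved)) {
          runs[[i]] <- c(runs[[i]], runs[[j]])
          runs[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
  }
  lapply(runs, function(g) rearrangement_event("translocation", g))
}

#' Maximal shared gene blocks across gene orders
#'
#' A shared block is a maximal run of genes whose strand-blind gene
#' boundaries are conserved in every order supplied (orientation is
#' deliberately ignored: a gene inverted in one lineage still shares its
#' boundaries). Blocks are read along the first order's chromosomes.
#'
#' @param orders List of >= 2 `gene_order`s.
#' @return List of `list(genes, size)`, largest first.
#' @export
shared_blocks <- function(orders) {
  if (length(orders) < 2L) stop("shared_blocks: need at least two orders")
  adjsets <- lapply(orders, adjacency_set, oriented = FALSE)
  conserved <- Reduce(intersect, adjsets)
  common <- Reduce(intersect, lapply(orders, order_genes))
  first <- reduce_paralogs(orders[[1]])
  blocks <- list()
  for (ch in first$chromosomes) {
    n <- length(ch$genes)
    if (n == 0L) next
    if (n == 1L) {
      blocks[[length(blocks) + 1L]] <- list(genes = ch$genes, size = 1L)
      next
    }
    nxt <- c(2:n, 1L)
    ok <- vapply(seq_len(n), function(i) {
      g1 <- ch$genes[i]; g2 <- ch$genes[nxt[i]]
      g1 %in% common && g2 %in% common &&
        adjacency_key(g1, g2) %in% conserved
    }, logical(1))
    if (all(ok)) {
      blocks[[length(blocks) + 1L]] <- list(genes = ch$genes, size = n)
      next
    }
    # walk the circle starting just after a broken boundary
    start <- (which(!ok)[1] %% n) + 1L
    idx <- ((start - 1L + 0:(n - 1L)) %% n) + 1L
    run <- character(0)
    for (k in seq_len(n)) {
      i <- idx[k]
      run <- c(run, ch$genes[i])
      if (!ok[i]) { # boundary after gene i is broken: close the run
        if (length(run) && any(ch$genes[idx[seq_len(k)]] %in% common)) {
          blocks[[length(blocks) + 1L]] <-
            list(genes = run, size = length(run))
        }
        run <- character(0)
      }
    }
    if (length(run)) {
      blocks[[length(blocks) + 1L]] <- list(genes = run, size = length(run))
    }
  }
  blocks[order(-vapply(blocks, `[[`, integer(1), "size"))]
}
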