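# Small fixtures built in code.

# Three-gene circular toy genome with explicit sequences.
toy_genome <- function(label = "toy") {
  seqs <- c(cox1 = strrep("ACGTTA", 20), trnW = strrep("TTAGCA", 11),
            nad2 = strrep("GATTAC", 30))
  strands <- c(cox1 = "J", trnW = "J", nad2 = "N")
  segs <- vapply(names(seqs), function(g) {
    if (strands[[g]] == "N") mitofrag::revcomp(seqs[[g]]) else seqs[[g]]
  }, character(1))
  ends <- cumsum(nchar(segs))
  starts <- ends - nchar(segs)
  feats <- lapply(seq_along(segs), function(i) {
    gene_feature(names(seqs)[i], strands[[i]], starts[i], ends[i])
  })
  mito_genome(label, chromosome(
    sequence_record(paste0(label, "_chr"), paste(segs, collapse = ""),
                    "circular"), feats))
}

# Default study-like synthetic pair, cached per session for speed.
study_pair_fixture <- local({
  cache <- NULL
  function(seed = 101) {
    if (is.null(cache)) cache <<- simulate_study_pair(seed = seed)
    cache
  }
})

default_ancestor <- local({
  cache <- NULL
  function(seed = 11) {
    if (is.null(cache)) {
      cache <<- generate_ancestor(generator_config(seed = seed))
    }
    cache
  }
})

# Random non-overlapping planted events on the thrips template: genes and
# landing sites are kept apart (including their template neighbourhoods) so
# every planted event is independently recoverable.
random_planted_events <- function(n_ev,
                                  template =
                                    thrips_order_template()$chromosomes[[1]]$genes,
                                  movable = setdiff(trna_genes(), "trnC")) {
  n <- length(template)
  nb <- function(x, dist = 1L) {
    i <- match(x, template)
    offs <- c(-seq_len(dist), seq_len(dist))
    template[((i - 1L + offs) %% n) + 1L]
  }
  nxt <- function(x) template[(match(x, template) %% n) + 1L]
  blocked <- character(0)
  ev <- list()
  for (k in seq_len(n_ev)) {
    pool <- setdiff(movable, blocked)
    if (!length(pool)) break
    kind <- sample(c("inversion", "translocation"), 1)
    g <- sample(pool, 1)
    if (kind == "translocation") {
      # a hop over a single gene is ambiguous (either gene may have moved),
      # so landing sites within template distance 2 of the source are barred
      land <- setdiff(template, c(blocked, g, nb(g, 2L)))
      land <- Filter(function(x) !(nxt(x) %in% c(blocked, g)), land)
      if (length(land)) {
        after <- sample(land, 1)
        ev[[length(ev) + 1L]] <- list(kind = "translocation", gene = g,
                                      after = after)
        blocked <- c(blocked, g, nb(g), after, nxt(after))
        next
      }
      kind <- "inversion"
    }
    ev[[length(ev) + 1L]] <- list(kind = "inversion", gene = g)
    blocked <- c(blocked, g, nb(g))
  }
  ev
}

# circular neighbors of one or more genes in a token order
neighbors_in <- function(ord, genes) {
  if (!length(genes)) return(character(0))
  n <- length(ord)
  out <- character(0)
  for (g in genes) {
    i <- match(g, ord)
    if (is.na(i)) next
    out <- c(out, ord[((i - 2L) %% n) + 1L], ord[(i %% n) + 1L])
  }
  unique(out)
}

# anchor-normalize a toy token order the way extract_order does
normalize_toy <- function(tokens) {
  genes <- sub("^-", "", tokens)
  signs <- ifelse(startsWith(tokens, "-"), -1L, 1L)
  target <- sort(genes)[1]
  i <- match(target, genes)
  if (signs[i] < 0) {
    genes <- rev(genes); signs <- rev(-signs)
    i <- match(target, genes)
  }
  idx <- ((seq_along(genes) + i - 2L) %% length(genes)) + 1L
  order_from_tokens(paste0(ifelse(signs[idx] < 0, "-", ""), genes[idx]))
}
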