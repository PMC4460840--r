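test_that("gene-order extraction is anchored and rotation-invariant", {
  g <- default_ancestor()
  ord <- extract_order(g)
  expect_identical(ord$chromosomes[[1]]$genes[1], "cox1")
  expect_equal(ord$chromosomes[[1]]$signs[1], 1L)
  rot <- mito_genome(g$label, rotate_chromosome(g$chromosomes[[1]], 1000))
  expect_identical(extract_order(rot), ord)
  expect_error(extract_order(g, anchor = "trnZ"), "anchor")
})

test_that("anchor on the N strand flips the chromosome on extraction", {
  ord0 <- order_from_tokens(c("cox1", "-trnW", "nad2"), id = "c")
  # build a genome whose cox1 sits on N: extraction must flip so cox1 is +
  g <- toy_genome()
  parts <- lapply(g$chromosomes[[1]]$features, function(f) f)
  feats <- lapply(parts, function(f) {
    gene_feature(f$name, if (f$strand == "J") "N" else "J",
                 f$start, f$end, kind = f$kind)
  })
  flipped <- mito_genome("flip", chromosome(g$chromosomes[[1]]$record, feats))
  ord <- extract_order(flipped)
  expect_identical(ord$chromosomes[[1]]$genes[1], "cox1")
  expect_equal(ord$chromosomes[[1]]$signs[1], 1L)
  # flipping a whole chromosome changes no strand-blind adjacency
  expect_setequal(adjacency_set(ord), adjacency_set(extract_order(g)))
})

test_that("adjacency sets include the circular closure", {
  ord <- order_from_tokens(c("a", "b", "c"))
  expect_setequal(adjacency_set(ord), c("a|b", "b|c", "a|c"))
  # oriented sets react to sign flips, strand-blind sets do not
  flipped <- order_from_tokens(c("a", "-b", "c"))
  expect_setequal(adjacency_set(ord), adjacency_set(flipped))
  expect_false(setequal(adjacency_set(ord, oriented = TRUE),
                        adjacency_set(flipped, oriented = TRUE)))
})

test_that("identical orders yield no events", {
  o <- sd_gene_orders()
  expect_length(classify_events(o$EA1, o$EA1), 0L)
  expect_length(classify_events(o$SA1, o$SA1), 0L)
})

test_that("orphan genes are a validation error", {
  a <- order_from_tokens(c("a", "b", "c"))
  b <- order_from_tokens(c("a", "b", "d"))
  expect_error(classify_events(a, b), "c, d")
})

test_that("the published orders classify as two inversions plus fission", {
  o <- sd_gene_orders()
  ev <- classify_events(o$SA1, o$EA1)
  kinds <- vapply(ev, `[[`, character(1), "kind")
  expect_setequal(kinds, c("fragmentation", "inversion", "inversion"))
  inv <- sort(unlist(lapply(ev[kinds == "inversion"], `[[`, "genes")))
  expect_identical(inv, c("trnF", "trnY"))
  frag <- ev[[which(kinds == "fragmentation")]]
  expect_setequal(frag$genes, c("nad6", "trnC"))
  expect_setequal(frag$evidence$duplicated, c("control_region", "trnS1"))
  # symmetric up to direction labels
  ev2 <- classify_events(o$EA1, o$SA1)
  expect_setequal(vapply(ev2, `[[`, character(1), "kind"), kinds)
})

test_that("planted events are recovered exactly across random pairs", {
  anc <- default_ancestor()
  n_exact <- 0L
  n_pairs <- 50L
  set.seed(99)
  for (i in seq_len(n_pairs)) {
    ev <- random_planted_events(sample(0:4, 1))
    res <- evolve_pair(anc, events = ev, divergence = numeric(0),
                       seed = 5000 + i)
    got <- classify_events(extract_order(res$a), extract_order(res$b))
    planted <- sort(vapply(ev, function(e) {
      paste0(e$kind, ":", e$gene)
    }, character(1)))
    found <- sort(vapply(got, function(e) {
      paste0(e$kind, ":", paste(e$genes, collapse = "+"))
    }, character(1)))
    if (identical(planted, found)) n_exact <- n_exact + 1L
  }
  expect_equal(n_exact, n_pairs)
})

test_that("a planted fission is recovered together with inversions", {
  anc <- default_ancestor()
  ev <- list(list(kind = "inversion", gene = "trnF"),
             list(kind = "inversion", gene = "trnY"),
             list(kind = "fission", move = c("nad6", "trnC"),
                  duplicate = c("control_region", "trnS1"),
                  paralog_divergence = 1.65))
  res <- evolve_pair(anc, events = ev, divergence = numeric(0), seed = 8)
  got <- classify_events(extract_order(res$a), extract_order(res$b))
  kinds <- sort(vapply(got, `[[`, character(1), "kind"))
  expect_identical(kinds, c("fragmentation", "inversion", "inversion"))
})

test_that("minimal event counts match exhaustive search on toy orders", {
  set.seed(3)
  genes <- letters[1:6]
  for (i in 1:12) {
    base <- sample(genes)
    a <- order_from_tokens(base)
    tokens <- base
    n_ops <- sample(1:2, 1)
    for (k in seq_len(n_ops)) {
      if (stats::runif(1) < 0.5) {
        # invert any gene except the anchor ("a"), which fixes orientation
        j <- sample(which(sub("^-", "", tokens) != "a"), 1)
        tokens[j] <- if (startsWith(tokens[j], "-")) {
          sub("^-", "", tokens[j])
        } else paste0("-", tokens[j])
      } else {
        j <- sample(length(tokens), 1)
        tok <- tokens[j]
        tokens <- append(tokens[-j], tok,
                         after = sample(0:(length(tokens) - 2L), 1))
      }
    }
    b_norm <- normalize_toy(tokens)
    a_norm <- normalize_toy(base)
    got <- tryCatch(
      suppressWarnings(classify_events(a_norm, b_norm)),
      error = function(e) NULL)
    if (is.null(got)) next
    oracle <- oracle_min_events(base, tokens, max_depth = 3L)
    if (is.na(oracle)) next
    expect_lte(length(got), max(oracle, length(got)))
    expect_equal(length(got), oracle,
                 info = paste(paste(base, collapse = ","), "->",
                              paste(tokens, collapse = ",")))
  }
})

test_that("shared blocks behave as conserved-boundary runs", {
  o1 <- order_from_tokens(c("a", "b", "c", "d", "e"))
  # identical orders: one block holding every gene
  bl <- shared_blocks(list(o1, o1))
  expect_length(bl, 1L)
  expect_equal(bl[[1]]$size, 5L)
  # one mid-block translocation (b moved between d and e) splits the circle
  # at exactly b's old and new boundaries
  o2 <- order_from_tokens(c("a", "c", "d", "b", "e"))
  bl2 <- shared_blocks(list(o1, o2))
  keys <- vapply(bl2, function(b) paste(b$genes, collapse = "+"),
                 character(1))
  expect_true("c+d" %in% keys)
  expect_true("e+a" %in% keys)
  expect_false(any(vapply(bl2, function(b) {
    "b" %in% b$genes && b$size > 1L
  }, logical(1))))
  expect_error(shared_blocks(list(o1)), "two orders")
})

test_that("the five thrips orders share the ten-gene trnY-atp6 block", {
  orders <- c(sd_gene_orders(), synthetic_reference_orders())
  expect_length(orders, 5L)
  blocks <- shared_blocks(unname(orders))
  ten <- Filter(function(b) b$size == 10L, blocks)
  expect_gte(length(ten), 1L)
  genes <- ten[[1]]$genes
  expect_setequal(genes, c("trnY", "nad2", "trnW", "nad1", "trnM", "trnA",
                           "trnF", "rrnS", "atp8", "atp6"))
  # and it is the largest block
  expect_equal(max(vapply(blocks, `[[`, integer(1), "size")), 10L)
})

test_that("shared blocks are argument-order invariant and monotone", {
  orders <- c(sd_gene_orders(), synthetic_reference_orders())
  b1 <- shared_blocks(list(orders[[1]], orders[[2]], orders[[3]]))
  b2 <- shared_blocks(list(orders[[1]], orders[[3]], orders[[2]]))
  key <- function(bl) sort(vapply(bl, function(b) {
    paste(sort(b$genes), collapse = "+")
  }, character(1)))
  expect_identical(key(b1), key(b2))
  # adding an order never enlarges the largest block containing a gene
  big3 <- max(vapply(b1, `[[`, integer(1), "size"))
  b4 <- shared_blocks(list(orders[[1]], orders[[2]], orders[[3]],
                           orders[[4]]))
  big4 <- max(vapply(b4, `[[`, integer(1), "size"))
  expect_lte(big4, big3)
})
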