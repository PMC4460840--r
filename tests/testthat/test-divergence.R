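test_that("alignment score matches exhaustive enumeration on short pairs", {
  sc <- align_scoring()
  # all pairs of 1- and 2-mers, exhaustively
  mers1 <- c("A", "C", "G", "T")
  mers2 <- apply(expand.grid(mers1, mers1), 1, paste, collapse = "")
  short <- c(mers1, mers2)
  for (a in short[seq(1, length(short), by = 3)]) {
    for (b in short) {
      aln <- align_homologs(a, b)
      expect_equal(attr(aln, "score"), oracle_best_score(a, b),
                   info = paste(a, b))
    }
  }
  # random pairs up to 6-mers
  set.seed(42)
  for (i in 1:30) {
    a <- random_dna_str(sample(3:6, 1))
    b <- random_dna_str(sample(3:6, 1))
    aln <- align_homologs(a, b)
    expect_equal(attr(aln, "score"), oracle_best_score(a, b),
                 info = paste(a, b))
    expect_equal(alignment_score(aln), attr(aln, "score"),
                 info = paste(a, b))
  }
})

test_that("a single deletion aligns as one single-column gap run", {
  aln <- align_homologs("ACGT", "AGT")
  gaps <- gregexpr("-", aln$b)[[1]]
  expect_equal(length(gaps[gaps > 0]), 1L)
  d <- homolog_divergence(aln)
  expect_equal(d$indel_events, 1L)
  expect_equal(d$substitutions, 0L)
})

test_that("alignment invariants hold: reconstruction and no gap-gap columns", {
  set.seed(7)
  for (i in 1:20) {
    a <- random_dna_str(sample(20:60, 1))
    b <- mutate_seq(a, 10, n_indels = 2)
    aln <- align_homologs(a, b)
    expect_identical(gsub("-", "", aln$a), a)
    expect_identical(gsub("-", "", aln$b), b)
  }
  expect_error(homolog_alignment("g", "A-C", "C-G"), "gap-gap")
  expect_error(homolog_alignment("g", "AC", "ACG"), "length")
  expect_error(align_homologs("", "ACGT"), "empty")
})

test_that("tRNA terminus trimming removes only terminal overhangs", {
  # 5' overhang of 4 nt in B, identical elsewhere -> 0 percent
  core <- "GGCTAAGGTTAAGCA"
  aln <- homolog_alignment("trnX", paste0("----", core),
                           paste0("ATTA", core), kind = "tRNA")
  trimmed <- trim_trna_termini(aln)
  expect_equal(nchar(trimmed$a), nchar(core))
  expect_equal(homolog_divergence(trimmed)$percent, 0)
  # no terminal gaps -> unchanged
  aln2 <- homolog_alignment("trnX", core, core, kind = "tRNA")
  expect_identical(trim_trna_termini(aln2)$a, core)
  # overhangs at both termini plus one interior mismatch -> only the
  # mismatch is counted
  a3 <- paste0("AAA", core, "---")
  b3 <- paste0("---", sub("C", "G", core), "TTT")
  aln3 <- homolog_alignment("trnX", a3, b3, kind = "tRNA")
  d3 <- homolog_divergence(trim_trna_termini(aln3))
  expect_equal(d3$substitutions, 1L)
  expect_equal(d3$indel_events, 0L)
  expect_equal(d3$effective_columns, nchar(core))
  # non-tRNA input is a warning no-op
  aln4 <- homolog_alignment("cox1", "ACGT", "ACGA", kind = "PCG")
  expect_warning(out <- trim_trna_termini(aln4), "non-tRNA")
  expect_identical(out$a, aln4$a)
})

test_that("divergence statistic collapses indels and matches the oracle", {
  ident <- homolog_alignment("g", strrep("ACGTT", 20), strrep("ACGTT", 20))
  expect_equal(homolog_divergence(ident)$percent, 0)
  # 95 matched columns plus one 5-column gap run: 1 difference over 96
  a <- strrep("A", 95)
  aln <- homolog_alignment("g", paste0(substr(a, 1, 40), "-----",
                                       substr(a, 41, 95)),
                           paste0(substr(a, 1, 40), "CCCCC",
                                  substr(a, 41, 95)))
  d <- homolog_divergence(aln)
  expect_equal(d$substitutions, 0L)
  expect_equal(d$indel_events, 1L)
  expect_equal(d$effective_columns, 96L)
  expect_equal(d$percent, 100 / 96, tolerance = 1e-10)
  # random gapped alignments against the column-walk oracle
  set.seed(13)
  for (i in 1:25) {
    a <- random_dna_str(sample(30:80, 1))
    b <- mutate_seq(a, sample(5:25, 1), n_indels = sample(0:3, 1))
    aln <- align_homologs(a, b)
    d <- homolog_divergence(aln)
    o <- oracle_divergence(aln$a, aln$b)
    expect_equal(d$substitutions, o$substitutions)
    expect_equal(d$indel_events, o$indels)
    expect_equal(d$effective_columns, o$effective)
    expect_equal(d$percent, o$percent)
  }
})

test_that("divergence is symmetric in its arguments", {
  set.seed(21)
  for (i in 1:10) {
    a <- random_dna_str(sample(40:90, 1))
    b <- mutate_seq(a, 15, n_indels = 2)
    d_ab <- homolog_divergence(align_homologs(a, b))
    d_ba <- homolog_divergence(align_homologs(b, a))
    expect_equal(d_ab$percent, d_ba$percent, tolerance = 1e-10)
    expect_equal(d_ab$substitutions + d_ab$indel_events,
                 d_ba$substitutions + d_ba$indel_events)
  }
})

test_that("percent depends on indel length only through the denominator", {
  base <- strrep("ACGTT", 10)
  for (k in c(1, 3, 7)) {
    aln <- homolog_alignment("g", paste0(base, strrep("-", k), base),
                             paste0(base, strrep("G", k), base))
    d <- homolog_divergence(aln)
    expect_equal(d$substitutions + d$indel_events, 1L)
    expect_equal(d$effective_columns, 100L + 1L)
  }
})

test_that("aggregate divergence computes pooled and mean modes", {
  r0 <- list(divergence_result("a", "PCG", 0, 0, 100),
             divergence_result("b", "tRNA", 0, 0, 60))
  expect_equal(aggregate_divergence(r0, "pooled"), 0)
  expect_equal(aggregate_divergence(r0, "mean"), 0)
  r1 <- list(divergence_result("a", "PCG", 1, 0, 100),
             divergence_result("b", "PCG", 3, 0, 100))
  expect_equal(aggregate_divergence(r1, "pooled"), 2)
  expect_equal(aggregate_divergence(r1, "mean"), 2)
  r2 <- list(divergence_result("a", "PCG", 1, 0, 50),
             divergence_result("b", "PCG", 9, 0, 150))
  expect_equal(aggregate_divergence(r2, "pooled"), 5)
  expect_equal(aggregate_divergence(r2, "mean"), 4)
  expect_error(aggregate_divergence(list()), "empty")
})

test_that("paralog divergence compares duplicated features within a genome", {
  anc <- default_ancestor()
  g0 <- fission_minicircle(anc, move = c("trnC", "nad6"),
                           duplicate = c("trnS1", "control_region"),
                           paralog_divergence = 0, seed = 3)
  expect_equal(paralog_divergence(g0, "trnS1")$percent, 0)
  expect_equal(paralog_divergence(g0, "control_region")$percent, 0)
  expect_error(paralog_divergence(g0, "cox1"), "fewer than two")
  g2 <- fission_minicircle(anc, move = c("trnC", "nad6"),
                           duplicate = c("trnS1", "control_region"),
                           paralog_divergence = 2, seed = 4)
  pd <- paralog_divergence(g2, "control_region")
  expect_lt(abs(pd$percent - 2), 0.5)
})
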