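test_that("the generator is deterministic under a fixed seed", {
  cfg <- generator_config(seed = 31)
  g1 <- generate_ancestor(cfg)
  g2 <- generate_ancestor(cfg)
  expect_identical(g1$chromosomes[[1]]$record$residues,
                   g2$chromosomes[[1]]$record$residues)
  p1 <- simulate_study_pair(seed = 55)
  p2 <- simulate_study_pair(seed = 55)
  expect_identical(genome_features(p1$sa1_like), genome_features(p2$sa1_like))
  expect_identical(p1$sa1_like$chromosomes[[2]]$record$residues,
                   p2$sa1_like$chromosomes[[2]]$record$residues)
})

test_that("generated ancestors hit the A+T target and pass completeness", {
  for (target in c(70, 80)) {
    g <- generate_ancestor(generator_config(seed = 17, at_target = target))
    realized <- at_content(g$chromosomes[[1]]$record)
    expect_gte(realized, target - 2)
    expect_lte(realized, target + 2)
    expect_true(genome_completeness(g)$complete)
    expect_identical(g$chromosomes[[1]]$record$topology, "circular")
  }
  # gene order equals the template
  g <- generate_ancestor(generator_config(seed = 17))
  ord <- extract_order(g)
  expect_identical(ord$chromosomes[[1]]$genes,
                   thrips_order_template()$chromosomes[[1]]$genes)
  # control region carries its motifs
  ch <- g$chromosomes[[1]]
  cr <- Filter(function(f) f$name == "control_region", ch$features)[[1]]
  cr_seq <- feature_seq(ch, cr)
  expect_true(grepl("TTTTTTTTTTTTTT", cr_seq))
})

test_that("seed is mandatory and config bounds are enforced", {
  expect_error(generator_config(), "seed")
  expect_error(generator_config(seed = 1, at_target = 20), "at_target")
})

test_that("evolving with no events and zero divergence is the identity", {
  anc <- default_ancestor()
  res <- evolve_pair(anc, events = list(), divergence = numeric(0), seed = 9)
  expect_identical(res$a$chromosomes[[1]]$record$residues,
                   res$b$chromosomes[[1]]$record$residues)
  expect_identical(genome_features(res$a)$name, genome_features(res$b)$name)
})

test_that("planted divergence is realized within one percentage point", {
  anc <- default_ancestor()
  targets <- c(nad2 = 20, cox1 = 11.76, trnQ = 2.94, control_region = 29.15,
               rrnL = 12.09)
  res <- evolve_pair(anc, events = list(), divergence = targets, seed = 23)
  for (g in names(targets)) {
    d <- gene_divergence(res$a, res$b, g)
    expect_lt(abs(d$percent - targets[[g]]), 1, label = g)
  }
  # untouched homolog stays identical
  expect_equal(gene_divergence(res$a, res$b, "atp6")$percent, 0)
})

test_that("conflicting or invalid planted events are rejected", {
  anc <- default_ancestor()
  expect_error(evolve_pair(anc, events = list(
    list(kind = "inversion", gene = "trnF"),
    list(kind = "inversion", gene = "trnF")), seed = 1), "conflict")
  expect_error(evolve_pair(anc, events = list(
    list(kind = "inversion", gene = "trnZ")), seed = 1), "absent")
  expect_error(evolve_pair(anc, divergence = c(trnZ = 5), seed = 1),
               "absent")
})

test_that("fission moves genes to a mini-circle and duplicates paralogs", {
  anc <- default_ancestor()
  # no-op case
  expect_identical(
    fission_minicircle(anc, move = character(0), duplicate = character(0)),
    anc)
  g <- fission_minicircle(anc, move = c("trnC", "nad6"),
                          duplicate = c("trnS1", "control_region"),
                          paralog_divergence = 1.65, seed = 5)
  expect_length(g$chromosomes, 2L)
  mini <- g$chromosomes[[2]]
  expect_length(mini$features, 4L)
  expect_setequal(vapply(mini$features, `[[`, character(1), "name"),
                  c("trnC", "nad6", "trnS1", "control_region"))
  # moved genes absent from chromosome 1
  chr1_names <- vapply(g$chromosomes[[1]]$features, `[[`, character(1),
                       "name")
  expect_false(any(c("trnC", "nad6") %in% chr1_names))
  expect_true(all(c("trnS1", "control_region") %in% chr1_names))
  expect_true(genome_completeness(g)$complete)
  # mini-circle emerges at the sub-kilobase scale
  expect_lt(nchar(mini$record$residues), 1000)
  expect_gt(nchar(mini$record$residues), 800)
  # paralog divergence realized within half a point
  expect_lt(abs(paralog_divergence(g, "control_region")$percent - 1.65), 0.5)
  # zero-divergence duplicates are byte-identical
  g0 <- fission_minicircle(anc, move = c("trnC", "nad6"),
                           duplicate = c("trnS1", "control_region"),
                           paralog_divergence = 0, seed = 6)
  copies <- lapply(g0$chromosomes, function(ch) {
    f <- Filter(function(x) x$name == "trnS1", ch$features)
    if (length(f)) feature_seq(ch, f[[1]]) else NULL
  })
  expect_identical(copies[[1]], copies[[2]])
  expect_error(fission_minicircle(anc, move = "trnZ", duplicate = NULL),
               "absent")
  expect_error(fission_minicircle(g, move = "cox1", duplicate = NULL),
               "unipartite")
})

test_that("a zero-error contig is the chromosome itself", {
  mini <- study_pair_fixture()$sa1_like$chromosomes[[2]]
  sim <- simulate_contig(mini, base_error = 0, seed = 2)
  expect_identical(sim$contig, mini$record$residues)
  expect_equal(nrow(sim$truth), 0L)
})

test_that("with unit multipliers planted errors are uniform over positions", {
  mini <- study_pair_fixture()$sa1_like$chromosomes[[2]]
  pos <- integer(0)
  for (s in 1:40) {
    sim <- simulate_contig(mini, base_error = 0.02, terminal_multiplier = 1,
                           homopolymer_multiplier = 1, seed = 1000 + s)
    pos <- c(pos, sim$truth$ref_pos)
  }
  len <- nchar(mini$record$residues)
  bins <- cut(pos, breaks = seq(0, len, length.out = 9),
              include.lowest = TRUE)
  p <- stats::chisq.test(table(bins))$p.value
  expect_gt(p, 0.001)
})

test_that("a strong homopolymer multiplier concentrates errors in runs", {
  # reference with a dense lattice of qualifying A/T runs (~1/3 of sites)
  set.seed(77)
  blocks <- replicate(60, paste0(random_dna_str(20, at = 0.5),
                                 strrep(sample(c("A", "T"), 1), 10)))
  ch <- chromosome(sequence_record("r", paste(blocks, collapse = ""),
                                   "circular"))
  sim <- simulate_contig(ch, base_error = 0.004, terminal_multiplier = 1,
                         homopolymer_multiplier = 10, seed = 3)
  expect_gt(nrow(sim$truth), 10)
  cl <- classify_changes(sim$truth, nchar(sim$contig), ch)
  expect_gt(cl$counts$homopolymer / cl$counts$total, 0.5)
})

test_that("planted contig errors are recovered by the audit diff", {
  mini <- study_pair_fixture()$sa1_like$chromosomes[[2]]
  for (s in c(11, 12, 13)) {
    sim <- simulate_contig(mini, base_error = 0.01, seed = s)
    rec <- diff_contig(sim$contig, mini)
    expect_equal(nrow(rec), nrow(sim$truth))
    lv <- c("substitution", "insertion", "deletion")
    expect_equal(as.vector(table(factor(rec$type, lv))),
                 as.vector(table(factor(sim$truth$type, lv))))
    cl <- classify_changes(rec, nchar(sim$contig), mini)
    expect_equal(cl$counts$terminal, sum(sim$truth$terminal))
    expect_equal(cl$counts$homopolymer, sum(sim$truth$homopolymer))
  }
})
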