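test_that("primer sites are found on both strands and across the origin", {
  s <- paste0("ATGCATGGACCT", random_dna_str(200), "GGTTCCAAGGCA")
  rec_lin <- sequence_record("t", s, "linear")
  # primer equal to the template prefix: site at 0 on +
  hits <- find_sites(rec_lin, "ATGCATGGACCT")
  expect_true(any(hits$position == 0 & hits$strand == "+"))
  # primer equal to the reverse complement of the suffix: - strand site there
  hits2 <- find_sites(rec_lin, revcomp("GGTTCCAAGGCA"))
  expect_true(any(hits2$position == nchar(s) - 12 & hits2$strand == "-"))
  # origin-straddling site found only on circular topology
  rec_circ <- sequence_record("t", s, "circular")
  straddle <- paste0(substr(s, nchar(s) - 5, nchar(s)), substr(s, 1, 6))
  expect_equal(nrow(find_sites(rec_lin, straddle)), 0L)
  hits3 <- find_sites(rec_circ, straddle)
  expect_true(any(hits3$position == nchar(s) - 6 & hits3$strand == "+"))
})

test_that("the 3'-terminal base must match even when mismatches are allowed", {
  s <- paste0("CCGGAATTCCGG", random_dna_str(100, at = 0))
  rec <- sequence_record("t", s, "linear")
  probe <- "CCGGAATTCCGG"
  # internal mismatch tolerated
  internal_mm <- probe
  substr(internal_mm, 5, 5) <- "T"
  expect_gte(nrow(find_sites(rec, internal_mm, max_mismatch = 1)), 1L)
  # 3' mismatch blocks the site
  terminal_mm <- probe
  substr(terminal_mm, 12, 12) <- "T"
  hits <- find_sites(rec, terminal_mm, max_mismatch = 1)
  expect_false(any(hits$position == 0 & hits$strand == "+"))
})

test_that("bipartite vs unipartite amplicon logic mirrors the gel test", {
  pair <- study_pair_fixture()
  sa1 <- pair$sa1_like  # bipartite truth
  # unipartite null hypothesis: the same genome's sequences on one circle
  uni <- merge_minicircle(sa1, after = "nad4L")
  mini <- sa1$chromosomes[[2]]
  nad6 <- Filter(function(f) f$name == "nad6", mini$features)[[1]]
  nad6_seq <- feature_seq(mini, nad6)
  fw <- substr(nad6_seq, 51, 72)
  rv <- revcomp(substr(nad6_seq, 301, 322))
  internal <- primer_pair("internal_nad6", fw, rv)
  outward <- primer_pair("outward_nad6", revcomp(rv), revcomp(fw))
  # boundary-spanning pair: rightward primer inside nad4 (an N-strand gene
  # upstream of nad6), leftward primer inside nad6
  ch1 <- sa1$chromosomes[[1]]
  nad4 <- Filter(function(f) f$name == "nad4", ch1$features)[[1]]
  nad4_seq <- feature_seq(ch1, nad4)
  boundary <- primer_pair("nad6_nad4", revcomp(substr(nad4_seq, 41, 62)), rv)

  # on the bipartite genome: boundary pair yields nothing (genes on
  # different molecules), internal works, outward completes the circle
  expect_equal(nrow(predict_amplicons(sa1, boundary)), 0L)
  amp_int <- predict_amplicons(sa1, internal)
  expect_equal(nrow(amp_int), 1L)
  expect_equal(amp_int$length, 272L)
  amp_out <- predict_amplicons(sa1, outward)
  expect_equal(nrow(amp_out), 1L)
  mini_len <- nchar(mini$record$residues)
  expect_equal(amp_out$length, mini_len - 272L + 22L + 22L)
  expect_true(amp_out$spans_origin)

  # on the unipartite model the boundary pair has a product
  expect_gte(nrow(predict_amplicons(uni, boundary, max_len = 5000)), 1L)
  # the outward pair's complementary arc is the rest of the ~15 kb circle:
  # absent under a 5 kb cap, present when the cap admits it
  expect_equal(nrow(predict_amplicons(uni, outward, max_len = 5000)), 0L)
  big <- predict_amplicons(uni, outward, max_len = 16000)
  expect_equal(nrow(big), 1L)
  chr_len <- nchar(uni$chromosomes[[1]]$record$residues)
  expect_equal(big$length, chr_len - 272L + 44L)
})

test_that("amplicon lengths are rotation-invariant and bounded", {
  pair <- study_pair_fixture()
  mini <- pair$sa1_like$chromosomes[[2]]
  nad6 <- Filter(function(f) f$name == "nad6", mini$features)[[1]]
  s <- feature_seq(mini, nad6)
  pp <- primer_pair("p", substr(s, 11, 32), revcomp(substr(s, 201, 222)))
  g0 <- mito_genome("m", mini)
  l0 <- predict_amplicons(g0, pp)$length
  for (off in c(13, 450, 900)) {
    gr <- mito_genome("m", rotate_chromosome(mini, off))
    expect_equal(predict_amplicons(gr, pp)$length, l0, label = off)
  }
  # swapping forward and reverse leaves product lengths unchanged
  pp_sw <- primer_pair("p_sw", pp$reverse, pp$forward)
  expect_equal(sort(predict_amplicons(g0, pp_sw)$length), sort(l0))
  # products never exceed the cap or the template
  set.seed(31)
  tpl <- mini$record$residues
  for (i in 1:10) {
    a <- sample(nchar(tpl) - 30, 1)
    b <- sample(nchar(tpl) - 30, 1)
    prm <- primer_pair("r", substr(tpl, a, a + 21),
                       revcomp(substr(tpl, b, b + 21)))
    amp <- predict_amplicons(g0, prm, max_len = 700)
    if (nrow(amp)) {
      expect_true(all(amp$length <= 700))
      expect_true(all(amp$length <= nchar(tpl)))
    }
  }
})

test_that("the architecture verdict follows the concordant hypothesis", {
  pair <- study_pair_fixture()
  sa1 <- pair$sa1_like
  uni <- merge_minicircle(sa1, after = "nad4L")
  mini <- sa1$chromosomes[[2]]
  mini_len <- nchar(mini$record$residues)
  nad6 <- Filter(function(f) f$name == "nad6", mini$features)[[1]]
  s <- feature_seq(mini, nad6)
  fw <- substr(s, 51, 72); rv <- revcomp(substr(s, 301, 322))
  ch1 <- sa1$chromosomes[[1]]
  nad4 <- Filter(function(f) f$name == "nad4", ch1$features)[[1]]
  rrnL <- Filter(function(f) f$name == "rrnL", ch1$features)[[1]]
  panel <- list(
    primer_pair("gap_nad4", revcomp(substr(feature_seq(ch1, nad4), 41, 62)),
                rv),
    primer_pair("internal", fw, rv),
    primer_pair("gap_rrnL", fw,
                revcomp(substr(feature_seq(ch1, rrnL), 31, 52))),
    primer_pair("outward", revcomp(rv), revcomp(fw))
  )
  observed_gel <- list(
    gap_nad4 = list(product = FALSE),
    internal = list(product = TRUE, size = 272),
    gap_rrnL = list(product = FALSE),
    outward = list(product = TRUE, size = mini_len - 272 + 44)
  )
  res <- architecture_test(uni, sa1, panel, observed_gel)
  expect_identical(res$verdict, "bipartite")
  expect_true(all(res$concordance$bipartite_ok))
  # mirror pattern: all boundary products present, outward absent
  mirror <- list(gap_nad4 = list(product = TRUE),
                 internal = list(product = TRUE),
                 gap_rrnL = list(product = TRUE),
                 outward = list(product = FALSE))
  expect_identical(architecture_test(uni, sa1, panel, mirror)$verdict,
                   "unipartite")
  # contradictory pattern (everything amplifies): ambiguous -- possible
  # coexistence of both architectures
  allprod <- list(gap_nad4 = list(product = TRUE),
                  internal = list(product = TRUE),
                  gap_rrnL = list(product = TRUE),
                  outward = list(product = TRUE))
  expect_identical(architecture_test(uni, sa1, panel, allprod)$verdict,
                   "ambiguous")
  expect_error(
    architecture_test(uni, sa1, panel, list(zzz = list(product = TRUE))),
    "unknown primer pair")
})
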