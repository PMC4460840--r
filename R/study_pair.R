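#' Simulate a cryptic-species genome pair under the study conditions
#'
#' Builds a synthetic analogue of the published two-genome contrast: from a
#' common ancestor, an EA1-like unipartite genome (trnY inverted onto the N
#' strand, a 623 bp species-specific noncoding region between trnR and trnG)
#' and an SA1-like bipartite genome (trnF inverted, nad6+trnC fissioned onto a
#' mini-circle with duplicated control region and trnS1, a 242 bp noncoding
#' region between nad5 and trnH). Per-homolog divergence targets default to
#' the published per-homolog values, planted on the SA1-like lineage, and the
#' control-region paralogs diverge by 1.65% (trnS1 copies identical).
#'
#' @param seed Integer seed.
#' @param at_target Ancestral A+T percent (default 77, between the two
#'   published genome-wide values).
#' @param divergence Named vector of per-homolog targets; defaults to the
#'   published table.
#' @param paralog_divergence Paralog divergence targets for the duplicated
#'   features, named by feature.
#' @return List with `ea1_like`, `sa1_like` (`mito_genome`s) and `truth`.
#' @export
simulate_study_pair <- function(seed, at_target = 77, divergence = NULL,
                                paralog_divergence = c(control_region = 1.65,
                                                       trnS1 = 0)) {
  if (is.null(divergence)) {
    tab <- sd_divergence_table()
    divergence <- stats::setNames(tab$percent, tab$gene)
  }
  cfg <- generator_config(seed = seed, at_target = at_target)
  anc <- generate_ancestor(cfg)
  ea1_core <- evolve_pair(anc, events = list(list(kind = "inversion",
                                                  gene = "trnY")),
                          divergence = numeric(0), seed = seed + 1L,
                          labels = c("ancestor", "EA1_like"))$b
  ea1 <- insert_noncoding(ea1_core, after = "trnR", length = 623L,
                          name = "NC_EA1", strand = "J")
  ev <- list(
    list(kind = "inversion", gene = "trnY"),  # back to the ancestral J strand
    list(kind = "inversion", gene = "trnF"),
    list(kind = "fission", move = c("trnC", "nad6"),
         duplicate = c("trnS1", "control_region"),
         paralog_divergence = paralog_divergence)
  )
  res <- evolve_pair(ea1_core, events = ev, divergence = divergence,
                     seed = seed + 2L, labels = c("EA1_like", "SA1_like"))
  sa1 <- insert_noncoding(res$b, after = "nad5", length = 242L,
                          name = "NC_SA1", strand = "N")
  list(ea1_like = ea1, sa1_like = sa1,
       truth = list(planted_events = ev, planted_divergence = divergence,
                    paralog_divergence = paralog_divergence, seed = seed))
}
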