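#!/usr/bin/env Rscript
# In-silico reproduction of the architecture-discriminating PCR experiment:
# boundary-spanning primer pairs versus internal and outward-facing nad6
# primers, predicted under both the unipartite null model and the bipartite
# mini-circle model, then scored against the expected gel pattern. Writes
# results/pcr/.

suppressPackageStartupMessages(library(mitofrag))

sim <- "results/simulation"
out <- "results/pcr"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
if (!file.exists(file.path(sim, "sa1_like.gb"))) {
  stop("run analysis/01_simulate.R first")
}

sa1 <- read_genbank(file.path(sim, "sa1_like.gb"), label = "SA1_like")
uni <- merge_minicircle(sa1, after = "nad4L")
mini <- sa1$chromosomes[[2]]
mini_len <- nchar(mini$record$residues)

nad6 <- Filter(function(f) f$name == "nad6", mini$features)[[1]]
nad6_seq <- feature_seq(mini, nad6)
fw <- substr(nad6_seq, 51, 72)
rv <- revcomp(substr(nad6_seq, 301, 322))
ch1 <- sa1$chromosomes[[1]]
nad4_seq <- feature_seq(
  ch1, Filter(function(f) f$name == "nad4", ch1$features)[[1]])
rrnL_seq <- feature_seq(
  ch1, Filter(function(f) f$name == "rrnL", ch1$features)[[1]])

panel <- list(
  primer_pair("gap_nad4", revcomp(substr(nad4_seq, 41, 62)), rv),
  primer_pair("internal", fw, rv),
  primer_pair("gap_rrnL", fw, revcomp(substr(rrnL_seq, 31, 52))),
  primer_pair("outward", revcomp(rv), revcomp(fw)))

panel_df <- do.call(rbind, lapply(panel, function(p) {
  data.frame(name = p$name, forward = p$forward, reverse = p$reverse)
}))
utils::write.table(panel_df, file.path(out, "primer_panel.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

predict_rows <- function(genome, hypothesis, p) {
  amp <- predict_amplicons(genome, p)
  if (!nrow(amp)) {
    return(data.frame(hypothesis = hypothesis, pair = p$name,
                      template = "(no product)", start = NA, end = NA,
                      length = NA, spans_origin = NA,
                      forward_primer = p$forward, reverse_primer = p$reverse))
  }
  cbind(hypothesis = hypothesis, pair = p$name, amp)
}
pred <- do.call(rbind, lapply(panel, function(p) {
  rbind(predict_rows(uni, "unipartite", p),
        predict_rows(sa1, "bipartite", p))
}))
utils::write.table(pred, file.path(out, "predicted_amplicons.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Predicted products:\n")
print(pred[, c("hypothesis", "pair", "template", "length", "spans_origin")])

observed <- list(
  gap_nad4 = list(product = FALSE),
  internal = list(product = TRUE, size = 272),
  gap_rrnL = list(product = FALSE),
  outward = list(product = TRUE, size = mini_len - 272 + 44))
res <- architecture_test(uni, sa1, panel, observed)
cat("\nVerdict:", res$verdict, "\n")
print(res$concordance)
jsonlite::write_json(list(verdict = res$verdict,
                          concordance = res$concordance),
                     file.path(out, "verdict.json"),
                     auto_unbox = TRUE, pretty = TRUE)
cat("Boundary pairs fail and the outward-facing internal pair completes",
    "the mini-circle only under the bipartite model.\n")
cat("Tables written to", out, "\n")
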