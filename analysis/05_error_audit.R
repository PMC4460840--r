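#!/usr/bin/env Rscript
# NGS error audit: the published change counts re-expressed as raw and
# filtered error rates, and a simulated audit of an NGS-style contig of the
# synthetic mini-circle (errors enriched at contig termini and in A/T
# homopolymer runs). Writes results/audit/.

suppressPackageStartupMessages(library(mitofrag))

sim <- "results/simulation"
out <- "results/audit"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# published counts: 15 changes, 7 terminal, 11 homopolymer, 3 neither
counts <- sd_audit_counts()
er <- error_rates(counts, counts$reference_length)
published <- data.frame(
  quantity = c("total_changes", "terminal", "homopolymer", "both",
               "neither", "raw_rate_pct", "filtered_rate_pct"),
  value = c(counts$total, counts$terminal, counts$homopolymer, counts$both,
            counts$neither, round(er$raw, 2), round(er$filtered, 2)))
utils::write.table(published, file.path(out, "published_rates.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Published audit counts over the 921 bp mini-circle:\n")
print(published)
cat(sprintf("Discounting both artefact contexts reduces the rate %.1f%% -> %.1f%%\n",
            er$raw, er$filtered))

if (!file.exists(file.path(sim, "sa1_like.gb"))) {
  stop("run analysis/01_simulate.R first")
}
sa1 <- read_genbank(file.path(sim, "sa1_like.gb"), label = "SA1_like")
mini <- sa1$chromosomes[[2]]

simc <- simulate_contig(mini, base_error = 0.006, terminal_multiplier = 5,
                        homopolymer_multiplier = 6, seed = 20150609L)
rec <- diff_contig(simc$contig, mini)
cl <- classify_changes(rec, nchar(simc$contig), mini)
er2 <- error_rates(cl$counts, nchar(mini$record$residues))
utils::write.table(cl$changes, file.path(out, "simulated_changes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(counts = cl$counts,
                          raw_pct = er2$raw, filtered_pct = er2$filtered,
                          planted = nrow(simc$truth),
                          recovered = nrow(rec)),
                     file.path(out, "simulated_rates.json"),
                     auto_unbox = TRUE, pretty = TRUE)
cat(sprintf("\nSimulated contig audit: %d planted, %d recovered; raw %.2f%%, filtered %.2f%%\n",
            nrow(simc$truth), nrow(rec), er2$raw, er2$filtered))
cat("Tables written to", out, "\n")
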