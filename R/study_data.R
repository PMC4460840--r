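#' Published gene orders of the two Scirtothrips dorsalis cryptic species
#'
#' Signed, cox1-anchored gene orders of the South Asia 1 (SA1, bipartite:
#' 14,283 bp chromosome 1 plus the 921 bp nad6 mini-circle) and East Asia 1
#' (EA1, unipartite) mitogenomes, transcribed from the published comparison
#' table. Strand signs follow the J/N convention (+ = majority-coding).
#' Species-specific non-homologous noncoding regions (623 bp in EA1 between
#' trnR and trnG; 242 bp in SA1 between nad5 and trnH) are not part of the
#' canonical order and are omitted here. The SA1 mini-circle carries
#' non-redundant nad6 and trnC together with paralogous copies of trnS1 and
#' the control region.
#'
#' @return A named list of two `gene_order` objects, `SA1` and `EA1`.
#' @export
sd_gene_orders <- function() {
  common_head <- c("cox1", "nad3", "trnL2", "cox2", "trnD", "trnR", "trnG",
                   "trnK", "cox3", "trnI", "trnL1", "trnT", "trnP", "trnN",
                   "trnE", "trnQ", "cob")
  block_mid <- c("nad2", "trnW", "nad1", "trnM", "trnA")
  after_f <- c("rrnS", "atp8", "atp6", "trnS1", "control_region")
  n_cluster <- c("-nad5", "-trnH", "-nad4", "-nad4L")
  tail_part <- c("trnV", "rrnL", "trnS2")

  ea1 <- order_from_tokens(
    c(common_head, "-trnY", block_mid, "trnF", after_f, n_cluster,
      "trnC", "nad6", tail_part),
    id = "EA1")

  sa1_chr1 <- c(common_head, "trnY", block_mid, "-trnF", after_f, n_cluster,
                tail_part)
  sa1 <- gene_order(list(
    list(id = "SA1_chr1",
         genes = sub("^-", "", sa1_chr1),
         signs = ifelse(startsWith(sa1_chr1, "-"), -1L, 1L)),
    list(id = "SA1_chr2",
         genes = c("trnC", "nad6", "trnS1", "control_region"),
         signs = c(1L, 1L, 1L, 1L))
  ))
  list(SA1 = sa1, EA1 = ea1)
}

#' Published per-homolog sequence differences between SA1 and EA1
#'
#' The percent sequence difference of each of the 38 homologs (37 genes plus
#' the control region) between the two cryptic species, as published
#' (indels collapsed to single differences; tRNA alignment termini trimmed).
#' The two species-specific noncoding regions are non-homologous and excluded.
#'
#' @return data.frame with columns `gene`, `kind`, `percent`.
#' @export
sd_divergence_table <- function() {
  vals <- c(
    cox1 = 11.76, nad3 = 19.21, trnL2 = 5.97, cox2 = 12.83, trnD = 13.43,
    trnR = 1.47, trnG = 9.23, trnK = 4.76, cox3 = 11.28, trnI = 14.29,
    trnL1 = 9.23, trnT = 7.81, trnP = 9.23, trnN = 10.17, trnE = 12.12,
    trnQ = 2.94, cob = 13.51, trnY = 10.61, nad2 = 19.64, trnW = 7.35,
    nad1 = 17.80, trnM = 6.25, trnA = 3.03, trnF = 4.41, rrnS = 12.42,
    atp8 = 21.14, atp6 = 18.82, trnS1 = 11.67, control_region = 29.15,
    nad5 = 16.34, trnH = 15.15, nad4 = 19.12, nad4L = 20.63, trnC = 8.06,
    nad6 = 21.37, trnV = 13.33, rrnL = 12.09, trnS2 = 4.41)
  data.frame(gene = names(vals), kind = gene_kind(names(vals)),
             percent = unname(vals), stringsAsFactors = FALSE)
}

#' Synthetic stand-in gene orders for the three reference thrips genomes
#'
#' The published comparison places the two cryptic-species genomes alongside
#' three previously sequenced thrips mitogenomes (Thrips imaginis,
#' Frankliniella occidentalis, F. intonsa). Their full tRNA-level orders are
#' not reproduced in this package; these stand-ins are *synthetic* orders
#' constructed to satisfy only what is reported about them: protein-coding and
#' rRNA gene order and strand identical to the cryptic-species pair, all
#' differences confined to tRNA translocations/inversions, and conservation of
#' every gene boundary inside the trnY-atp6 block while boundaries flanking
#' that block are disrupted in at least one genome. They support
#' block-structure analysis, not sequence-level inference.
#'
#' @return Named list of three `gene_order` objects.
#' @export
synthetic_reference_orders <- function() {
  base <- c("cox1", "nad3", "trnL2", "cox2", "trnD", "trnR", "trnG",
            "trnK", "cox3", "trnI", "trnL1", "trnT", "trnP", "trnN",
            "trnE", "trnQ", "cob", "trnY", "nad2", "trnW", "nad1", "trnM",
            "trnA", "trnF", "rrnS", "atp8", "atp6", "trnS1",
            "control_region", "-nad5", "-trnH", "-nad4", "-nad4L",
            "trnC", "nad6", "trnV", "rrnL", "trnS2")
  move_gene <- function(tokens, gene, after) {
    tok <- tokens[sub("^-", "", tokens) == gene]
    tokens <- tokens[sub("^-", "", tokens) != gene]
    i <- which(sub("^-", "", tokens) == after)
    append(tokens, tok, after = i)
  }
  flip_gene <- function(tokens, gene) {
    i <- which(sub("^-", "", tokens) == gene)
    tokens[i] <- if (startsWith(tokens[i], "-")) sub("^-", "", tokens[i])
                 else paste0("-", tokens[i])
    tokens
  }
  # imaginis-like: trnQ moved between cob and trnY (breaks cob|trnY), trnS1
  # moved after trnS2 (breaks atp6|trnS1)
  ref1 <- move_gene(base, "trnQ", "cob")
  ref1 <- move_gene(ref1, "trnS1", "trnS2")
  # occidentalis-like: trnI moved after rrnL, trnT inverted
  ref2 <- move_gene(base, "trnI", "rrnL")
  ref2 <- flip_gene(ref2, "trnT")
  # intonsa-like: trnK moved between nad4L and trnC, trnV inverted
  ref3 <- move_gene(base, "trnK", "nad4L")
  ref3 <- flip_gene(ref3, "trnV")
  list(
    imaginis_like = order_from_tokens(ref1, id = "REF1_synthetic"),
    occidentalis_like = order_from_tokens(ref2, id = "REF2_synthetic"),
    intonsa_like = order_from_tokens(ref3, id = "REF3_synthetic")
  )
}

#' Published NGS-vs-Sanger change counts for the mini-circle contig
#'
#' The audit of the NGS contig covering the 921 bp mini-circle against the
#' capillary-validated chromosome found 15 changes: 7 within the first or
#' last 80 nt of the contig, 11 in A/T homopolymer runs >= 8 nt, and 3
#' meeting neither criterion (so 6 met both, by inclusion-exclusion).
#'
#' @return Named list: `total`, `terminal`, `homopolymer`, `neither`, `both`,
#'   and `reference_length` (bp).
#' @export
sd_audit_counts <- function() {
  total <- 15L; terminal <- 7L; homopolymer <- 11L; neither <- 3L
  list(total = total, terminal = terminal, homopolymer = homopolymer,
       neither = neither,
       both = terminal + homopolymer - (total - neither),
       reference_length = 921L)
}
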