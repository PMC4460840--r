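#' Canonical mitochondrial gene vocabulary
#'
#' The 37 genes shared by virtually all insect mitochondrial genomes:
#' 13 protein-coding genes, 22 tRNAs (with the serine and leucine isoacceptors
#' disambiguated by anticodon: S1 = tct, S2 = tga, L1 = tag, L2 = taa), and the
#' two ribosomal RNAs. The non-coding control region (A+T-rich region) is
#' handled as an additional named feature, and any unrecognised annotation maps
#' to `noncoding`.
#'
#' @return Character vector of the 37 canonical gene tokens.
#' @export
mito_genes <- function() {
  c(pcg_genes(), trna_genes(), rrna_genes())
}

#' @rdname mito_genes
#' @export
pcg_genes <- function() {
  c("atp6", "atp8", "cob", "cox1", "cox2", "cox3",
    "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")
}

#' @rdname mito_genes
#' @export
trna_genes <- function() {
  c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH", "trnI",
    "trnK", "trnL1", "trnL2", "trnM", "trnN", "trnP", "trnQ", "trnR",
    "trnS1", "trnS2", "trnT", "trnV", "trnW", "trnY")
}

#' @rdname mito_genes
#' @export
rrna_genes <- function() {
  c("rrnS", "rrnL")
}

#' Feature kind for a canonical token
#'
#' @param name Canonical gene token (or `control_region` / `noncoding`).
#' @return One of `"PCG"`, `"tRNA"`, `"rRNA"`, `"control"`, `"noncoding"`.
#' @export
gene_kind <- function(name) {
  vapply(name, function(x) {
    if (x %in% pcg_genes()) "PCG"
    else if (x %in% trna_genes()) "tRNA"
    else if (x %in% rrna_genes()) "rRNA"
    else if (x == "control_region") "control"
    else "noncoding"
  }, character(1), USE.NAMES = FALSE)
}

# Alias table mapping depositor nomenclature onto the canonical vocabulary.
# Anticodon-less serine/leucine aliases are ambiguous and resolved by the
# anticodon argument of normalize_gene_name() when available.
gene_alias_table <- function() {
  al <- list(
    cox1 = c("cox1", "coi", "co1", "cox-1", "coxi", "cytochrome c oxidase subunit i",
             "cytochrome c oxidase subunit 1"),
    cox2 = c("cox2", "coii", "co2", "coxii", "cytochrome c oxidase subunit ii",
             "cytochrome c oxidase subunit 2"),
    cox3 = c("cox3", "coiii", "co3", "coxiii", "cytochrome c oxidase subunit iii",
             "cytochrome c oxidase subunit 3"),
    cob = c("cob", "cytb", "cyt b", "cytochrome b"),
    atp6 = c("atp6", "atpase6", "atpase 6", "atp synthase f0 subunit 6"),
    atp8 = c("atp8", "atpase8", "atpase 8", "atp synthase f0 subunit 8"),
    nad1 = c("nad1", "nd1", "nadh dehydrogenase subunit 1"),
    nad2 = c("nad2", "nd2", "nadh dehydrogenase subunit 2"),
    nad3 = c("nad3", "nd3", "nadh dehydrogenase subunit 3"),
    nad4 = c("nad4", "nd4", "nadh dehydrogenase subunit 4"),
    nad4L = c("nad4l", "nd4l", "nadh dehydrogenase subunit 4l"),
    nad5 = c("nad5", "nd5", "nadh dehydrogenase subunit 5"),
    nad6 = c("nad6", "nd6", "nadh dehydrogenase subunit 6"),
    rrnS = c("rrns", "12s", "12s rrna", "12s ribosomal rna", "s-rrna", "srrna",
             "small subunit ribosomal rna", "rrn12"),
    rrnL = c("rrnl", "16s", "16s rrna", "16s ribosomal rna", "l-rrna", "lrrna",
             "large subunit ribosomal rna", "rrn16"),
    control_region = c("control_region", "control region", "a+t rich region",
                       "at rich region", "a+t-rich region", "d-loop", "dloop",
                       "putative control region", "control"),
    trnL1 = c("trnl1", "trna-leu1", "trnl(tag)", "trna-leu(tag)", "l1"),
    trnL2 = c("trnl2", "trna-leu2", "trnl(taa)", "trna-leu(taa)", "l2"),
    trnS1 = c("trns1", "trna-ser1", "trns(tct)", "trna-ser(tct)", "trns(agn)",
              "trna-ser(agn)", "s1"),
    trnS2 = c("trns2", "trna-ser2", "trns(tga)", "trna-ser(tga)", "trns(ucn)",
              "trna-ser(ucn)", "s2")
  )
  one <- c(A = "ala", C = "cys", D = "asp", E = "glu", F = "phe", G = "gly",
           H = "his", I = "ile", K = "lys", M = "met", N = "asn", P = "pro",
           Q = "gln", R = "arg", T = "thr", V = "val", W = "trp", Y = "tyr")
  for (aa in names(one)) {
    tok <- paste0("trn", aa)
    al[[tok]] <- c(tolower(tok), paste0("trna-", one[[aa]]), one[[aa]],
                   tolower(aa), paste0("trna-", aa))
  }
  data.frame(
    alias = unlist(al, use.names = FALSE),
    canonical = rep(names(al), lengths(al)),
    stringsAsFactors = FALSE
  )
}

#' Map a depositor gene name onto the canonical vocabulary
#'
#' Annotation nomenclature varies across GenBank depositors ("ND6" vs "nad6",
#' "COI" vs "cox1", one-letter tRNA codes, ...). This resolves an annotated
#' name to its canonical token, using the anticodon to split the serine and
#' leucine tRNA isoacceptors when the name alone is ambiguous. Unrecognised
#' names return `NA` so callers can fall back to `noncoding`.
#'
#' @param name Annotated name (any case, e.g. "ND6", "tRNA-Ser", "COI").
#' @param anticodon Optional anticodon string (e.g. "tct") used to
#'   disambiguate trnS1/trnS2 and trnL1/trnL2.
#' @param extra Optional two-column data.frame (`alias`, `canonical`) of
#'   user-supplied aliases consulted before the built-in table.
#' @return Canonical token, or `NA_character_` if unmappable.
#' @export
normalize_gene_name <- function(name, anticodon = NULL, extra = NULL) {
  key <- tolower(trimws(name))
  if (!is.null(extra)) {
    hit <- match(key, tolower(extra$alias))
    if (!is.na(hit)) return(extra$canonical[hit])
  }
  ac <- if (is.null(anticodon)) "" else tolower(trimws(anticodon))
  # ambiguous serine / leucine names resolved by anticodon
  if (grepl("^(trns|trna-ser|s)$", key)) {
    if (ac == "tct") return("trnS1")
    if (ac == "tga") return("trnS2")
    return(NA_character_)
  }
  if (grepl("^(trnl|trna-leu|l)$", key)) {
    if (ac == "tag") return("trnL1")
    if (ac == "taa") return("trnL2")
    return(NA_character_)
  }
  tab <- gene_alias_table()
  hit <- match(key, tab$alias)
  if (is.na(hit)) NA_character_ else tab$canonical[hit]
}
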