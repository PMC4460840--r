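#' Primer pair
#'
#' Both primers are given as synthesized, 5'-to-3'. The forward primer anneals
#' to the minus strand (extends rightward on the plus strand); the reverse
#' primer anneals to the plus strand (extends leftward).
#'
#' @param name Pair label.
#' @param forward,reverse Primer sequences, length >= 10.
#' @return Object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  stopifnot(nchar(forward) >= 10L, nchar(reverse) >= 10L)
  if (grepl("[^ACGT]", paste0(forward, reverse))) {
    stop("primer_pair: primers must be unambiguous A/C/G/T")
  }
  structure(list(name = name, forward = forward, reverse = reverse),
            class = "primer_pair")
}

#' Find primer annealing sites on a template
#'
#' Reports every position where the primer anneals on either strand with at
#' most `max_mismatch` mismatches; the primer's 3'-terminal base must match
#' exactly (a 3' mismatch blocks extension). Circular templates are searched
#' across the origin.
#'
#' @param template A `sequence_record` (or plain DNA string, taken as linear).
#' @param primer Primer sequence, 5'-to-3'.
#' @param max_mismatch Allowed mismatches (default 0).
#' @return data.frame with `position` (0-based start of the primer footprint
#'   on plus-strand coordinates) and `strand` (`"+"` = primer extends
#'   rightward, `"-"` = leftward).
#' @export
find_sites <- function(template, primer, max_mismatch = 0L) {
  if (is.character(template)) template <- sequence_record("t", template)
  primer <- toupper(primer)
  k <- nchar(primer)
  len <- nchar(template$residues)
  if (k >= len) stop("find_sites: primer not shorter than template")
  subject <- template$residues
  circular <- template$topology == "circular"
  if (circular) {
    subject <- paste0(subject, substr(template$residues, 1L, k - 1L))
  }
  hits_for <- function(pat, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat),
                                  Biostrings::DNAString(subject),
                                  max.mismatch = max_mismatch)
    st <- BiocGenerics::start(m) - 1L
    if (!length(st)) return(NULL)
    # mandatory exact 3' base: rightmost footprint base for "+", leftmost
    # (complemented) for "-"
    keep <- vapply(st, function(p) {
      if (strand == "+") {
        substr(subject, p + k, p + k) == substr(pat, k, k)
      } else {
        substr(subject, p + 1L, p + 1L) == substr(pat, 1L, 1L)
      }
    }, logical(1))
    st <- st[keep]
    if (!length(st)) return(NULL)
    if (circular) st <- unique(st %% len)
    data.frame(position = st, strand = strand, stringsAsFactors = FALSE)
  }
  out <- rbind(hits_for(primer, "+"), hits_for(revcomp(primer), "-"))
  if (is.null(out)) {
    return(data.frame(position = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Predict PCR amplicons of a primer pair on a genome
#'
#' Every convergent combination of sites (a rightward-extending site followed,
#' going rightward, by a leftward-extending site) with product length at most
#' `max_len` is reported, on every chromosome. On circular templates the
#' product may traverse the origin, which is how outward-facing primers placed
#' inside a single gene amplify "the rest of the circle" and can complete a
#' mini-circle chromosome; the product may be as long as the whole template.
#'
#' @param genome A `mito_genome` (or a single `chromosome`/`sequence_record`).
#' @param pair A `primer_pair`.
#' @param max_len Maximum product size in bp.
#' @param max_mismatch Allowed mismatches per primer (3' base always exact).
#' @return data.frame with `template`, `start`, `end` (0-based half-open,
#'   end may exceed template length for origin-spanning products), `length`,
#'   `spans_origin`, `forward_primer`, `reverse_primer`.
#' @export
predict_amplicons <- function(genome, pair, max_len = 5000L,
                              max_mismatch = 0L) {
  if (inherits(genome, "sequence_record")) {
    genome <- mito_genome(genome$id, chromosome(genome))
  }
  if (inherits(genome, "chromosome")) {
    genome <- mito_genome(genome$record$id, genome)
  }
  out <- list()
  for (ch in genome$chromosomes) {
    rec <- ch$record
    len <- nchar(rec$residues)
    circular <- rec$topology == "circular"
    sf <- find_sites(rec, pair$forward, max_mismatch)
    sr <- find_sites(rec, pair$reverse, max_mismatch)
    combos <- rbind(
      merge_sites(sf, sr, pair$forward, pair$reverse),
      merge_sites(sr, sf, pair$reverse, pair$forward)
    )
    if (is.null(combos) || !nrow(combos)) next
    for (i in seq_len(nrow(combos))) {
      p_plus <- combos$plus_pos[i]      # rightward primer footprint start
      p_minus <- combos$minus_pos[i]    # leftward primer footprint start
      k_minus <- nchar(combos$minus_primer[i])
      amp_end <- p_minus + k_minus      # rightmost base of product, exclusive
      span <- amp_end - p_plus
      if (circular) {
        span <- ((span - 1L) %% len) + 1L  # full-circle product maps to len
      } else if (span <= 0L) next
      if (span > len || span > max_len) next
      if (span < nchar(combos$plus_primer[i]) || span < k_minus) next
      out[[length(out) + 1L]] <- data.frame(
        template = rec$id, start = p_plus, end = p_plus + span,
        length = span, spans_origin = p_plus + span > len,
        forward_primer = combos$plus_primer[i],
        reverse_primer = combos$minus_primer[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(template = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      spans_origin = logical(0),
                      forward_primer = character(0),
                      reverse_primer = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- unique(res)
  res[order(res$template, res$start, res$length), , drop = FALSE]
}

merge_sites <- function(a, b, primer_a, primer_b) {
  a <- a[a$strand == "+", , drop = FALSE]
  b <- b[b$strand == "-", , drop = FALSE]
  if (!nrow(a) || !nrow(b)) return(NULL)
  expand <- expand.grid(ai = seq_len(nrow(a)), bi = seq_len(nrow(b)))
  data.frame(plus_pos = a$position[expand$ai],
             minus_pos = b$position[expand$bi],
             plus_primer = primer_a, minus_primer = primer_b,
             stringsAsFactors = FALSE)
}

#' Architecture hypothesis test by in-silico PCR
#'
#' Given two candidate genome architectures (a unipartite single-chromosome
#' model and a bipartite mini-circle model), a primer panel, and the observed
#' gel pattern, predicts the product presence/size pattern under each
#' hypothesis and returns the verdict for the hypothesis matching every
#' observation. Product sizes are compared with +/-10% tolerance (gel sizing
#' precision). If both or neither hypothesis matches, the verdict is
#' `ambiguous` — e.g. when every reaction yields product, consistent with
#' coexistence of both architectures.
#'
#' @param unipartite,bipartite `mito_genome`s embodying the two hypotheses.
#' @param panel List of `primer_pair`s.
#' @param observed Named list (by pair name): each element
#'   `list(product = TRUE/FALSE, size = bp or NULL)`.
#' @param max_len,size_tol Prediction cap and relative size tolerance.
#' @return List with `verdict` (`"unipartite"`, `"bipartite"` or
#'   `"ambiguous"`) and `concordance` (per-pair data.frame).
#' @export
architecture_test <- function(unipartite, bipartite, panel, observed,
                              max_len = 5000L, size_tol = 0.10) {
  if (!length(panel)) stop("architecture_test: empty primer panel")
  panel_names <- vapply(panel, `[[`, character(1), "name")
  unknown <- setdiff(names(observed), panel_names)
  if (length(unknown)) {
    stop("architecture_test: observation(s) for unknown primer pair(s): ",
         paste(unknown, collapse = ", "))
  }
  rows <- list()
  for (pair in panel) {
    obs <- observed[[pair$name]]
    if (is.null(obs)) next
    concord <- vapply(list(unipartite, bipartite), function(g) {
      pred <- predict_amplicons(g, pair, max_len = max_len)
      if (!obs$product) return(nrow(pred) == 0L)
      if (nrow(pred) == 0L) return(FALSE)
      if (is.null(obs$size)) return(TRUE)
      any(abs(pred$length - obs$size) <= size_tol * obs$size)
    }, logical(1))
    rows[[length(rows) + 1L]] <- data.frame(
      pair = pair$name, observed_product = obs$product,
      unipartite_ok = concord[1], bipartite_ok = concord[2],
      stringsAsFactors = FALSE)
  }
  concordance <- do.call(rbind, rows)
  uni_ok <- all(concordance$unipartite_ok)
  bi_ok <- all(concordance$bipartite_ok)
  verdict <- if (uni_ok && !bi_ok) "unipartite"
             else if (bi_ok && !uni_ok) "bipartite"
             else "ambiguous"
  list(verdict = verdict, concordance = concordance)
}
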