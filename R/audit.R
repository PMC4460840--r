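#' Rules for classifying NGS contig errors
#'
#' Two contexts concentrate NGS contig errors relative to a capillary-validated
#' reference: the first/last `terminal_window` nucleotides of the contig
#' (assembly quality decays at contig ends) and A/T homopolymer runs of at
#' least `homopolymer_min` nt (run-length miscounts typical of
#' semiconductor sequencing). Because an indel inside a run can be placed at
#' either run edge by the aligner, a change within `margin` bases of a run
#' still counts as homopolymer-associated (set `margin = 0` to disable).
#'
#' @param terminal_window Window size in bp (default 80).
#' @param homopolymer_min Minimum run length (default 8).
#' @param homopolymer_bases Bases whose runs count (default A and T).
#' @param margin Adjacency margin in bp (default 1).
#' @return List of class `audit_rules`.
#' @export
audit_rules <- function(terminal_window = 80L, homopolymer_min = 8L,
                        homopolymer_bases = c("A", "T"), margin = 1L) {
  stopifnot(terminal_window >= 0, homopolymer_min >= 2, margin >= 0)
  structure(list(terminal_window = as.integer(terminal_window),
                 homopolymer_min = as.integer(homopolymer_min),
                 homopolymer_bases = homopolymer_bases,
                 margin = as.integer(margin)),
            class = "audit_rules")
}

# Logical mask over reference positions lying in (or within `margin` of) a
# homopolymer run of qualifying length.
homopolymer_mask <- function(ref, rules) {
  chars <- strsplit(ref, "")[[1]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mask <- logical(length(chars))
  qual <- r$values %in% rules$homopolymer_bases &
    r$lengths >= rules$homopolymer_min
  for (i in which(qual)) {
    from <- max(1L, starts[i] - rules$margin)
    to <- min(length(chars), ends[i] + rules$margin)
    mask[from:to] <- TRUE
  }
  mask
}

# Shared flag logic: the change's reference footprint (expanded to the
# adjacent base for insertions, whose placement is boundary-ambiguous).
flag_homopolymer <- function(ref_pos, type, ref, mask) {
  len <- length(mask)
  vapply(seq_along(ref_pos), function(i) {
    if (type[i] == "insertion") {
      span <- c(ref_pos[i], ref_pos[i] + 1L)  # flanking bases, 0-based
    } else {
      span <- seq(ref_pos[i] + 1L, ref_pos[i] + max(1L, nchar(ref[i])))
    }
    span <- span[span >= 1L & span <= len]
    any(mask[span])
  }, logical(1))
}

#' Diff an NGS contig against a validated reference chromosome
#'
#' Globally aligns the contig to the reference (at the best rotation when the
#' reference is circular, via a contig-global/reference-local alignment
#' against the doubled reference) and reports each discrepancy as one change
#' record; a maximal gap run is a single insertion or deletion regardless of
#' length.
#'
#' @param contig DNA string (or `sequence_record`).
#' @param reference A `chromosome` or `sequence_record`.
#' @param scoring An [align_scoring()].
#' @return data.frame of change records: `type`
#'   (substitution/insertion/deletion), `contig_pos`, `ref_pos` (0-based;
#'   for insertions the reference position before which bases were inserted),
#'   `ref`, `alt`.
#' @export
diff_contig <- function(contig, reference, scoring = align_scoring()) {
  if (inherits(contig, "sequence_record")) contig <- contig$residues
  rec <- if (inherits(reference, "chromosome")) reference$record else reference
  if (!nchar(contig) || !nchar(rec$residues)) {
    stop("diff_contig: empty sequence")
  }
  len <- nchar(rec$residues)
  circular <- rec$topology == "circular"
  subject <- if (circular) strrep(rec$residues, 2L) else rec$residues
  letters <- c("A", "C", "G", "T", "N")
  mat <- matrix(scoring$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(mat) <- scoring$match
  mat["N", ] <- 0; mat[, "N"] <- 0
  aln <- Biostrings::pairwiseAlignment(
    pattern = contig, subject = subject,
    type = if (circular) "global-local" else "global",
    substitutionMatrix = mat,
    gapOpening = abs(scoring$gap_open),
    gapExtension = abs(scoring$gap_extend))
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sub_start <- BiocGenerics::start(Biostrings::subject(aln)) - 1L  # 0-based
  covered <- sum(sa != "-")
  if (covered < 0.5 * len) {
    stop("diff_contig: alignment covers ", covered, "/", len,
         " reference bases (< 50%)")
  }
  cp <- 0L  # contig bases consumed
  rp <- sub_start  # reference bases consumed (doubled coordinates)
  rows <- list()
  i <- 1L
  n <- length(pa)
  wrap <- function(x) if (circular) x %% len else x
  while (i <= n) {
    if (pa[i] != "-" && sa[i] != "-") {
      if (pa[i] != sa[i]) {
        rows[[length(rows) + 1L]] <- data.frame(
          type = "substitution", contig_pos = cp, ref_pos = wrap(rp),
          ref = sa[i], alt = pa[i], stringsAsFactors = FALSE)
      }
      cp <- cp + 1L; rp <- rp + 1L; i <- i + 1L
    } else if (sa[i] == "-") {
      j <- i
      while (j <= n && sa[j] == "-") j <- j + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        type = "insertion", contig_pos = cp, ref_pos = wrap(rp),
        ref = "", alt = paste(pa[i:(j - 1L)], collapse = ""),
        stringsAsFactors = FALSE)
      cp <- cp + (j - i); i <- j
    } else {
      j <- i
      while (j <= n && pa[j] == "-") j <- j + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        type = "deletion", contig_pos = cp, ref_pos = wrap(rp),
        ref = paste(sa[i:(j - 1L)], collapse = ""), alt = "",
        stringsAsFactors = FALSE)
      rp <- rp + (j - i); i <- j
    }
  }
  if (!length(rows)) {
    return(data.frame(type = character(0), contig_pos = integer(0),
                      ref_pos = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Classify contig changes by position and homopolymer context
#'
#' Flags each change as terminal (within the first or last
#' `terminal_window` nt of the contig) and/or homopolymer-associated (within,
#' or immediately adjacent to, a qualifying A/T run in the reference); the
#' flags are independent. Returns the annotated records and the category
#' counts used for error-rate estimation.
#'
#' @param changes data.frame from [diff_contig()] (or planted truth).
#' @param contig_length Contig length in bp.
#' @param reference A `chromosome` or `sequence_record`.
#' @param rules An [audit_rules()].
#' @return List with `changes` (annotated data.frame with logical `terminal`,
#'   `homopolymer`) and `counts` (`total`, `terminal`, `homopolymer`, `both`,
#'   `neither`).
#' @export
classify_changes <- function(changes, contig_length, reference,
                             rules = audit_rules()) {
  rec <- if (inherits(reference, "chromosome")) reference$record else reference
  if (nrow(changes)) {
    stopifnot(all(changes$contig_pos >= 0),
              all(changes$contig_pos <= contig_length),
              all(changes$ref_pos >= 0),
              all(changes$ref_pos <= nchar(rec$residues)))
  }
  mask <- homopolymer_mask(rec$residues, rules)
  w <- rules$terminal_window
  terminal <- changes$contig_pos < w |
    changes$contig_pos >= contig_length - w
  homopolymer <- if (nrow(changes)) {
    flag_homopolymer(changes$ref_pos, changes$type, changes$ref, mask)
  } else logical(0)
  changes$terminal <- terminal
  changes$homopolymer <- homopolymer
  counts <- list(total = nrow(changes),
                 terminal = sum(terminal),
                 homopolymer = sum(homopolymer),
                 both = sum(terminal & homopolymer),
                 neither = sum(!terminal & !homopolymer))
  list(changes = changes, counts = counts)
}

#' Raw and context-filtered NGS error rates
#'
#' The raw rate is all changes over the reference length; the filtered rate
#' keeps only changes explained by neither the contig-terminal nor the
#' homopolymer context, i.e. the residual error after discounting the two
#' known artefact classes.
#'
#' @param counts Category counts from [classify_changes()] (or a list with
#'   `total` and `neither`).
#' @param reference_length Reference chromosome length in bp.
#' @return List with `raw` and `filtered`, in percent.
#' @export
error_rates <- function(counts, reference_length) {
  stopifnot(reference_length > 0)
  list(raw = 100 * counts$total / reference_length,
       filtered = 100 * counts$neither / reference_length)
}
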