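#' Configuration for the synthetic mitogenome generator
#'
#' Defines the study-like conditions the generator emulates: a 37-gene +
#' control-region circular mitogenome with a thrips-like gene order, A+T
#' content in the high-70s, and gene lengths typical of insect mitogenomes
#' chosen so that a nad6 mini-circle of roughly 0.9-1.0 kb and main
#' chromosomes of 14-15.5 kb emerge naturally.
#'
#' @param seed Mandatory integer seed; the generator is fully deterministic
#'   given the config.
#' @param gene_lengths Named integer vector, gene token -> bp.
#' @param at_target Target whole-genome A+T percent in `[50, 95]`.
#' @param order_template A `gene_order` giving the ancestral arrangement
#'   (default: the thrips arrangement with nad6 and trnC at their ancestral
#'   location and all tRNAs on the J strand except the shared N-strand
#'   nad5-nad4L cluster).
#' @param control_at_boost Extra A+T percentage points for the control region
#'   (A+T-rich region), capped at 95% total.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(seed, gene_lengths = default_gene_lengths(),
                             at_target = 77,
                             order_template = thrips_order_template(),
                             control_at_boost = 12) {
  if (missing(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    stop("generator_config: integer seed is mandatory")
  }
  stopifnot(at_target >= 50, at_target <= 95, all(gene_lengths >= 1))
  structure(list(seed = as.integer(seed), gene_lengths = gene_lengths,
                 at_target = at_target, order_template = order_template,
                 control_at_boost = control_at_boost),
            class = "generator_config")
}

#' @rdname generator_config
#' @export
default_gene_lengths <- function() {
  lens <- c(cox1 = 1530L, cox2 = 680L, cox3 = 780L, cob = 1130L,
            nad1 = 930L, nad2 = 980L, nad3 = 350L, nad4 = 1330L,
            nad4L = 280L, nad5 = 1700L, nad6 = 460L, atp6 = 670L,
            atp8 = 160L, rrnS = 780L, rrnL = 1250L, control_region = 330L)
  trna <- rep(65L, length(trna_genes()))
  names(trna) <- trna_genes()
  c(lens, trna)
}

#' @rdname generator_config
#' @export
thrips_order_template <- function() {
  order_from_tokens(
    c("cox1", "nad3", "trnL2", "cox2", "trnD", "trnR", "trnG", "trnK",
      "cox3", "trnI", "trnL1", "trnT", "trnP", "trnN", "trnE", "trnQ",
      "cob", "trnY", "nad2", "trnW", "nad1", "trnM", "trnA", "trnF",
      "rrnS", "atp8", "atp6", "trnS1", "control_region", "-nad5", "-trnH",
      "-nad4", "-nad4L", "trnC", "nad6", "trnV", "rrnL", "trnS2"),
    id = "ancestor_chr1")
}

random_dna <- function(n, at_fraction) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at_fraction / 2, at_fraction / 2,
                        (1 - at_fraction) / 2, (1 - at_fraction) / 2)),
        collapse = "")
}

# Control region: elevated A+T, a T-stretch, and an A+T-rich segment -- the
# motifs that distinguish a true control region from other noncoding DNA.
random_control_region <- function(n, at_fraction) {
  at <- min(at_fraction + 0.12, 0.95)
  body <- random_dna(n, at)
  t_stretch <- strrep("T", 14L)
  rich <- random_dna(min(60L, max(10L, n %/% 5L)), 0.96)
  pos1 <- max(1L, n %/% 10L)
  pos2 <- max(pos1 + nchar(t_stretch) + 5L, n %/% 2L)
  body <- `substr<-`(body, pos1, pos1 + nchar(t_stretch) - 1L, value = t_stretch)
  if (pos2 + nchar(rich) - 1L <= n) {
    body <- `substr<-`(body, pos2, pos2 + nchar(rich) - 1L, value = rich)
  }
  body
}

# Internal gene-list representation: per chromosome, an ordered list of
# parts (name, kind, strand, seq read 5'->3' on the coding strand). The
# generator produces gap-free chromosomes, so parts tile the molecule.
disassemble_genome <- function(genome) {
  lapply(genome$chromosomes, function(ch) {
    list(id = ch$record$id, topology = ch$record$topology,
         parts = lapply(ch$features, function(f) {
           list(name = f$name, kind = f$kind, strand = f$strand,
                seq = feature_seq(ch, f))
         }))
  })
}

assemble_genome <- function(label, chrom_parts) {
  chroms <- lapply(chrom_parts, function(cp) {
    segs <- vapply(cp$parts, function(p) {
      if (p$strand == "N") revcomp(p$seq) else p$seq
    }, character(1))
    lens <- nchar(segs)
    ends <- cumsum(lens)
    starts <- ends - lens
    feats <- lapply(seq_along(cp$parts), function(i) {
      gene_feature(cp$parts[[i]]$name, cp$parts[[i]]$strand,
                   starts[i], ends[i], kind = cp$parts[[i]]$kind)
    })
    chromosome(sequence_record(cp$id, paste(segs, collapse = ""),
                               cp$topology %||% "circular"), feats)
  })
  mito_genome(label, chroms)
}

#' Generate a synthetic ancestral mitogenome
#'
#' A single circular chromosome whose gene order equals the config's template,
#' with i.i.d. A/T-biased sequence per gene and a control region carrying a
#' T-stretch and an A+T-rich segment. Fully deterministic given the config.
#'
#' @param config A [generator_config()].
#' @param label Genome label.
#' @return A `mito_genome` passing the 37-gene completeness check.
#' @export
generate_ancestor <- function(config, label = "ancestor") {
  set.seed(config$seed)
  at <- config$at_target / 100
  tmpl <- config$order_template$chromosomes[[1]]
  parts <- lapply(seq_along(tmpl$genes), function(i) {
    g <- tmpl$genes[i]
    n <- config$gene_lengths[[g]]
    if (is.null(n)) stop("generate_ancestor: no length for gene ", g)
    seq <- if (g == "control_region") random_control_region(n, at)
           else random_dna(n, at)
    list(name = g, kind = gene_kind(g),
         strand = if (tmpl$signs[i] < 0) "N" else "J", seq = seq)
  })
  assemble_genome(label, list(list(id = paste0(label, "_chr1"),
                                   topology = "circular", parts = parts)))
}

#' Plant substitutions (and optionally indels) into a sequence
#'
#' Substitutes `round(percent/100 * L)` distinct sites to a different base, so
#' that the realized divergence under the homolog statistic equals the target
#' up to rounding. Optional indel events (each one difference under the
#' indel-collapse rule) have geometric lengths with the given mean.
#'
#' @param seq DNA string.
#' @param percent Target divergence percent.
#' @param n_indels Number of indel events to plant.
#' @param indel_mean Mean indel length (geometric).
#' @param at_fraction A/T-biased equilibrium from which replacement bases are
#'   drawn (conditioned on differing from the original), so that repeated
#'   substitution holds the genome near its target composition.
#' @return Mutated sequence.
#' @export
mutate_seq <- function(seq, percent, n_indels = 0L, indel_mean = 3,
                       at_fraction = 0.77) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  chars <- substitute_sites(chars, round(percent / 100 * L), at_fraction)
  if (n_indels > 0) {
    for (i in seq_len(n_indels)) {
      len <- 1L + stats::rgeom(1L, 1 / indel_mean)
      pos <- sample.int(max(1L, length(chars) - len - 1L), 1L)
      if (stats::runif(1) < 0.5 && length(chars) > len + 2L) {
        chars <- chars[-(pos:(pos + len - 1L))]
      } else {
        ins <- strsplit(random_dna(len, 0.75), "")[[1]]
        chars <- append(chars, ins, after = pos)
      }
    }
  }
  paste(chars, collapse = "")
}

substitute_sites <- function(chars, k, at_fraction) {
  k <- max(0L, min(as.integer(k), length(chars)))
  if (k == 0L) return(chars)
  sites <- sample.int(length(chars), k)
  bases <- c("A", "T", "C", "G")
  probs <- c(at_fraction / 2, at_fraction / 2,
             (1 - at_fraction) / 2, (1 - at_fraction) / 2)
  chars[sites] <- vapply(chars[sites], function(b) {
    keep <- bases != b
    sample(bases[keep], 1L, prob = probs[keep])
  }, character(1))
  chars
}

# Plant substitutions so that the *realized* divergence -- the percent the
# homolog statistic reports after optimal re-alignment, including tRNA
# terminus trimming -- lands on the target. At high divergence an optimal
# alignment explains some substitutions away as indels, so the planted count
# is calibrated by measure-and-adjust with rejection (capped), keeping the
# best realization seen.
calibrate_divergence <- function(seq, percent, kind, tol = 0.9,
                                 max_tries = 100L) {
  if (percent <= 0) return(seq)
  at <- at_content(seq) / 100
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  k <- round(percent / 100 * L)
  best <- seq; best_err <- Inf
  for (t in seq_len(max_tries)) {
    cand <- paste(substitute_sites(chars, k, at), collapse = "")
    aln <- align_homologs(seq, cand, kind = kind)
    if (identical(kind, "tRNA")) aln <- trim_trna_termini(aln)
    realized <- homolog_divergence(aln)$percent
    err <- abs(realized - percent)
    if (err < best_err) { best <- cand; best_err <- err }
    if (err <= tol) break
    step <- round((percent - realized) / 100 * L)
    if (step == 0L) step <- sign(percent - realized)
    k <- max(0L, min(L, k + step))
  }
  best
}

#' Evolve a genome pair with planted, recorded truth
#'
#' Copies the ancestor into lineage A unchanged and derives lineage B by
#' applying the requested rearrangement events and per-homolog divergences.
#' Events: `list(kind = "inversion", gene =)`, `list(kind = "translocation",
#' gene =, after =)`, or `list(kind = "fission", move =, duplicate =,
#' paralog_divergence =)`. No two events may touch the same gene. Divergence
#' is planted as substitutions, so the realized per-homolog divergence (by
#' [homolog_divergence()]) equals its target up to rounding (within one
#' percentage point).
#'
#' @param ancestor A `mito_genome` (unipartite).
#' @param events List of planted events (possibly empty).
#' @param divergence Named numeric vector, homolog -> target percent; homologs
#'   not named get 0.
#' @param seed Integer seed.
#' @param labels Labels for the two output genomes.
#' @return List with `a`, `b` (`mito_genome`s) and `truth`
#'   (`planted_events`, `planted_divergence`, `seed`).
#' @export
evolve_pair <- function(ancestor, events = list(), divergence = numeric(0),
                        seed, labels = c("lineage_A", "lineage_B")) {
  set.seed(seed)
  all_genes <- genome_features(ancestor)$name
  touched <- character(0)
  for (ev in events) {
    ev_genes <- c(ev$gene, ev$move, ev$duplicate)
    missing <- setdiff(ev_genes, all_genes)
    if (length(missing)) {
      stop("evolve_pair: event touches absent gene(s): ",
           paste(missing, collapse = ", "))
    }
    if (length(intersect(ev_genes, touched))) {
      stop("evolve_pair: conflicting events touch gene(s): ",
           paste(intersect(ev_genes, touched), collapse = ", "))
    }
    touched <- c(touched, ev_genes)
  }
  bad_div <- setdiff(names(divergence), all_genes)
  if (length(bad_div)) {
    stop("evolve_pair: divergence target for absent gene(s): ",
         paste(bad_div, collapse = ", "))
  }

  a <- ancestor; a$label <- labels[1]
  parts <- disassemble_genome(ancestor)
  fission <- NULL
  for (ev in events) {
    if (ev$kind == "inversion") {
      parts <- apply_inversion(parts, ev$gene)
    } else if (ev$kind == "translocation") {
      parts <- apply_translocation(parts, ev$gene, ev$after)
    } else if (ev$kind == "fission") {
      fission <- ev
    } else {
      stop("evolve_pair: unknown event kind '", ev$kind, "'")
    }
  }
  # plant per-homolog divergence as substitutions
  for (ci in seq_along(parts)) {
    for (pi in seq_along(parts[[ci]]$parts)) {
      g <- parts[[ci]]$parts[[pi]]$name
      pct <- if (g %in% names(divergence)) divergence[[g]] else 0
      if (pct > 0) {
        parts[[ci]]$parts[[pi]]$seq <-
          calibrate_divergence(parts[[ci]]$parts[[pi]]$seq, pct,
                               parts[[ci]]$parts[[pi]]$kind)
      }
    }
  }
  for (ci in seq_along(parts)) {
    parts[[ci]]$id <- sub(ancestor$label, labels[2], parts[[ci]]$id,
                          fixed = TRUE)
  }
  b <- assemble_genome(labels[2], parts)
  if (!is.null(fission)) {
    b <- fission_minicircle(b, move = fission$move,
                            duplicate = fission$duplicate,
                            paralog_divergence =
                              fission$paralog_divergence %||% 0,
                            seed = seed + 1L)
  }
  truth <- list(planted_events = events, planted_divergence = divergence,
                seed = seed)
  list(a = a, b = b, truth = truth)
}

apply_inversion <- function(parts, gene) {
  for (ci in seq_along(parts)) {
    for (pi in seq_along(parts[[ci]]$parts)) {
      if (parts[[ci]]$parts[[pi]]$name == gene) {
        parts[[ci]]$parts[[pi]]$strand <-
          if (parts[[ci]]$parts[[pi]]$strand == "J") "N" else "J"
        return(parts)
      }
    }
  }
  stop("apply_inversion: gene not found: ", gene)
}

apply_translocation <- function(parts, gene, after) {
  moved <- NULL
  for (ci in seq_along(parts)) {
    idx <- which(vapply(parts[[ci]]$parts, `[[`, character(1), "name") == gene)
    if (length(idx)) {
      moved <- parts[[ci]]$parts[[idx[1]]]
      parts[[ci]]$parts[[idx[1]]] <- NULL
      break
    }
  }
  if (is.null(moved)) stop("apply_translocation: gene not found: ", gene)
  for (ci in seq_along(parts)) {
    names_ci <- vapply(parts[[ci]]$parts, `[[`, character(1), "name")
    at <- which(names_ci == after)
    if (length(at)) {
      parts[[ci]]$parts <- append(parts[[ci]]$parts, list(moved),
                                  after = at[1])
      return(parts)
    }
  }
  stop("apply_translocation: target gene not found: ", after)
}

#' Fission a mini-circle chromosome out of a unipartite genome
#'
#' Moves the `move` genes onto a new small circular chromosome and places
#' duplicated copies of the `duplicate` features (e.g. the control region and
#' trnS1) on it, mutated to the requested paralog divergence; the originals
#' stay on chromosome 1. Emulates the fission that created the nad6
#' mini-circle: the bipartite genome still passes the 37-gene completeness
#' check, with the moved genes absent from chromosome 1.
#'
#' @param genome A unipartite `mito_genome`.
#' @param move Genes to move (absent from chromosome 1 afterwards).
#' @param duplicate Features to duplicate onto the mini-circle.
#' @param paralog_divergence Target percent divergence between duplicate
#'   copies, realized within 0.5 points: a scalar applied to every duplicated
#'   feature, or a vector named by feature.
#' @param seed Integer seed.
#' @return A bipartite `mito_genome` (unchanged if `move` and `duplicate` are
#'   both empty).
#' @export
fission_minicircle <- function(genome, move, duplicate,
                               paralog_divergence = 0, seed = 1L) {
  if (length(genome$chromosomes) != 1L) {
    stop("fission_minicircle: genome must be unipartite")
  }
  if (!length(move) && !length(duplicate)) return(genome)
  present <- genome_features(genome)$name
  missing <- setdiff(c(move, duplicate), present)
  if (length(missing)) {
    stop("fission_minicircle: gene(s) absent from genome: ",
         paste(missing, collapse = ", "))
  }
  set.seed(seed)
  parts <- disassemble_genome(genome)[[1]]
  names_all <- vapply(parts$parts, `[[`, character(1), "name")
  mini <- parts$parts[names_all %in% move]
  dups <- lapply(parts$parts[names_all %in% duplicate], function(p) {
    pd <- if (!is.null(names(paralog_divergence))) {
      if (p$name %in% names(paralog_divergence)) {
        paralog_divergence[[p$name]]
      } else 0
    } else paralog_divergence
    p$seq <- mutate_seq(p$seq, pd, at_fraction = at_content(p$seq) / 100)
    p
  })
  chr1_parts <- parts$parts[!names_all %in% move]
  assemble_genome(genome$label, list(
    list(id = parts$id, topology = "circular", parts = chr1_parts),
    list(id = paste0(genome$label, "_chr2"), topology = "circular",
         parts = c(mini, dups))
  ))
}

#' Merge a mini-circle back into chromosome 1
#'
#' Builds the unipartite model of a bipartite genome by inserting the
#' mini-circle's non-redundant genes into chromosome 1 after a named gene
#' (their proposed ancestral location) and dropping the mini-circle together
#' with its duplicated paralog copies. This is the single-chromosome null
#' hypothesis tested by the in-silico PCR architecture test: it carries the
#' bipartite genome's own sequences, so primers designed on them anneal
#' exactly.
#'
#' @param genome A bipartite `mito_genome` (2 chromosomes; the smaller one is
#'   taken as the mini-circle).
#' @param after Gene on chromosome 1 after which the moved genes are
#'   reinserted.
#' @return A unipartite `mito_genome`.
#' @export
merge_minicircle <- function(genome, after = "nad4L") {
  if (length(genome$chromosomes) != 2L) {
    stop("merge_minicircle: genome must be bipartite")
  }
  sizes <- vapply(genome$chromosomes, function(ch) nchar(ch$record$residues),
                  numeric(1))
  main_i <- which.max(sizes)
  parts <- disassemble_genome(genome)
  main <- parts[[main_i]]
  mini <- parts[[setdiff(1:2, main_i)]]
  main_names <- vapply(main$parts, `[[`, character(1), "name")
  moved <- Filter(function(p) !p$name %in% main_names, mini$parts)
  at <- which(main_names == after)
  if (!length(at)) stop("merge_minicircle: gene not found: ", after)
  main$parts <- append(main$parts, moved, after = at[1])
  assemble_genome(genome$label,
                  list(list(id = main$id, topology = "circular",
                            parts = main$parts)))
}

#' Insert a species-specific noncoding region into a genome
#'
#' Adds a random noncoding feature (no control-region motifs) after a named
#' gene, emulating the long non-homologous noncoding regions observed in the
#' two cryptic-species genomes.
#'
#' @param genome A `mito_genome`.
#' @param after Gene token after which to insert.
#' @param length Length in bp.
#' @param name Feature name (kind is `noncoding`).
#' @param strand `"J"` or `"N"`.
#' @param at_fraction A+T fraction of the random filler.
#' @return Modified `mito_genome`.
#' @export
insert_noncoding <- function(genome, after, length, name, strand = "J",
                             at_fraction = 0.75) {
  parts <- disassemble_genome(genome)
  nc <- list(name = name, kind = "noncoding", strand = strand,
             seq = random_dna(length, at_fraction))
  for (ci in seq_along(parts)) {
    names_ci <- vapply(parts[[ci]]$parts, `[[`, character(1), "name")
    at <- which(names_ci == after)
    if (length(at)) {
      parts[[ci]]$parts <- append(parts[[ci]]$parts, list(nc), after = at[1])
      return(assemble_genome(genome$label, parts))
    }
  }
  stop("insert_noncoding: gene not found: ", after)
}

#' Simulate an NGS-style contig with planted errors
#'
#' Plants sequencing errors into a copy of the chromosome at a per-site base
#' rate, multiplied in the first/last `terminal_window` nucleotides and inside
#' (or within one base of) A/T homopolymer runs of at least
#' `homopolymer_min` nt -- the two contexts in which Ion Torrent-style contig
#' errors concentrate. Homopolymer errors are mostly single-base indels
#' (run-length miscounts); elsewhere substitutions dominate. Planted changes
#' are separated by at least three bases so each maps to one
#' alignment-resolvable change record.
#'
#' @param chrom A `chromosome`.
#' @param base_error Per-site error rate outside enriched contexts.
#' @param terminal_multiplier,homopolymer_multiplier Rate multipliers (>= 1).
#' @param seed Integer seed.
#' @param rules An [audit_rules()] (defines windows/runs).
#' @return List with `contig` (DNA string) and `truth` (data.frame of planted
#'   `change_record`-style rows with `type`, `contig_pos`, `ref_pos`, `ref`,
#'   `alt`, `terminal`, `homopolymer`).
#' @export
simulate_contig <- function(chrom, base_error = 0.005,
                            terminal_multiplier = 5,
                            homopolymer_multiplier = 6, seed,
                            rules = audit_rules()) {
  stopifnot(base_error >= 0, base_error <= 1,
            terminal_multiplier >= 1, homopolymer_multiplier >= 1)
  set.seed(seed)
  ref <- chrom$record$residues
  len <- nchar(ref)
  chars <- strsplit(ref, "")[[1]]
  hp <- homopolymer_mask(ref, rules)
  term <- seq_len(len) <= rules$terminal_window |
    seq_len(len) > len - rules$terminal_window
  p <- pmin(base_error * ifelse(term, terminal_multiplier, 1) *
              ifelse(hp, homopolymer_multiplier, 1), 0.9)
  hit <- which(stats::runif(len) < p)
  # enforce spacing so adjacent edits stay alignment-resolvable
  if (length(hit) > 1L) {
    keep <- c(TRUE, diff(hit) >= 3L)
    while (!all(keep)) {
      hit <- hit[keep]
      keep <- c(TRUE, diff(hit) >= 3L)
    }
  }
  out <- chars
  ins_before <- rep("", len)
  records <- list()
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    type <- if (hp[i]) {
      sample(c("substitution", "insertion", "deletion"), 1L,
             prob = c(0.3, 0.35, 0.35))
    } else {
      sample(c("substitution", "insertion", "deletion"), 1L,
             prob = c(0.8, 0.1, 0.1))
    }
    # indels in the outermost bases are alignment-ambiguous (a terminal gap
    # can be traded for mismatches); plant substitutions there instead
    if (i <= 3L || i > len - 3L) type <- "substitution"
    if (type == "substitution") {
      alt <- sample(setdiff(bases, chars[i]), 1L)
      out[i] <- alt
      records[[length(records) + 1L]] <-
        list(type = type, ref_pos = i - 1L, ref = chars[i], alt = alt)
    } else if (type == "deletion") {
      out[i] <- ""
      records[[length(records) + 1L]] <-
        list(type = type, ref_pos = i - 1L, ref = chars[i], alt = "")
    } else {
      ins <- if (hp[i]) chars[i] else sample(bases, 1L)
      ins_before[i] <- ins
      records[[length(records) + 1L]] <-
        list(type = type, ref_pos = i - 1L, ref = "", alt = ins)
    }
  }
  pieces <- paste0(ins_before, out)
  contig <- paste(pieces, collapse = "")
  # contig coordinate of each reference position's emitted piece
  piece_starts <- cumsum(c(0L, nchar(pieces)))[seq_len(len)]
  truth <- data.frame(type = character(0), contig_pos = integer(0),
                      ref_pos = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE)
  if (length(records)) {
    truth <- do.call(rbind, lapply(records, function(r) {
      cp <- piece_starts[r$ref_pos + 1L]
      if (r$type == "deletion") cp <- cp  # position following the lost base
      data.frame(type = r$type, contig_pos = cp, ref_pos = r$ref_pos,
                 ref = r$ref, alt = r$alt, stringsAsFactors = FALSE)
    }))
  }
  clen <- nchar(contig)
  truth$terminal <- truth$contig_pos < rules$terminal_window |
    truth$contig_pos >= clen - rules$terminal_window
  truth$homopolymer <- flag_homopolymer(truth$ref_pos, truth$type,
                                        truth$ref, hp)
  list(contig = contig, truth = truth,
       seed = seed, reference = chrom$record$id)
}
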