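# Independent oracles used to validate the package's algorithms on small
# inputs. Everything here is deliberately written without reference to the
# package internals.

# Score an explicit alignment (two equal-length gapped character vectors)
# under match/mismatch plus affine gaps: each maximal gap run of length k
# costs open + k * extend.
oracle_score_cols <- function(ca, cb, match = 1, mismatch = -1,
                              open = -2, extend = -0.5) {
  s <- 0
  for (i in seq_along(ca)) {
    if (ca[i] != "-" && cb[i] != "-") {
      s <- s + if (ca[i] == cb[i]) match else mismatch
    }
  }
  for (row in list(ca, cb)) {
    r <- rle(row == "-")
    runs <- r$lengths[r$values]
    s <- s + length(runs) * open + sum(runs) * extend
  }
  s
}

# Exhaustive enumeration of all global alignments of two short sequences;
# returns the optimal score. Exponential -- intended for sequences <= 6 nt.
oracle_best_score <- function(a, b, match = 1, mismatch = -1,
                              open = -2, extend = -0.5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, cols_a, cols_b) {
    if (i > length(ca) && j > length(cb)) {
      s <- oracle_score_cols(cols_a, cols_b, match, mismatch, open, extend)
      if (s > best) best <<- s
      return(invisible(NULL))
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1L, j + 1L, c(cols_a, ca[i]), c(cols_b, cb[j]))
    }
    if (i <= length(ca)) rec(i + 1L, j, c(cols_a, ca[i]), c(cols_b, "-"))
    if (j <= length(cb)) rec(i, j + 1L, c(cols_a, "-"), c(cols_b, cb[j]))
  }
  rec(1L, 1L, character(0), character(0))
  best
}

# Column-walk divergence counter: mismatch columns are one difference each,
# each maximal gap run is one difference; effective columns = columns - gap
# columns + gap runs.
oracle_divergence <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  gap <- ca == "-" | cb == "-"
  subs <- sum(!gap & ca != cb)
  r <- rle(gap)
  runs <- sum(r$values)
  eff <- length(ca) - sum(gap) + runs
  list(substitutions = subs, indels = runs, effective = eff,
       percent = 100 * (subs + runs) / eff)
}

# --- Minimal-event-count oracle on toy signed circular gene orders --------
# States are signed circular orders (single chromosome); operations are
# single-gene inversions and single-gene translocations (any new position,
# sign kept). Breadth-first search gives the true minimal event count.

oracle_canonical <- function(tokens) {
  # canonical form of a signed circular order: all rotations of both the
  # order and its reflected complement, lexicographically smallest
  n <- length(tokens)
  variants <- character(0)
  flip <- function(t) {
    rev(vapply(t, function(x) {
      if (startsWith(x, "-")) sub("^-", "", x) else paste0("-", x)
    }, character(1), USE.NAMES = FALSE))
  }
  for (form in list(tokens, flip(tokens))) {
    for (r in seq_len(n)) {
      rot <- form[((seq_len(n) + r - 2L) %% n) + 1L]
      variants <- c(variants, paste(rot, collapse = " "))
    }
  }
  min(variants)
}

oracle_neighbors <- function(tokens) {
  n <- length(tokens)
  out <- list()
  for (i in seq_len(n)) {
    t2 <- tokens
    t2[i] <- if (startsWith(t2[i], "-")) sub("^-", "", t2[i])
             else paste0("-", t2[i])
    out[[length(out) + 1L]] <- t2
  }
  for (i in seq_len(n)) {
    rest <- tokens[-i]
    for (j in 0:(n - 2L)) {
      out[[length(out) + 1L]] <- append(rest, tokens[i], after = j)
    }
  }
  out
}

oracle_min_events <- function(from, to, max_depth = 3L) {
  target <- oracle_canonical(to)
  frontier <- list(from)
  seen <- oracle_canonical(from)
  if (seen == target) return(0L)
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (state in frontier) {
      for (nb in oracle_neighbors(state)) {
        key <- oracle_canonical(nb)
        if (key == target) return(depth)
        if (!key %in% seen) {
          seen <- c(seen, key)
          nxt[[length(nxt) + 1L]] <- nb
        }
      }
    }
    frontier <- nxt
  }
  NA_integer_
}

random_dna_str <- function(n, at = 0.6) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}
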