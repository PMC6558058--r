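#' Oligonucleotide melting temperature by the Wallace rule
#'
#' `Tm = 4 * (#G + #C) + 2 * (#A + #T)` degrees C, the classical short-oligo
#' approximation used to characterize the spread of probe melting
#' temperatures within a probe set.
#'
#' @param sequence character vector of DNA sequences (A/C/G/T only).
#' @return numeric Tm in degrees C.
#' @export
wallace_tm <- function(sequence) {
  check_dna(sequence)
  up <- toupper(sequence)
  gc <- nchar(gsub("[AT]", "", up))
  at <- nchar(up) - gc
  4 * gc + 2 * at
}

check_dna <- function(sequence) {
  if (!is.character(sequence) || any(is.na(sequence)) ||
      any(!grepl("^[ACGTacgt]+$", sequence)))
    stop("sequences must be non-empty A/C/G/T strings ",
         "(ambiguity codes are not allowed)")
  invisible(TRUE)
}

revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sequence)))
}

#' Enumerate candidate probes over the conserved regions of an OTU's targets
#'
#' Slides windows of the requested lengths along the OTU's target sequences
#' and keeps windows that are identical across all targets (with several
#' target sequences per OTU, only fully conserved windows can probe the OTU
#' as a whole). The probe is the reverse complement of the target window, so
#' it hybridizes the rRNA sense strand. Coordinates are 0-based half-open on
#' the target.
#'
#' @param targets character vector (or `DNAStringSet`) of target sequences
#'   for one OTU; with more than one sequence all must have equal length
#'   (i.e. be aligned without gaps).
#' @param lengths integer vector of probe lengths to enumerate (default
#'   20:25 nt).
#' @param step offset between consecutive window starts (default 1).
#' @return data frame: `target_start` (0-based), `length`, `sequence` (the
#'   probe, reverse complement of the window), `target_window`, `tm`
#'   (Wallace rule). Empty (with a warning) when no conserved window exists.
#' @export
enumerate_candidates <- function(targets, lengths = 20:25, step = 1L) {
  targets <- as.character(targets)
  check_dna(targets)
  targets <- toupper(targets)
  stopifnot(length(targets) >= 1, all(lengths >= 1), step >= 1)
  L <- unique(nchar(targets))
  if (length(L) != 1)
    stop("multiple target sequences must have equal length")
  if (L < max(lengths))
    stop("targets shorter than the maximum probe length")
  chars <- do.call(rbind, strsplit(targets, ""))
  conserved <- apply(chars, 2, function(col)
    length(unique(col)) == 1 && col[1] %in% c("A", "C", "G", "T"))
  # a window [s, s+len) is usable iff every position in it is conserved;
  # run-length prefix sums give this in O(L) per length
  csum <- cumsum(conserved)
  rows <- list()
  for (len in sort(unique(as.integer(lengths)))) {
    starts <- seq(1L, L - len + 1L, by = as.integer(step))
    n_cons <- csum[starts + len - 1L] - c(0, csum)[starts]
    ok <- starts[n_cons == len]
    if (!length(ok)) next
    window <- substring(targets[1], ok, ok + len - 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      target_start = ok - 1L, length = len,
      sequence = revcomp(window), target_window = window,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    warning("no conserved window across the target sequences")
    return(data.frame(target_start = integer(), length = integer(),
                      sequence = character(), target_window = character(),
                      tm = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$tm <- wallace_tm(out$sequence)
  out <- out[order(out$target_start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count non-target sequences hit by a probe within a mismatch budget
#'
#' Counts how many sequences of a database contain at least one ungapped
#' (Hamming) match to the probe with at most `max_mismatches` substitutions,
#' on either strand. Sequences are counted once however many sites they
#' contain; sequences shorter than the probe cannot be hit.
#'
#' @param probe a single A/C/G/T probe sequence.
#' @param db character vector or `DNAStringSet` of non-target sequences.
#' @param max_mismatches allowed substitutions (the screening rules use 0
#'   and 2).
#' @return integer number of sequences hit.
#' @export
count_offtarget <- function(probe, db, max_mismatches = 0L) {
  stopifnot(length(probe) == 1, max_mismatches >= 0)
  check_dna(probe)
  db <- Biostrings::DNAStringSet(db)
  if (!length(db)) return(0L)
  long_enough <- Biostrings::width(db) >= nchar(probe)
  if (!any(long_enough)) return(0L)
  sub <- db[long_enough]
  # vmatchPattern also reports alignments hanging over the subject ends
  # (out-of-bounds positions count as mismatches); only fully in-bounds
  # Hamming matches qualify as hybridization sites
  hit_any <- function(pattern) {
    m <- Biostrings::vmatchPattern(pattern, sub,
                                   max.mismatch = max_mismatches,
                                   fixed = TRUE)
    w <- Biostrings::width(sub)
    vapply(seq_along(sub), function(i) {
      r <- m[[i]]
      any(BiocGenerics::start(r) >= 1L & BiocGenerics::end(r) <= w[i])
    }, logical(1))
  }
  sum(hit_any(toupper(probe)) | hit_any(revcomp(probe)))
}

#' Screen probe candidates against the specificity rules
#'
#' Applies the off-target specificity rules to each candidate: a probe is
#' accepted when it perfectly matches fewer than `max_perfect` non-target
#' sequences and when probes carrying up to two mismatches match no more than
#' `max_two_mismatch` non-target sequences.
#'
#' @param candidates data frame from [enumerate_candidates()].
#' @param background non-target sequence database (character or
#'   `DNAStringSet`).
#' @param max_perfect exclusive upper bound on perfect off-target hits
#'   (default 5: accepted means fewer than 5).
#' @param max_two_mismatch inclusive upper bound on 2-mismatch off-target
#'   hits (default 100).
#' @return `candidates` with `perfect_hits`, `twomm_hits`, `accepted` added.
#' @export
screen_candidates <- function(candidates, background, max_perfect = 5L,
                              max_two_mismatch = 100L) {
  background <- Biostrings::DNAStringSet(background)
  candidates$perfect_hits <- vapply(
    candidates$sequence, count_offtarget, integer(1), db = background,
    max_mismatches = 0L, USE.NAMES = FALSE)
  candidates$twomm_hits <- vapply(
    candidates$sequence, count_offtarget, integer(1), db = background,
    max_mismatches = 2L, USE.NAMES = FALSE)
  candidates$accepted <- candidates$perfect_hits < max_perfect &
    candidates$twomm_hits <= max_two_mismatch
  candidates
}

#' Select a probe set spread along the target
#'
#' Greedily selects up to `k` accepted candidates so that their target
#' positions are spread as evenly as possible along the region covered by
#' the candidates (each of `k` evenly spaced anchor positions claims the
#' nearest unused candidate), which also yields a spread of melting
#' temperatures. Ties at equal distance prefer the candidate whose Tm is
#' farthest from the already-selected Tms, then break deterministically by
#' (target_start, sequence).
#'
#' @param candidates data frame of accepted candidates (needs
#'   `target_start`, `sequence`, `tm`).
#' @param k probe-set size (default 25).
#' @return the selected rows, ordered by `target_start`; fewer than `k` rows
#'   (with a warning) when fewer candidates are available.
#' @export
select_probe_set <- function(candidates, k = 25L) {
  if (!nrow(candidates)) stop("no candidates to select from")
  ord <- order(candidates$target_start, candidates$sequence)
  candidates <- candidates[ord, , drop = FALSE]
  n <- nrow(candidates)
  if (n <= k) {
    if (n < k) warning("only ", n, " candidate(s) available for k = ", k)
    rownames(candidates) <- NULL
    return(candidates)
  }
  lo <- min(candidates$target_start); hi <- max(candidates$target_start)
  anchors <- if (k == 1) (lo + hi) / 2 else seq(lo, hi, length.out = k)
  used <- rep(FALSE, n)
  pick <- integer(0)
  for (a in anchors) {
    d <- abs(candidates$target_start - a)
    d[used] <- Inf
    best <- which(d == min(d))
    if (length(best) > 1 && length(pick)) {
      tm_gap <- vapply(candidates$tm[best], function(tm)
        min(abs(tm - candidates$tm[pick])), numeric(1))
      best <- best[tm_gap == max(tm_gap)]
    }
    best <- best[1]  # candidates are already in (start, sequence) order
    used[best] <- TRUE
    pick <- c(pick, best)
  }
  out <- candidates[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Design a screened probe set for each OTU
#'
#' End-to-end probe design: enumerate conserved-window candidates per OTU,
#' screen them against the non-target background with the specificity rules,
#' and select a positionally spread set of up to `k` accepted probes.
#'
#' @param targets named list of per-OTU target sequence sets (names are OTU
#'   ids; each element a character vector or `DNAStringSet`), or a single
#'   unnamed set for one OTU.
#' @param background non-target database screened against.
#' @param k probes per OTU (default 25).
#' @inheritParams enumerate_candidates
#' @inheritParams screen_candidates
#' @return probe manifest data frame: `probe_id, otu_id, sequence,
#'   target_start, length, tm, perfect_hits, twomm_hits, accepted` (only
#'   selected probes; all have `accepted = TRUE`).
#' @export
design_probes <- function(targets, background, k = 25L, lengths = 20:25,
                          step = 1L, max_perfect = 5L,
                          max_two_mismatch = 100L) {
  if (!is.list(targets)) targets <- list(OTU1 = targets)
  if (is.null(names(targets)) || any(names(targets) == ""))
    stop("targets must be a named list (names are OTU ids)")
  manifests <- lapply(names(targets), function(otu) {
    cand <- enumerate_candidates(targets[[otu]], lengths, step)
    if (!nrow(cand)) return(NULL)
    cand <- screen_candidates(cand, background, max_perfect,
                              max_two_mismatch)
    acc <- cand[cand$accepted, , drop = FALSE]
    if (!nrow(acc)) {
      warning("OTU ", otu, ": no candidate passed the specificity screen")
      return(NULL)
    }
    sel <- select_probe_set(acc, k)
    data.frame(probe_id = sprintf("%s_p%02d", otu, seq_len(nrow(sel))),
               otu_id = otu,
               sel[c("sequence", "target_start", "length", "tm",
                     "perfect_hits", "twomm_hits", "accepted")],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, manifests)
  if (is.null(out)) stop("no probes could be designed for any OTU")
  rownames(out) <- NULL
  out
}

#' Write a probe manifest's sequences to FASTA
#'
#' @param manifest data frame from [design_probes()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_probe_fasta <- function(manifest, path) {
  seqs <- Biostrings::DNAStringSet(manifest$sequence)
  names(seqs) <- manifest$probe_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
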