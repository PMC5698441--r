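# Position-specific scoring matrix construction and sequence scanning for
# candidate 1-4-7-8 CaM-binding sites.

#' Construct a motif scoring matrix
#'
#' @param weights numeric matrix, one row per window position, 20 columns
#'   named with the one-letter amino-acid codes. Weights are nonnegative;
#'   larger means more favourable.
#' @param anchor_offset window index (1-based) of the motif's position-1
#'   anchor residue.
#' @return An object of class `motif_matrix` with fields `weights`,
#'   `width` and `anchor_offset`.
#' @export
motif_matrix <- function(weights, anchor_offset = 1L) {
  weights <- as.matrix(weights)
  if (ncol(weights) != 20) stopf("weights must have 20 columns")
  if (is.null(colnames(weights))) colnames(weights) <- AA1
  weights <- weights[, AA1, drop = FALSE]
  if (any(!is.finite(weights)) || any(weights < 0))
    stopf("weights must be finite and nonnegative")
  if (any(apply(weights, 1, max) <= 0))
    stopf("every position needs a positive maximum weight")
  if (anchor_offset < 1 || anchor_offset > nrow(weights))
    stopf("anchor_offset outside the window")
  out <- list(weights = weights, width = nrow(weights),
              anchor_offset = as.integer(anchor_offset))
  class(out) <- "motif_matrix"
  out
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("motif_matrix: width %d, anchor at window index %d\n",
              x$width, x$anchor_offset))
  invisible(x)
}

#' Default 1-4-7-8 motif matrix
#'
#' Encodes the 1-4-7-8 CaM-recognition pattern over a 15-residue window
#' with the position-1 anchor at window index 4 (three N-terminal and four
#' C-terminal flanking positions, uniformly weighted). The tryptophan
#' anchor at motif position 1 carries the strongest weight in the matrix;
#' motif positions 4, 7 and 8 favour hydrophobic residues (L, I, V, M, F,
#' W, with A and C as intermediate conservative substitutions); lysine and
#' arginine are equally weighted at motif positions 5 and 6 (Q and H
#' intermediate).
#'
#' @param width window width (default 15).
#' @param anchor_offset window index of motif position 1 (default 4).
#' @return A [motif_matrix()].
#' @export
build_default_matrix <- function(width = 15L, anchor_offset = 4L) {
  if (width < anchor_offset + 7)
    stopf("window of width %d cannot hold 8 motif positions from index %d",
          width, anchor_offset)
  w <- matrix(1, nrow = width, ncol = 20, dimnames = list(NULL, AA1))
  mp <- function(k) anchor_offset + k - 1  # motif position -> window index
  hydrophobic <- c("L", "I", "V", "M", "F", "W")
  # position 1: tryptophan anchor dominates the whole matrix;
  # aromatics are tolerated conservative substitutions
  w[mp(1), "W"] <- 50
  w[mp(1), c("F", "Y")] <- 5
  # positions 4, 7, 8: hydrophobic anchors
  for (k in c(4, 7, 8)) {
    w[mp(k), hydrophobic] <- 8
    w[mp(k), c("A", "C")] <- 4
  }
  # positions 5, 6: basic stretch, K and R equal
  for (k in c(5, 6)) {
    w[mp(k), c("K", "R")] <- 6
    w[mp(k), c("Q", "H")] <- 3
  }
  motif_matrix(w, anchor_offset = anchor_offset)
}

#' Consensus window of a matrix
#'
#' The window built from each position's highest-weight residue (first in
#' alphabetical order on ties); it scores 0 under [score_window()].
#'
#' @param matrix a [motif_matrix()].
#' @return Character string of length `matrix$width`.
#' @export
consensus_window <- function(matrix) {
  paste(AA1[apply(matrix$weights, 1, which.max)], collapse = "")
}

#' Score one window against a motif matrix
#'
#' The raw score is the sum over window positions of the weight of the
#' residue observed there; `X` (or any non-canonical letter) contributes
#' the position minimum. The normalized score is
#' `s = (S_best - S) / (S_best - S_worst)` where `S_best` and `S_worst`
#' are the best and worst attainable raw sums, so `s` lies in \[0, 1\]
#' with 0 optimal (lower is better).
#'
#' @param matrix a [motif_matrix()].
#' @param window residue string of length `matrix$width`.
#' @return Normalized score in \[0, 1\].
#' @export
score_window <- function(matrix, window) {
  letters_w <- strsplit(toupper(window), "")[[1]]
  if (length(letters_w) != matrix$width)
    stopf("window length %d does not match matrix width %d",
          length(letters_w), matrix$width)
  score_windows_internal(matrix, matrix(letters_w, nrow = 1))
}

# vectorized scorer: rows of `mat_letters` are windows
#' @noRd
score_windows_internal <- function(matrix, mat_letters) {
  w <- matrix$weights
  pos_min <- apply(w, 1, min)
  pos_max <- apply(w, 1, max)
  denom <- sum(pos_max) - sum(pos_min)
  raw <- numeric(nrow(mat_letters))
  for (p in seq_len(matrix$width)) {
    idx <- match(mat_letters[, p], AA1)
    v <- ifelse(is.na(idx), pos_min[p], w[p, ][idx])
    raw <- raw + v
  }
  if (denom == 0) return(rep(0, nrow(mat_letters)))
  (sum(pos_max) - raw) / denom
}

#' Scan one sequence for motif hits
#'
#' Every full window of the sequence is scored; windows with normalized
#' score `s <= threshold` are returned sorted by ascending score (ties by
#' ascending start). Sequences shorter than the window yield no hits.
#'
#' @param matrix a [motif_matrix()].
#' @param record either a single-row data frame with columns `id`, `seq`
#'   (as from [read_fasta()]) or a plain character sequence.
#' @param threshold maximal normalized score for a hit (default 0.5).
#' @param offset residue number of the first letter of the sequence
#'   (default 1), used to express anchor positions in full-length protein
#'   numbering.
#' @return Data frame with columns `id`, `start`, `anchor_pos`, `window`,
#'   `score`.
#' @export
scan_sequence <- function(matrix, record, threshold = 0.5, offset = 1L) {
  if (is.character(record)) record <- data.frame(id = "seq", seq = record)
  seqc <- toupper(record$seq[1])
  id <- record$id[1]
  n <- nchar(seqc)
  wdt <- matrix$width
  empty <- data.frame(id = character(), start = integer(),
                      anchor_pos = integer(), window = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (n < wdt) return(empty)
  letters_s <- strsplit(seqc, "")[[1]]
  starts <- seq_len(n - wdt + 1)
  win_mat <- t(vapply(starts, function(s) letters_s[s:(s + wdt - 1)],
                      character(wdt)))
  scores <- score_windows_internal(matrix, win_mat)
  keep <- which(scores <= threshold)
  if (length(keep) == 0) return(empty)
  out <- data.frame(
    id = id,
    start = starts[keep] + offset - 1L,
    anchor_pos = starts[keep] + matrix$anchor_offset - 1L + offset - 1L,
    window = vapply(keep, function(i) paste(win_mat[i, ], collapse = ""), ""),
    score = scores[keep],
    stringsAsFactors = FALSE)
  out[order(out$score, out$start), , drop = FALSE]
}

#' Scan a set of sequences and summarize
#'
#' @param matrix a [motif_matrix()].
#' @param records data frame of sequence records (columns `id`, `seq`).
#' @param threshold maximal normalized score for a hit.
#' @return List with `hits` (concatenated per-sequence hits, each sorted
#'   as in [scan_sequence()]) and `summary`: `n_sites`, `median_score`,
#'   `mad_score` (unscaled median absolute deviation of hit scores).
#' @export
scan_proteome <- function(matrix, records, threshold = 0.5) {
  hits <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    scan_sequence(matrix, records[i, , drop = FALSE], threshold)
  }))
  if (is.null(hits))
    hits <- data.frame(id = character(), start = integer(),
                       anchor_pos = integer(), window = character(),
                       score = numeric(), stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  med <- if (nrow(hits) > 0) stats::median(hits$score) else NA_real_
  madu <- if (nrow(hits) > 0) stats::median(abs(hits$score - med)) else NA_real_
  list(hits = hits,
       summary = list(n_sites = nrow(hits), median_score = med,
                      mad_score = madu))
}
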