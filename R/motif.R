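# Core dinucleotide scoring, core-anchored alignment, nucleotide motif
# construction (including database-derived post hoc motifs), log-odds
# scanning and ROC evaluation.

GAP_CHAR <- "-"

.aln_matrix <- function(x) {
  if (is.matrix(x)) {
    return(x)
  }
  if (inherits(x, "core_alignment")) x <- x$rows
  x <- .as_seq(x)
  w <- unique(nchar(x))
  if (length(w) != 1L) stop("aligned sequences must share one width")
  matrix(unlist(strsplit(x, "")), nrow = length(x), byrow = TRUE)
}

#' Rank candidate core dinucleotides in an attB alignment
#'
#' For every adjacent column pair the score equally weights (i) the mean
#' modal-base frequency of the two columns (gaps excluded) and (ii) one
#' minus the pair's distance to the alignment center, normalized by half
#' the alignment width. Pairs are ranked by descending score, ties broken
#' by proximity to the center, then leftmost. Column pairs that are all
#' gaps are skipped.
#'
#' @param alignment Character vector of equal-width aligned sequences
#'   (gap `"-"`), a character matrix, or a `core_alignment`.
#' @return Data frame with 1-based `col_left`, `col_right`,
#'   `conservation`, `distance`, `score`, sorted best-first.
#' @export
score_core_dinucleotides <- function(alignment) {
  m <- .aln_matrix(alignment)
  if (nrow(m) < 2L) stop("need at least two sequences")
  w <- ncol(m)
  if (w < 2L) stop("alignment width must be at least 2")
  modal_freq <- vapply(seq_len(w), function(j) {
    col <- m[, j]
    col <- col[col != GAP_CHAR]
    if (length(col) == 0L) {
      return(NA_real_)
    }
    max(table(col)) / length(col)
  }, numeric(1))
  i <- seq_len(w - 1L)
  conservation <- (modal_freq[i] + modal_freq[i + 1L]) / 2
  midpoint <- (w + 1) / 2
  distance <- abs((i + 0.5) - midpoint) / (w / 2)
  score <- 0.5 * conservation + 0.5 * (1 - distance)
  out <- data.frame(
    col_left = i, col_right = i + 1L,
    conservation = conservation, distance = distance, score = score
  )
  out <- out[!is.na(out$score), , drop = FALSE]
  out <- out[order(-out$score, out$distance, out$col_left), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Align attachment sites on their core dinucleotides
#'
#' Rows are shifted so the 2-bp cores occupy the same columns; flanks are
#' padded with the gap character and no internal gaps are introduced.
#'
#' @param attBs Character vector of attachment-site sequences.
#' @param core_offsets Integer vector of 0-based core offsets, one per
#'   sequence.
#' @return A `core_alignment`: list with `rows` (equal-width padded
#'   strings), `core_col` (1-based column of the core's first base), and
#'   `width`.
#' @export
align_on_core <- function(attBs, core_offsets) {
  attBs <- .as_seq(attBs)
  core_offsets <- as.integer(core_offsets)
  stopifnot(length(attBs) == length(core_offsets))
  lens <- nchar(attBs)
  if (any(core_offsets < 0L | core_offsets + 2L > lens)) {
    stop("core offset out of bounds for its sequence")
  }
  left <- core_offsets
  right <- lens - core_offsets - 2L
  maxl <- max(left)
  maxr <- max(right)
  rows <- paste0(
    strrep(GAP_CHAR, maxl - left), attBs, strrep(GAP_CHAR, maxr - right)
  )
  structure(
    list(rows = rows, core_col = maxl + 1L, width = maxl + 2L + maxr),
    class = "core_alignment"
  )
}

#' Construct a nucleotide motif from a frequency matrix
#'
#' @param freq Numeric matrix, positions x bases (columns A, C, G, T), each
#'   row summing to 1.
#' @param background Named background frequencies (default uniform).
#' @param core_col Optional 1-based column of the core anchor.
#' @return A `nucleotide_motif`.
#' @export
nucleotide_motif <- function(freq, background = NULL, core_col = NA_integer_) {
  freq <- as.matrix(freq)
  stopifnot(ncol(freq) == 4)
  colnames(freq) <- DNA_BASES4
  if (any(abs(rowSums(freq) - 1) > 1e-9)) {
    stop("each motif position's frequencies must sum to 1")
  }
  .new_motif(freq, core_col = core_col, background = background)
}

.new_motif <- function(freq, core_col = NA_integer_, pseudocount = 0.01,
                       background = NULL, uniform_cols = integer(0), ...) {
  if (is.null(background)) {
    background <- stats::setNames(rep(0.25, 4), DNA_BASES4)
  }
  structure(
    list(
      freq = freq, core_col = core_col, pseudocount = pseudocount,
      background = background, uniform_cols = uniform_cols, ...
    ),
    class = "nucleotide_motif"
  )
}

#' Build a position-frequency motif from an alignment
#'
#' Per-column base frequencies over non-gap characters, pseudocount
#' smoothed and renormalized. Columns with no non-gap characters get
#' uniform frequencies and are flagged.
#'
#' @param alignment A `core_alignment`, character matrix, or character
#'   vector of equal-width aligned sequences.
#' @param pseudocount Added to each base count before normalization
#'   (default 0.01).
#' @return A `nucleotide_motif`: list with `freq` (positions x ACGT matrix,
#'   rows summing to 1), `core_col`, `pseudocount`, `background`, and
#'   `uniform_cols` (flagged empty columns).
#' @export
build_motif <- function(alignment, pseudocount = 0.01) {
  stopifnot(pseudocount > 0)
  core_col <- if (inherits(alignment, "core_alignment")) alignment$core_col else NA_integer_
  m <- .aln_matrix(alignment)
  w <- ncol(m)
  freq <- matrix(0, nrow = w, ncol = 4, dimnames = list(NULL, DNA_BASES4))
  uniform_cols <- integer(0)
  for (j in seq_len(w)) {
    col <- m[, j]
    counts <- vapply(DNA_BASES4, function(b) sum(col == b), numeric(1))
    n <- sum(counts)
    if (n == 0L) {
      freq[j, ] <- 0.25
      uniform_cols <- c(uniform_cols, j)
    } else {
      freq[j, ] <- (counts + pseudocount) / (n + 4 * pseudocount)
    }
  }
  if (length(uniform_cols) > 0L) {
    warning("column(s) with no unambiguous bases set to uniform frequencies: ",
      paste(uniform_cols, collapse = ", "),
      call. = FALSE
    )
  }
  .new_motif(freq,
    core_col = core_col, pseudocount = pseudocount,
    uniform_cols = uniform_cols
  )
}

#' Build a database-derived motif for a query LSR
#'
#' Starting from a query LSR and its own attB, relatives at >= 30% amino
#' acid identity are visited in order of decreasing identity (ties by id)
#' and their attB sequences accumulated until `n_sites` are selected,
#' skipping any attB more than 95% identical to one already selected. Each
#' candidate attB is oriented by the strand with the higher global
#' alignment score to the query's attB, then anchored onto the query attB
#' coordinates by global alignment (insertions relative to the query are
#' dropped). Columns with over 50% gaps are excluded, the middle
#' `middle_nt` of the remaining columns are kept, and per-column
#' frequencies are computed with gap cells contributing equal weight to
#' all four bases.
#'
#' @param query_protein Query LSR amino-acid sequence.
#' @param query_attB The query LSR's own attB sequence.
#' @param database Data frame with columns `lsr_id`, `protein`, `attB`.
#' @param n_sites Number of relative attBs to select (the published
#'   construction uses 20, 50 and 100).
#' @param min_lsr_identity Minimum amino-acid identity of relatives
#'   (default 0.30).
#' @param max_attB_identity Redundancy cap: candidate attBs are added only
#'   if at most this identical to every already-selected attB (default
#'   0.95).
#' @param middle_nt Width of the central window kept after gap-column
#'   exclusion (default 60).
#' @param pseudocount Pseudocount for the final frequencies.
#' @param align_fun Projection aligner: a `function(seq, ref)` returning one
#'   character (a base or `"-"`) per position of `ref`. The default anchors
#'   by global pairwise alignment; substitute to route through a full
#'   multiple aligner.
#' @return A `nucleotide_motif` with extra fields `n_sites_used` and
#'   `query_positions` (0-based offsets of the motif columns on
#'   `query_attB`).
#' @export
build_posthoc_motif <- function(query_protein, query_attB, database,
                                n_sites = 20L, min_lsr_identity = 0.30,
                                max_attB_identity = 0.95, middle_nt = 60L,
                                pseudocount = 0.01,
                                align_fun = .anchor_to_reference) {
  stopifnot(
    is.data.frame(database),
    all(c("lsr_id", "protein", "attB") %in% names(database)),
    nrow(database) > 0L
  )
  query_attB <- .as_seq(query_attB)
  ident <- vapply(database$protein, function(p) {
    seq_identity(query_protein, p)
  }, numeric(1), USE.NAMES = FALSE)
  db <- database[ident >= min_lsr_identity, , drop = FALSE]
  db_ident <- ident[ident >= min_lsr_identity]
  ord <- order(-db_ident, db$lsr_id)
  db <- db[ord, , drop = FALSE]

  selected <- query_attB # redundancy guard includes the query's own site
  used <- character(0)
  for (i in seq_len(nrow(db))) {
    if (length(used) >= n_sites) break
    cand <- .as_seq(db$attB[i])
    fw <- .global_score(cand, query_attB)
    rv <- .global_score(revcomp(cand), query_attB)
    if (rv > fw) cand <- revcomp(cand)
    if (any(vapply(selected, function(s) seq_identity(cand, s), numeric(1)) > max_attB_identity)) {
      next
    }
    selected <- c(selected, cand)
    used <- c(used, db$lsr_id[i])
  }
  if (length(used) == 0L) {
    warning("no relative at or above the identity floor contributed an attB; ",
      "motif built from the query attB alone",
      call. = FALSE
    )
  }

  # stack every selected attB (query first) onto query attB coordinates
  nq <- nchar(query_attB)
  rows <- matrix(GAP_CHAR, nrow = length(selected), ncol = nq)
  rows[1, ] <- strsplit(query_attB, "")[[1]]
  if (length(selected) > 1L) {
    for (i in 2:length(selected)) {
      rows[i, ] <- align_fun(selected[i], query_attB)
    }
  }
  gap_frac <- colMeans(rows == GAP_CHAR)
  keep <- which(gap_frac <= 0.5)
  if (length(keep) > middle_nt) {
    start <- (length(keep) - middle_nt) %/% 2L
    keep <- keep[(start + 1L):(start + middle_nt)]
  }
  rows <- rows[, keep, drop = FALSE]

  # gap cells contribute equally weighted base frequencies
  w <- ncol(rows)
  freq <- matrix(0, nrow = w, ncol = 4, dimnames = list(NULL, DNA_BASES4))
  for (j in seq_len(w)) {
    col <- rows[, j]
    counts <- vapply(DNA_BASES4, function(b) sum(col == b), numeric(1))
    counts <- counts + sum(!(col %in% DNA_BASES4)) * 0.25
    freq[j, ] <- (counts + pseudocount) / (sum(counts) + 4 * pseudocount)
  }
  .new_motif(freq,
    pseudocount = pseudocount,
    n_sites_used = length(used),
    relatives_used = used,
    query_positions = keep - 1L
  )
}

# Project `seq` onto the coordinates of `ref` via global alignment:
# one character (or gap) per reference position; insertions relative to the
# reference are discarded.
.anchor_to_reference <- function(seq, ref) {
  aln <- Biostrings::pairwiseAlignment(
    seq, ref,
    type = "global",
    substitutionMatrix = .unit_submat(seq, ref, match = 1, mismatch = -1),
    gapOpening = 0, gapExtension = 2
  )
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  pat[sub != GAP_CHAR]
}

#' Scan sequences with a motif by summed log-odds
#'
#' Every window of motif width on both strands is scored as the sum over
#' positions of `log2(freq(base) / background(base))`; positions with a
#' non-ACGT base contribute zero. The per-sequence score is the maximum
#' over windows and strands.
#'
#' @param motif A `nucleotide_motif`.
#' @param sequences Character vector of sequences (each at least motif
#'   width long), optionally named.
#' @param background Named background frequencies for ACGT (default: the
#'   motif's background, uniform unless set).
#' @param all_scores Return all window scores instead of the per-sequence
#'   maximum.
#' @return Data frame with `seq_id`, `score`, `position` (0-based window
#'   offset on the forward sequence), `strand`; one row per sequence (or
#'   per window when `all_scores`).
#' @export
scan_motif <- function(motif, sequences, background = NULL, all_scores = FALSE) {
  stopifnot(inherits(motif, "nucleotide_motif"))
  if (is.null(background)) background <- motif$background
  background <- background[DNA_BASES4]
  lo <- log2(sweep(motif$freq, 2, background, "/")) # w x 4
  lo <- cbind(lo, other = 0)
  w <- nrow(lo)
  sequences <- .as_seq(sequences)
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  res <- vector("list", length(sequences))
  for (s in seq_along(sequences)) {
    x <- sequences[[s]]
    n <- nchar(x)
    if (n < w) stop("sequence ", ids[s], " shorter than motif width")
    score_strand <- function(str) {
      code <- match(strsplit(str, "")[[1]], DNA_BASES4)
      code[is.na(code)] <- 5L
      starts <- 0:(n - w)
      vapply(starts, function(o) {
        sum(lo[cbind(seq_len(w), code[(o + 1):(o + w)])])
      }, numeric(1))
    }
    fwd <- score_strand(x)
    rev <- score_strand(revcomp(x))
    if (all_scores) {
      res[[s]] <- data.frame(
        seq_id = ids[s],
        score = c(fwd, rev),
        position = c(0:(n - w), (n - w):0),
        strand = rep(c("+", "-"), each = n - w + 1L),
        stringsAsFactors = FALSE
      )
    } else {
      all <- c(fwd, rev)
      best <- which.max(all)
      res[[s]] <- data.frame(
        seq_id = ids[s],
        score = all[best],
        position = c(0:(n - w), (n - w):0)[best],
        strand = rep(c("+", "-"), each = n - w + 1L)[best],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' ROC curve and AUC from two score sets
#'
#' Sweeps thresholds over the union of observed scores (calls are
#' `score >= threshold`), reporting the true- and false-positive rate at
#' each cutoff and the trapezoidal area under the curve. Tied scores are
#' credited 0.5, so the AUC equals the Mann-Whitney statistic
#' U / (n1 * n2).
#'
#' @param positive_scores,negative_scores Numeric score vectors (each
#'   non-empty).
#' @return A `roc_result`: list with `thresholds` (descending), `tpr`,
#'   `fpr` (monotone non-decreasing, beginning at 0, ending at 1), and
#'   `auc`.
#' @export
roc_auc <- function(positive_scores, negative_scores) {
  stopifnot(length(positive_scores) >= 1L, length(negative_scores) >= 1L)
  thr <- sort(unique(c(positive_scores, negative_scores)), decreasing = TRUE)
  n1 <- length(positive_scores)
  n2 <- length(negative_scores)
  tpr <- vapply(thr, function(t) sum(positive_scores >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(negative_scores >= t) / n2, numeric(1))
  tpr <- c(0, tpr)
  fpr <- c(0, fpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(thresholds = c(Inf, thr), tpr = tpr, fpr = fpr, auc = auc),
    class = "roc_result"
  )
}

#' @export
print.nucleotide_motif <- function(x, ...) {
  cat("Nucleotide motif, ", nrow(x$freq), " positions",
    if (!is.na(x$core_col)) paste0(", core at column ", x$core_col) else "",
    "\n  consensus: ", paste(DNA_BASES4[apply(x$freq, 1, which.max)], collapse = ""),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC over", length(x$thresholds), "cutoffs; AUC =", format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Write a motif in MEME minimal format
#'
#' @param motif A `nucleotide_motif`.
#' @param path Output path.
#' @param name Motif name written in the file.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motif, path, name = "motif1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(sprintf("%s %.6f", DNA_BASES4, motif$background[DNA_BASES4]), collapse = " "),
    "",
    paste("MOTIF", name),
    sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      nrow(motif$freq)
    )
  ), con)
  utils::write.table(
    format(motif$freq, digits = 6),
    con,
    row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}
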