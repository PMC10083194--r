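# attB/attP reconstruction, attachment-site center and core detection, and
# attL/attR derivation.

#' Reconstruct attB and attP from an insertion call
#'
#' Applies the concatenation rules attB = B1 + D + B2 and attP = P2 + D + P1
#' (flanks read from the post-integration chromosome, which most closely
#' represents the pre-integration attB), then trims both to a window
#' centered on the duplicated segment (or the breakpoint when |D| = 0). The
#' attachment-site center and core dinucleotide are located with
#' [find_center()].
#'
#' @param call An `insertion_call` from [find_insertion()].
#' @param window Window width in bp (default 50).
#' @return An `att_pair` list: `attB`, `attP`, `center`, `core`,
#'   `core_offset_attB`, `core_offset_attP` (0-based offsets of the core
#'   2-mer), `orientation`, `truncated` flag, and `window`.
#' @export
reconstruct_sites <- function(call, window = 50L) {
  stopifnot(inherits(call, "insertion_call"))
  window <- as.integer(window)
  d <- nchar(call$duplication)
  if (d >= window) {
    off <- (d - window) %/% 2L
    attB <- .substr0(call$duplication, off, off + window)
    attP <- attB
    truncated <- FALSE
  } else {
    nl <- (window - d) %/% 2L
    nr <- window - d - nl
    b1 <- call$b1_flank
    b2 <- call$b2_flank
    p1 <- call$p1_terminal
    p2 <- call$p2_terminal
    attB <- paste0(
      .substr0(b1, max(0L, nchar(b1) - nl), nchar(b1)),
      call$duplication,
      .substr0(b2, 0L, min(nchar(b2), nr))
    )
    attP <- paste0(
      .substr0(p2, max(0L, nchar(p2) - nl), nchar(p2)),
      call$duplication,
      .substr0(p1, 0L, min(nchar(p1), nr))
    )
    truncated <- nchar(attB) < window || nchar(attP) < window
    if (truncated) {
      warning("flanks shorter than required window; attachment sites truncated",
        call. = FALSE
      )
    }
  }
  # The attachment-site center is the homologous stretch containing the
  # duplication: extend outward from the D region, whose offset is known
  # here (both windows place D at the same offset). Fall back to the
  # generic longest-common-substring search when the anchored stretch is
  # shorter than 2 bp (possible when |D| = 0).
  nl_off <- if (d >= window) 0L else (window - d) %/% 2L
  ctr <- .anchored_center(attB, attP, nl_off, min(d, window))
  if (is.null(ctr)) ctr <- find_center(attB, attP)
  structure(
    list(
      attB = attB, attP = attP,
      center = ctr$center, core = ctr$core,
      center_offset_attB = ctr$offset_b, center_offset_attP = ctr$offset_p,
      core_offset_attB = ctr$offset_b + ctr$core_offset,
      core_offset_attP = ctr$offset_p + ctr$core_offset,
      orientation = "forward",
      truncated = truncated,
      window = window
    ),
    class = "att_pair"
  )
}

# Maximal common substring of a/b containing the segment [offset,
# offset+d) present at the same offset in both (the duplication); extends
# the match outward on both sides. NULL when shorter than 2 bp.
.anchored_center <- function(a, b, offset, d) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  lo <- offset # 0-based start of the anchored stretch
  hi <- offset + d # 0-based exclusive end
  if (hi > n) {
    return(NULL)
  }
  while (lo > 0L && ra[lo] == rb[lo]) lo <- lo - 1L
  while (hi < n && ra[hi + 1L] == rb[hi + 1L]) hi <- hi + 1L
  len <- hi - lo
  if (len < 2L) {
    return(NULL)
  }
  core_offset <- (len - 2L) %/% 2L
  center <- .substr0(a, lo, hi)
  list(
    center = center,
    core = .substr0(center, core_offset, core_offset + 2L),
    offset_b = lo, offset_p = lo, core_offset = core_offset
  )
}

#' Locate the attachment-site center and core dinucleotide
#'
#' The center is the stretch of sequence homologous between attB and attP:
#' here, their longest common substring, with ties broken by proximity of
#' the substring midpoint to each sequence's midpoint, then leftmost. The
#' core is the central 2-mer of the center.
#'
#' @param attB,attP Attachment-site sequences (length >= 2).
#' @return List with `center`, `core`, `offset_b`, `offset_p` (0-based
#'   offsets of the center in each sequence), and `core_offset` (0-based
#'   offset of the core within the center).
#' @export
find_center <- function(attB, attP) {
  attB <- .as_seq(attB)
  attP <- .as_seq(attP)
  n <- nchar(attB)
  m <- nchar(attP)
  stopifnot(n >= 2L, m >= 2L)
  a <- charToRaw(attB)
  b <- charToRaw(attP)
  # O(nm) longest-common-substring dynamic program
  prev <- integer(m)
  best_len <- 0L
  ends <- NULL # matrix of (end_i, end_j), 1-based inclusive ends
  for (i in seq_len(n)) {
    cur <- integer(m)
    eq <- which(b == a[i])
    if (length(eq) > 0L) {
      cur[eq] <- c(0L, prev)[eq] + 1L
      mx <- max(cur[eq])
      if (mx > best_len) {
        best_len <- mx
        ends <- cbind(i, eq[cur[eq] == mx])
      } else if (mx == best_len && best_len > 0L) {
        hit <- eq[cur[eq] == best_len]
        if (length(hit) > 0L) ends <- rbind(ends, cbind(i, hit))
      }
    }
    prev <- cur
  }
  if (best_len < 2L) {
    stop("no common substring of length >= 2 between attB and attP")
  }
  start_b <- ends[, 1] - best_len # 0-based offsets
  start_p <- ends[, 2] - best_len
  sub_mid_b <- start_b + best_len / 2
  sub_mid_p <- start_p + best_len / 2
  tie <- abs(sub_mid_b - n / 2) + abs(sub_mid_p - m / 2)
  ord <- order(tie, start_b, start_p)
  pick <- ord[1]
  center <- .substr0(attB, start_b[pick], start_b[pick] + best_len)
  core_offset <- (best_len - 2L) %/% 2L
  list(
    center = center,
    core = .substr0(center, core_offset, core_offset + 2L),
    offset_b = as.integer(start_b[pick]),
    offset_p = as.integer(start_p[pick]),
    core_offset = core_offset
  )
}

#' Derive the post-recombination attL and attR sites
#'
#' Recombination crosses over at the core dinucleotide: attL carries the
#' attB left half and the attP right half around the shared core, and attR
#' the converse. Applying the derivation again with the roles swapped
#' returns the original pair.
#'
#' @param pair An `att_pair` from [reconstruct_sites()], or any list with
#'   `attB`, `attP`, `core_offset_attB`, `core_offset_attP`.
#' @return List of class `recombined_sites` with `attL` and `attR`.
#' @export
derive_attL_attR <- function(pair) {
  ob <- pair$core_offset_attB
  op <- pair$core_offset_attP
  core_b <- .substr0(pair$attB, ob, ob + 2L)
  core_p <- .substr0(pair$attP, op, op + 2L)
  if (!identical(core_b, core_p)) {
    stop("core dinucleotide differs between attB and attP")
  }
  structure(
    list(
      attL = paste0(
        .substr0(pair$attB, 0L, ob), core_b,
        .substr0(pair$attP, op + 2L, nchar(pair$attP))
      ),
      attR = paste0(
        .substr0(pair$attP, 0L, op), core_b,
        .substr0(pair$attB, ob + 2L, nchar(pair$attB))
      )
    ),
    class = "recombined_sites"
  )
}

#' @export
print.att_pair <- function(x, ...) {
  cat(
    "Attachment-site pair (window ", x$window, " bp",
    if (x$truncated) ", truncated" else "", ")\n",
    "  attB: ", x$attB, "\n",
    "  attP: ", x$attP, "\n",
    "  center (", nchar(x$center), " bp): ", x$center,
    "  core: ", x$core, "\n",
    sep = ""
  )
  invisible(x)
}

#' Export an attachment-site pair (and derived sites) as FASTA
#'
#' @param pair An `att_pair`.
#' @param lsr_id Identifier prefix for the FASTA records.
#' @param path Output path.
#' @param derived Also write attL/attR (default TRUE).
#' @return `path`, invisibly.
#' @export
write_att_fasta <- function(pair, lsr_id, path, derived = TRUE) {
  seqs <- c(pair$attB, pair$attP)
  names(seqs) <- paste0(lsr_id, c("_attB", "_attP"))
  if (derived) {
    lr <- derive_attL_attR(pair)
    seqs <- c(seqs, stats::setNames(
      c(lr$attL, lr$attR),
      paste0(lsr_id, c("_attL", "_attR"))
    ))
  }
  write_fasta(seqs, path)
}
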