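# Amplicon barcode counting with quality gating, dropout analysis, and the
# pooled-reporter log-ratio statistic.

#' Enumerate the complete barcode universe
#'
#' @param k Barcode length (default 6, giving 4096 barcodes).
#' @return Character vector of all 4^k DNA k-mers, sorted.
#' @export
barcode_universe <- function(k = 6L) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  g <- do.call(expand.grid, c(rep(list(DNA_BASES4), k), stringsAsFactors = FALSE))
  sort(do.call(paste0, g[rev(seq_len(k))]))
}

#' Count amplicon barcodes with quality gating
#'
#' Reads are kept when their mean Phred quality over all positions is at
#' least `q_mean_min` and the minimum quality over the k-bp barcode region
#' is at least `q_barcode_min`; the barcode region is then tallied by
#' exact match against the complete 4^k universe (no mismatch rescue).
#' Barcodes with 0 or 1 counts form the dropout set.
#'
#' @param reads Character vector of read sequences, a data frame with
#'   columns `seq` and `qual`, or a FASTQ path.
#' @param quals Character vector of Phred+33 quality strings (ignored when
#'   `reads` carries its own).
#' @param barcode_offset 0-based offset of the barcode region within each
#'   read.
#' @param k Barcode length (default 6).
#' @param q_mean_min Minimum mean quality over the whole read (default 30).
#' @param q_barcode_min Minimum per-base quality over the barcode region
#'   (default 30).
#' @param phred_offset Quality encoding offset (default 33).
#' @return A `barcode_tally`: list with `k`, `counts` (named integer over
#'   all 4^k barcodes), `kept`, `discarded` (named reason tally), and
#'   `dropout` (barcodes with counts <= 1).
#' @export
count_barcodes <- function(reads, quals = NULL, barcode_offset = 0L, k = 6L,
                           q_mean_min = 30, q_barcode_min = 30,
                           phred_offset = 33L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fq <- read_fastq(reads)
    reads <- fq$seq
    quals <- fq$qual
  }
  if (is.data.frame(reads)) {
    quals <- reads$qual
    reads <- reads$seq
  }
  stopifnot(length(reads) == length(quals))
  k <- as.integer(k)
  barcode_offset <- as.integer(barcode_offset)
  universe <- barcode_universe(k)
  counts <- stats::setNames(integer(length(universe)), universe)
  discarded <- c(
    too_short = 0L, low_mean_q = 0L, low_barcode_q = 0L, no_match = 0L
  )
  for (i in seq_along(reads)) {
    if (nchar(reads[i]) < barcode_offset + k) {
      discarded["too_short"] <- discarded["too_short"] + 1L
      next
    }
    q <- utf8ToInt(quals[i]) - phred_offset
    if (mean(q) < q_mean_min) {
      discarded["low_mean_q"] <- discarded["low_mean_q"] + 1L
      next
    }
    bq <- q[(barcode_offset + 1L):(barcode_offset + k)]
    if (min(bq) < q_barcode_min) {
      discarded["low_barcode_q"] <- discarded["low_barcode_q"] + 1L
      next
    }
    bc <- toupper(substr(reads[i], barcode_offset + 1L, barcode_offset + k))
    j <- match(bc, universe)
    if (is.na(j)) {
      discarded["no_match"] <- discarded["no_match"] + 1L
      next
    }
    counts[j] <- counts[j] + 1L
  }
  structure(
    list(
      k = k,
      counts = counts,
      kept = sum(counts),
      discarded = discarded,
      dropout = names(counts)[counts <= 1L]
    ),
    class = "barcode_tally"
  )
}

#' @export
print.barcode_tally <- function(x, ...) {
  cat(
    "Barcode tally over ", length(x$counts), " ", x$k, "-mers: ",
    x$kept, " reads kept, ", sum(x$discarded), " discarded; ",
    length(x$dropout), " dropouts (counts <= 1)\n",
    sep = ""
  )
  invisible(x)
}

#' Pooled-reporter log2 bound:unbound ratio
#'
#' Depth-normalizes both samples to counts per million and reports
#' log2((cpm_bound + pseudocount) / (cpm_unbound + pseudocount)) per
#' element, the ON:OFF statistic of magnetically separated reporter pools.
#'
#' @param bound_counts,unbound_counts Named count vectors over the same
#'   element universe.
#' @param pseudocount Added to both normalized counts (default 0.5).
#' @return Named numeric vector of per-element log2 ratios.
#' @export
reporter_log_ratio <- function(bound_counts, unbound_counts, pseudocount = 0.5) {
  if (!is.null(names(bound_counts)) || !is.null(names(unbound_counts))) {
    stopifnot(identical(names(bound_counts), names(unbound_counts)))
  }
  stopifnot(length(bound_counts) == length(unbound_counts))
  tb <- sum(bound_counts)
  tu <- sum(unbound_counts)
  if (tb == 0 || tu == 0) stop("zero total depth in one of the samples")
  cpm_b <- 1e6 * bound_counts / tb
  cpm_u <- 1e6 * unbound_counts / tu
  log2((cpm_b + pseudocount) / (cpm_u + pseudocount))
}
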