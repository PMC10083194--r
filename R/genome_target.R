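# Attachment-site search against a target genome (seed-and-extend local
# alignment with Karlin-Altschul E-values) and attA/attD/attH role
# assignment.

# Ungapped Karlin-Altschul lambda for a match/mismatch scheme under the
# background base composition: solves sum p_i p_j exp(lambda * s_ij) = 1.
.ka_lambda <- function(match, mismatch, p_match = 0.25) {
  f <- function(l) p_match * exp(l * match) + (1 - p_match) * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 10), tol = 1e-12)$root
}

#' Search attachment sites against a target genome
#'
#' Seed-and-extend local search: exact `word_size`-mers of each site (both
#' strands) are located in the genome, seed diagonals are refined by a
#' local alignment (match +2, mismatch -3, affine gaps) over the
#' surrounding window, and each alignment score S is converted to an
#' expectation value E = K m n exp(-lambda S) over the site length m and
#' total searched genome length n, with lambda solved from the scoring
#' scheme and K a calibration constant. Hits with E strictly below
#' `e_threshold` are reported, sorted by ascending E.
#'
#' @param att_sites Named character vector of attachment-site sequences
#'   (typically 20-200 bp).
#' @param target_genome Character scalar or named character vector of
#'   contigs.
#' @param e_threshold Strict E-value cutoff (default 1e-3).
#' @param word_size Seed word size (default 11).
#' @param match,mismatch,gap_opening,gap_extension Alignment scoring.
#' @param K Karlin-Altschul K calibration constant (default 0.21).
#' @return Data frame of `genome_hit` rows: `att_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `aln_len`, `identity`, `score`,
#'   `bit_score`, `e_value`.
#' @export
search_sites <- function(att_sites, target_genome, e_threshold = 1e-3,
                         word_size = 11L, match = 2, mismatch = -3,
                         gap_opening = 5, gap_extension = 2, K = 0.21) {
  if (is.null(names(att_sites))) {
    names(att_sites) <- paste0("site", seq_along(att_sites))
  }
  if (is.null(names(target_genome))) names(target_genome) <- "chr"
  target_genome <- vapply(target_genome, .as_seq, character(1))
  if (any(nchar(target_genome) == 0L)) stop("empty genome")
  lambda <- .ka_lambda(match, mismatch)
  n_total <- sum(nchar(target_genome))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch)

  hits <- list()
  for (chrom in names(target_genome)) {
    gseq <- Biostrings::DNAString(target_genome[[chrom]])
    glen <- length(gseq)
    for (att_id in names(att_sites)) {
      site <- .as_seq(att_sites[[att_id]])
      m <- nchar(site)
      for (strand in c("+", "-")) {
        qry <- if (strand == "+") site else revcomp(site)
        diags <- .seed_diagonals(qry, gseq, word_size)
        for (dg in diags) {
          lo <- max(0L, dg - m)
          hi <- min(glen, dg + 2L * m)
          if (hi - lo < word_size) next
          win <- Biostrings::subseq(gseq, lo + 1L, hi)
          aln <- Biostrings::pairwiseAlignment(
            qry, win,
            type = "local", substitutionMatrix = submat,
            gapOpening = gap_opening, gapExtension = gap_extension
          )
          score <- Biostrings::score(aln)
          if (score <= 0) next
          e_value <- K * m * n_total * exp(-lambda * score)
          if (e_value >= e_threshold) next
          sstart <- lo + Biostrings::start(Biostrings::subject(aln)) - 1L
          send <- lo + Biostrings::end(Biostrings::subject(aln))
          width <- nchar(as.character(Biostrings::alignedPattern(aln)))
          hits[[length(hits) + 1L]] <- data.frame(
            att_id = att_id, chrom = chrom,
            start = sstart, end = send, strand = strand,
            aln_len = width,
            identity = Biostrings::nmatch(aln) / width,
            score = score,
            bit_score = (lambda * score - log(K)) / log(2),
            e_value = e_value,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(
      att_id = character(0), chrom = character(0), start = integer(0),
      end = integer(0), strand = character(0), aln_len = integer(0),
      identity = numeric(0), score = numeric(0), bit_score = numeric(0),
      e_value = numeric(0), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, hits)
  # collapse duplicate/overlapping hits of one site on one strand: keep best
  key <- paste(out$att_id, out$chrom, out$strand)
  keep <- unlist(lapply(split(seq_len(nrow(out)), key), function(idx) {
    d <- out[idx, , drop = FALSE]
    o <- order(d$e_value, -d$bit_score)
    chosen <- integer(0)
    for (i in o) {
      overlaps <- any(vapply(chosen, function(j) {
        d$start[i] < d$end[j] && d$end[i] > d$start[j]
      }, logical(1)))
      if (!overlaps) chosen <- c(chosen, i)
    }
    idx[chosen]
  }))
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$e_value, -out$bit_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Distinct plausible start offsets (0-based) of `qry` in `gseq` from exact
# word matches, clustered so each candidate region is refined once.
.seed_diagonals <- function(qry, gseq, word_size) {
  words <- unique(.kmers(qry, word_size))
  if (length(words) == 0L) {
    return(integer(0))
  }
  qpos <- lapply(words, function(wd) {
    as.integer(regexpr(wd, qry, fixed = TRUE)) - 1L
  })
  pd <- Biostrings::PDict(words)
  mt <- Biostrings::matchPDict(pd, gseq)
  starts <- integer(0)
  for (i in seq_along(words)) {
    s <- Biostrings::start(mt[[i]])
    if (length(s) > 0L) starts <- c(starts, s - 1L - qpos[[i]])
  }
  if (length(starts) == 0L) {
    return(integer(0))
  }
  starts <- sort(unique(pmax(starts, 0L)))
  # cluster diagonals within half a query length
  keep <- starts[c(TRUE, diff(starts) > nchar(qry) %/% 2L)]
  keep
}

#' Assign attA/attD/attH roles from genome hits
#'
#' The attachment site with the best (lowest-E) genome hit is the acceptor
#' attA; its cognate partner is the donor attD; the hit's genomic span is
#' the predicted target site attH. E-value ties are broken by higher bit
#' score, then attB is preferred.
#'
#' @param attB,attP The cognate attachment-site sequences.
#' @param hits Hit table from [search_sites()] in which `att_id` is
#'   `"attB"` or `"attP"`.
#' @param genome Optional genome (named character) used to extract the attH
#'   sequence.
#' @return A `role_assignment` list: `attA`, `attA_kind`, `attD`,
#'   `attD_kind`, `attH` (sequence or `NA`), `attH_chrom`, `attH_start`,
#'   `attH_end`, `attH_strand`, `best_hit` (the winning row). `NULL` when
#'   there are no hits (the candidate is not genome-targeting).
#' @export
assign_roles <- function(attB, attP, hits, genome = NULL) {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(NULL)
  }
  stopifnot(all(hits$att_id %in% c("attB", "attP")))
  pref <- ifelse(hits$att_id == "attB", 0L, 1L)
  best <- hits[order(hits$e_value, -hits$bit_score, pref), , drop = FALSE][1, ]
  acceptor_is_b <- best$att_id == "attB"
  attH <- NA_character_
  if (!is.null(genome)) {
    if (is.null(names(genome))) names(genome) <- "chr"
    g <- genome[[best$chrom]]
    if (!is.null(g)) {
      attH <- .substr0(.as_seq(g), best$start, best$end)
      if (best$strand == "-") attH <- revcomp(attH)
    }
  }
  structure(
    list(
      attA = if (acceptor_is_b) attB else attP,
      attA_kind = best$att_id,
      attD = if (acceptor_is_b) attP else attB,
      attD_kind = if (acceptor_is_b) "attP" else "attB",
      attH = attH,
      attH_chrom = best$chrom,
      attH_start = best$start,
      attH_end = best$end,
      attH_strand = best$strand,
      best_hit = best
    ),
    class = "role_assignment"
  )
}

#' Read precomputed search hits in BLAST tabular (outfmt 6) layout
#'
#' Allows an external search engine to substitute for [search_sites()]
#' bit-compatibly: the twelve standard columns are mapped onto the
#' `genome_hit` table (coordinates converted to 0-based half-open, strand
#' inferred from subject start/end order).
#'
#' @param path Path to a tab-separated file with the standard columns
#'   qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#'   sstart, send, evalue, bitscore.
#' @param e_threshold Strict E-value cutoff applied on ingest.
#' @return Data frame with the [search_sites()] hit columns.
#' @export
read_blast_hits <- function(path, e_threshold = 1e-3) {
  cols <- c(
    "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore"
  )
  x <- utils::read.table(path, sep = "\t", col.names = cols, stringsAsFactors = FALSE)
  out <- data.frame(
    att_id = x$qseqid, chrom = x$sseqid,
    start = pmin(x$sstart, x$send) - 1L,
    end = pmax(x$sstart, x$send),
    strand = ifelse(x$sstart <= x$send, "+", "-"),
    aln_len = x$length,
    identity = x$pident / 100,
    score = NA_real_,
    bit_score = x$bitscore,
    e_value = x$evalue,
    stringsAsFactors = FALSE
  )
  out <- out[out$e_value < e_threshold, , drop = FALSE]
  out <- out[order(out$e_value, -out$bit_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}
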