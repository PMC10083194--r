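# Integration-site calling from donor-genome junction sequencing:
# read filtering and deduplication, clipped-end consensus, identity-gated
# site calling, locus merging and quantification, site-motif construction,
# and chromatin-accessibility enrichment.

#' Filter junction-read records
#'
#' Keeps reads that mapped to both the donor and the genome, began at the
#' primer site, and did not have an intact attD (undeterminable attD status
#' is kept); removes supplementary alignments, mapping quality below
#' `min_mapq`, and insert sizes above `max_insert`; then collapses PCR
#' duplicates positionally on (chrom, position, orientation, mate
#' position), or including the UMI when a UMI column is populated.
#' Applying the filter twice equals applying it once.
#'
#' @param records Junction-read record table (see
#'   [simulate_junction_reads()] or [read_junction_sam()]): columns
#'   `read_id`, `chrom`, `pos`, `strand`, `aln_len`, `mapq`, `insert_size`,
#'   `maps_to_donor`, `maps_to_genome`, `begins_at_primer`, `attd_intact`,
#'   `supplementary`, `mate_pos`, `umi`, `clip`.
#' @param min_mapq Minimum mapping quality retained (default 30).
#' @param max_insert Maximum insert size retained (default 1500 bp).
#' @return The surviving records, with a `filter_stats` attribute tallying
#'   removal reasons.
#' @export
filter_reads <- function(records, min_mapq = 30L, max_insert = 1500L) {
  req <- c(
    "chrom", "pos", "strand", "mapq", "insert_size", "maps_to_donor",
    "maps_to_genome", "begins_at_primer", "attd_intact", "supplementary",
    "mate_pos"
  )
  missing <- setdiff(req, names(records))
  if (length(missing) > 0L) {
    stop("malformed alignment records; missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!"umi" %in% names(records)) records$umi <- NA_character_
  keep_both <- records$maps_to_donor & records$maps_to_genome
  keep_primer <- records$begins_at_primer
  keep_attd <- records$attd_intact != "intact"
  keep_suppl <- !records$supplementary
  keep_mapq <- records$mapq >= min_mapq
  keep_insert <- is.na(records$insert_size) | records$insert_size <= max_insert
  keep <- keep_both & keep_primer & keep_attd & keep_suppl & keep_mapq & keep_insert
  keep[is.na(keep)] <- FALSE
  stats <- c(
    input = nrow(records),
    not_both_refs = sum(!keep_both, na.rm = TRUE),
    not_at_primer = sum(!keep_primer, na.rm = TRUE),
    attd_intact = sum(!keep_attd, na.rm = TRUE),
    supplementary = sum(!keep_suppl, na.rm = TRUE),
    low_mapq = sum(!keep_mapq, na.rm = TRUE),
    long_insert = sum(!keep_insert, na.rm = TRUE)
  )
  out <- records[keep, , drop = FALSE]
  key <- if (any(!is.na(out$umi))) {
    paste(out$chrom, out$pos, out$strand, out$umi)
  } else {
    paste(out$chrom, out$pos, out$strand, out$mate_pos)
  }
  dup <- duplicated(key)
  stats["duplicates"] <- sum(dup)
  out <- out[!dup, , drop = FALSE]
  stats["kept"] <- nrow(out)
  rownames(out) <- NULL
  attr(out, "filter_stats") <- stats
  out
}

# Junction coordinate: the genomic base where the read crosses from donor
# into genome. "+" reads align leftmost at the junction; "-" reads end at it.
.junction_pos <- function(records) {
  ifelse(records$strand == "+", records$pos, records$pos + records$aln_len)
}

#' Consensus of clipped ends per genomic anchor
#'
#' Groups reads by their donor-genome junction coordinate and strand and
#' builds a per-position majority consensus of the clipped (donor-side)
#' sequences, which all begin at the primer site. Ties are written as `N`.
#'
#' @param records Filtered junction-read records (must carry `clip`).
#' @return Data frame with `chrom`, `junction_pos`, `strand`, `n_reads`,
#'   `consensus`.
#' @export
consensus_clips <- function(records) {
  stopifnot("clip" %in% names(records))
  records <- records[!is.na(records$clip) & nchar(records$clip) > 0L, , drop = FALSE]
  if (nrow(records) == 0L) stop("no clipped reads to build a consensus from")
  jpos <- .junction_pos(records)
  key <- paste(records$chrom, jpos, records$strand, sep = "\r")
  groups <- split(seq_len(nrow(records)), key)
  rows <- lapply(groups, function(idx) {
    clips <- records$clip[idx]
    data.frame(
      chrom = records$chrom[idx[1]],
      junction_pos = jpos[idx[1]],
      strand = records$strand[idx[1]],
      n_reads = length(idx),
      consensus = .majority_consensus(clips),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$junction_pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.majority_consensus <- function(clips) {
  maxlen <- max(nchar(clips))
  mat <- vapply(clips, function(cl) {
    ch <- strsplit(cl, "")[[1]]
    c(ch, rep(NA_character_, maxlen - length(ch)))
  }, character(maxlen))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = maxlen)
  cons <- apply(mat, 1, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0L) {
      return("")
    }
    tb <- sort(table(col), decreasing = TRUE)
    if (length(tb) > 1L && tb[1] == tb[2]) "N" else names(tb)[1]
  })
  paste(cons, collapse = "")
}

#' Call integration sites from per-anchor consensus sequences
#'
#' Each consensus (beginning at the primer) must share at least one 9-mer
#' with the attD subsequence (donor sequence from the primer to 25 bp past
#' the attD end), reach at least 80% nucleotide identity to it in either
#' the full local alignment or the longest gap- and ambiguity-free
#' contiguous sub-alignment, and place the crossover within 15 bp of the
#' predicted core dinucleotide. Rejection reasons are reported per anchor.
#'
#' @param consensus Data frame from [consensus_clips()].
#' @param attd_subseq Donor subsequence from the primer start to 25 bp
#'   after the attD end.
#' @param core_pos 0-based offset of the core 2-mer within `attd_subseq`.
#' @param min_identity Identity gate (default 0.8, applied as >=).
#' @param kmer Shared k-mer length (default 9).
#' @param max_core_dist Maximum crossover distance from the core (default
#'   15 bp).
#' @param min_support Minimum reads per anchor (default 1).
#' @return List with `sites` (data frame `chrom`, `position` of the core,
#'   `orientation`, `support`) and `rejections` (anchor, reason).
#' @export
call_sites <- function(consensus, attd_subseq, core_pos,
                       min_identity = 0.8, kmer = 9L, max_core_dist = 15L,
                       min_support = 1L) {
  attd_subseq <- .as_seq(attd_subseq)
  attd_kmers <- unique(.kmers(attd_subseq, kmer))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2)
  sites <- list()
  rejections <- list()
  reject <- function(i, reason) {
    rejections[[length(rejections) + 1L]] <<- data.frame(
      chrom = consensus$chrom[i], junction_pos = consensus$junction_pos[i],
      strand = consensus$strand[i], reason = reason, stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(nrow(consensus))) {
    cons <- consensus$consensus[i]
    if (consensus$n_reads[i] < min_support) {
      reject(i, "insufficient_support")
      next
    }
    if (nchar(cons) < kmer || !any(.kmers(cons, kmer) %in% attd_kmers)) {
      reject(i, "no_shared_kmer")
      next
    }
    aln <- Biostrings::pairwiseAlignment(
      cons, attd_subseq,
      type = "local", substitutionMatrix = submat,
      gapOpening = 4, gapExtension = 1
    )
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    full_identity <- Biostrings::nmatch(aln) / length(pat)
    contig_identity <- .contiguous_identity(pat, sub)
    if (full_identity < min_identity && contig_identity < min_identity) {
      reject(i, "low_identity")
      next
    }
    crossover <- Biostrings::end(Biostrings::subject(aln)) # 1-based end in attd_subseq
    if (abs(crossover - (core_pos + 2L)) > max_core_dist) {
      reject(i, "crossover_far_from_core")
      next
    }
    core_position <- if (consensus$strand[i] == "+") {
      consensus$junction_pos[i]
    } else {
      consensus$junction_pos[i] - 2L
    }
    sites[[length(sites) + 1L]] <- data.frame(
      chrom = consensus$chrom[i],
      position = core_position,
      orientation = consensus$strand[i],
      support = consensus$n_reads[i],
      stringsAsFactors = FALSE
    )
  }
  list(
    sites = if (length(sites) > 0L) {
      do.call(rbind, sites)
    } else {
      data.frame(
        chrom = character(0), position = integer(0),
        orientation = character(0), support = integer(0),
        stringsAsFactors = FALSE
      )
    },
    rejections = if (length(rejections) > 0L) {
      do.call(rbind, rejections)
    } else {
      data.frame(
        chrom = character(0), junction_pos = integer(0),
        strand = character(0), reason = character(0),
        stringsAsFactors = FALSE
      )
    }
  )
}

# Identity over the longest aligned run free of gaps and ambiguous bases.
.contiguous_identity <- function(pat, sub) {
  ok <- pat %in% DNA_BASES4 & sub %in% DNA_BASES4
  if (!any(ok)) {
    return(0)
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  idx <- starts[best]:ends[best]
  mean(pat[idx] == sub[idx])
}

#' Merge integration sites into loci
#'
#' Single-linkage merge of sites within `merge_distance` of each other on
#' the same chromosome (sites in opposite orientations merge together),
#' with per-locus unique-read (and UMI, when provided) counts and the
#' percent share of all counted reads.
#'
#' @param sites Site table from [call_sites()]; an optional `umi_support`
#'   column is summed into `umi_count`.
#' @param merge_distance Merge radius in bp (default 500).
#' @return Data frame of loci: `chrom`, `start`, `end` (0-based half-open,
#'   spanning member cores), `n_sites`, `read_count`, `umi_count`,
#'   `percent`.
#' @export
merge_loci <- function(sites, merge_distance = 500L) {
  stopifnot(all(c("chrom", "position", "support") %in% names(sites)))
  if (nrow(sites) == 0L) {
    return(data.frame(
      chrom = character(0), start = integer(0), end = integer(0),
      n_sites = integer(0), read_count = integer(0),
      umi_count = integer(0), percent = numeric(0), stringsAsFactors = FALSE
    ))
  }
  sites <- sites[order(sites$chrom, sites$position), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    sites$chrom,
    IRanges::IRanges(start = sites$position + 1L, width = 2L)
  )
  merged <- IRanges::reduce(gr, min.gapwidth = merge_distance + 1L)
  ov <- IRanges::findOverlaps(gr, merged)
  locus_of_site <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  umi <- if ("umi_support" %in% names(sites)) sites$umi_support else rep(NA_integer_, nrow(sites))
  rows <- lapply(seq_along(merged), function(l) {
    idx <- which(locus_of_site == l)
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(merged))[l],
      start = GenomicRanges::start(merged)[l] - 1L,
      end = GenomicRanges::end(merged)[l],
      n_sites = length(idx),
      read_count = sum(sites$support[idx]),
      umi_count = if (all(is.na(umi[idx]))) NA_integer_ else sum(umi[idx], na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  counts <- if (all(!is.na(out$umi_count))) out$umi_count else out$read_count
  out$percent <- 100 * counts / sum(counts)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Build a target-site motif from integration loci
#'
#' One integration site is chosen per locus (the most-supported, ties to
#' the leftmost), a window of `flank_bp` on each side of the core 2-mer is
#' extracted from the genome on the strand given by the integration
#' orientation, and the stacked windows are summarized with
#' [build_motif()].
#'
#' @param loci Locus table from [merge_loci()].
#' @param sites Site table from [call_sites()].
#' @param genome Named character vector of chromosome sequences.
#' @param flank_bp Flank width around the core (default 20).
#' @param top_n Optionally restrict to the `top_n` most-supported loci.
#' @param pseudocount Pseudocount for [build_motif()].
#' @return A `nucleotide_motif` of width `2 * flank_bp + 2`.
#' @export
locus_motif <- function(loci, sites, genome, flank_bp = 20L, top_n = NULL,
                        pseudocount = 0.01) {
  if (is.null(names(genome))) names(genome) <- "chr"
  genome <- vapply(genome, .as_seq, character(1))
  chosen <- lapply(seq_len(nrow(loci)), function(l) {
    d <- sites[
      sites$chrom == loci$chrom[l] &
        sites$position >= loci$start[l] & sites$position < loci$end[l], ,
      drop = FALSE
    ]
    d[order(-d$support, d$position), , drop = FALSE][1, ]
  })
  chosen <- do.call(rbind, chosen)
  chosen$locus_support <- loci$read_count
  if (!is.null(top_n)) {
    chosen <- chosen[order(-chosen$locus_support), , drop = FALSE]
    chosen <- utils::head(chosen, top_n)
  }
  windows <- character(0)
  for (i in seq_len(nrow(chosen))) {
    g <- genome[[chosen$chrom[i]]]
    lo <- chosen$position[i] - flank_bp
    hi <- chosen$position[i] + 2L + flank_bp
    if (is.null(g) || lo < 0L || hi > nchar(g)) {
      warning("window for site at ", chosen$chrom[i], ":", chosen$position[i],
        " exceeds chromosome bounds; site skipped",
        call. = FALSE
      )
      next
    }
    win <- .substr0(g, lo, hi)
    if (chosen$orientation[i] == "-") win <- revcomp(win)
    windows <- c(windows, win)
  }
  if (length(windows) == 0L) stop("no usable windows for motif construction")
  motif <- build_motif(windows, pseudocount = pseudocount)
  motif$core_col <- flank_bp + 1L
  motif
}

#' Accessibility enrichment of integration sites
#'
#' Tests whether integration sites fall within accessibility peaks more
#' often than matched background positions (two random positions drawn
#' within 100 kb of each true site), using a two-sided Fisher's exact test
#' on the 2x2 site/background by in-peak/out-of-peak table.
#'
#' @param sites Site table (`chrom`, `position`).
#' @param peaks Peak intervals: a data frame with `chrom`, `start`, `end`
#'   (0-based half-open, BED-style) or a `GRanges`.
#' @param seed Integer seed for the background draw.
#' @param n_background Background positions per site (default 2).
#' @param max_dist Background window half-width (default 100 kb).
#' @param chrom_lengths Optional named vector bounding background draws.
#' @return List with `odds_ratio` (sample odds ratio; `Inf` sentinel when
#'   the background never overlaps but sites do), `p_value`, `table`.
#' @export
accessibility_enrichment <- function(sites, peaks, seed = NULL,
                                     n_background = 2L, max_dist = 100000L,
                                     chrom_lengths = NULL) {
  stopifnot(nrow(sites) >= 1L)
  if (is.data.frame(peaks)) {
    peaks <- GenomicRanges::GRanges(
      peaks$chrom, IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
    )
  }
  absent <- setdiff(unique(sites$chrom), as.character(GenomicRanges::seqnames(peaks)))
  if (length(absent) > 0L) {
    warning("chromosome(s) absent from the peak set counted out-of-peak: ",
      paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  bg <- with_seed(seed, {
    off <- sample(-max_dist:max_dist, n_background * nrow(sites), replace = TRUE)
    pos <- rep(sites$position, each = n_background) + off
    chrom <- rep(sites$chrom, each = n_background)
    if (!is.null(chrom_lengths)) {
      pos <- pmin(pos, chrom_lengths[chrom] - 1L)
    }
    data.frame(chrom = chrom, position = pmax(pos, 0L), stringsAsFactors = FALSE)
  })
  in_peak <- function(d) {
    gr <- GenomicRanges::GRanges(
      d$chrom, IRanges::IRanges(start = d$position + 1L, width = 2L)
    )
    S4Vectors::queryHits(IRanges::findOverlaps(gr, peaks))
  }
  a <- length(unique(in_peak(sites)))
  b <- nrow(sites) - a
  c_ <- length(unique(in_peak(bg)))
  d_ <- nrow(bg) - c_
  tab <- matrix(c(a, b, c_, d_),
    nrow = 2,
    dimnames = list(c("in_peak", "out_peak"), c("sites", "background"))
  )
  or <- if (b * c_ == 0) {
    if (a * d_ == 0) NaN else Inf
  } else {
    (a * d_) / (b * c_)
  }
  list(
    odds_ratio = or,
    p_value = stats::fisher.test(tab, alternative = "two.sided")$p.value,
    table = tab
  )
}

#' Read junction alignments from a SAM/BAM file
#'
#' Parses alignments against a composite donor+genome reference (donor
#' contig named `"donor"`) into the junction-read record table consumed by
#' [filter_reads()]. Donor mapping, primer start, attD intactness and the
#' clipped donor-side sequence are derived from the donor-contig
#' alignments; genome anchors from the genome-contig alignments.
#'
#' @param path SAM or BAM path (SAM is converted via [Rsamtools::asBam()]).
#' @param primer Primer sequence (reads must begin with it).
#' @param attd_interval 0-based half-open interval of the attD on the donor
#'   contig; a donor alignment spanning it marks the read attD-intact.
#' @param donor_contig Name of the donor contig (default `"donor"`).
#' @return Junction-read record table.
#' @export
read_junction_sam <- function(path, primer, attd_interval,
                              donor_contig = "donor") {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required to read SAM/BAM input")
  }
  primer <- .as_seq(primer)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path,
      destination = tempfile(), overwrite = TRUE,
      indexDestination = FALSE
    )
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "isize", "mpos")
  )
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  aligned <- !is.na(b$pos)
  df <- data.frame(
    qname = b$qname, flag = b$flag, rname = as.character(b$rname),
    pos = b$pos, mapq = b$mapq, cigar = b$cigar,
    seq = as.character(b$seq), isize = b$isize, mpos = b$mpos,
    stringsAsFactors = FALSE
  )[aligned, , drop = FALSE]
  df$supplementary <- bitwAnd(df$flag, 2048L) > 0L
  df$reverse <- bitwAnd(df$flag, 16L) > 0L
  donor <- df[df$rname == donor_contig, , drop = FALSE]
  genome <- df[df$rname != donor_contig & !df$supplementary, , drop = FALSE]
  donor_reads <- unique(donor$qname)
  attd_hit <- donor$qname[
    donor$pos - 1L <= attd_interval[1] &
      donor$pos - 1L + .cigar_ref_span(donor$cigar) >= attd_interval[2]
  ]
  out <- lapply(seq_len(nrow(genome)), function(i) {
    r <- genome[i, ]
    clip <- .leading_softclip(r$cigar, r$seq, r$reverse)
    read_seq <- if (r$reverse) revcomp(r$seq) else r$seq
    data.frame(
      read_id = r$qname,
      chrom = r$rname,
      pos = r$pos - 1L,
      strand = if (r$reverse) "-" else "+",
      aln_len = .cigar_ref_span(r$cigar),
      mapq = r$mapq,
      insert_size = abs(r$isize),
      maps_to_donor = r$qname %in% donor_reads,
      maps_to_genome = TRUE,
      begins_at_primer = startsWith(read_seq, primer),
      attd_intact = if (r$qname %in% attd_hit) "intact" else "disrupted",
      supplementary = FALSE,
      mate_pos = if (is.na(r$mpos)) NA_integer_ else r$mpos - 1L,
      umi = NA_character_,
      clip = clip,
      stringsAsFactors = FALSE
    )
  })
  if (length(out) == 0L) {
    return(.empty_junction_records())
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    if (ops[1] == -1L) {
      return(0L)
    }
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]", "", toks))
    op <- sub("\\d+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# Soft-clipped sequence on the junction side of the genome alignment, in
# read orientation (the donor-derived part, beginning at the primer).
.leading_softclip <- function(cigar, seq, reverse) {
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (length(toks) == 0L) {
    return(NA_character_)
  }
  n <- as.integer(sub("[MIDNSHP=X]", "", toks))
  op <- sub("\\d+", "", toks)
  if (!reverse) {
    if (op[1] != "S") {
      return(NA_character_)
    }
    substr(seq, 1L, n[1])
  } else {
    last <- length(op)
    if (op[last] != "S") {
      return(NA_character_)
    }
    revcomp(substr(seq, nchar(seq) - n[last] + 1L, nchar(seq)))
  }
}
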