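# Synthetic-data generators: genomes, planted integrations, junction reads
# and barcode amplicon reads with recorded ground truth. These define the
# study conditions under which the downstream modules are exercised.

#' Generate a random genome sequence
#'
#' Bases are drawn i.i.d. with the requested GC fraction (C and G equally
#' likely, likewise A and T). Identical seeds give identical sequences.
#'
#' @param length Genome length in bp (positive integer).
#' @param gc_fraction Target GC fraction in `[0, 1]`.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A character scalar of exactly `length` bases over ACGT.
#' @examples
#' make_genome(10, 0.5, seed = 1)
#' @export
make_genome <- function(length, gc_fraction = 0.5, seed = NULL) {
  stopifnot(is.numeric(length), length >= 1, gc_fraction >= 0, gc_fraction <= 1)
  length <- as.integer(length)
  probs <- c(
    A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
    G = gc_fraction / 2, T = (1 - gc_fraction) / 2
  )
  with_seed(seed, {
    paste(sample(DNA_BASES4, length, replace = TRUE, prob = probs), collapse = "")
  })
}

#' Plant a mobile-element integration into a genome
#'
#' Emulates the post-integration locus structure B1-D-P1-E-P2-D-B2: the
#' target-site segment `D` of length `duplication_len` starting at
#' `position` is duplicated on both sides of the inserted element. The
#' recorded truth uses the same canonical-leftmost breakpoint and
#' duplication inference as [find_insertion()], so planted truths and
#' recovered calls compare exactly even when microhomology makes the
#' breakpoint ambiguous.
#'
#' @param genome Pre-integration genome (character scalar).
#' @param element Element sequence to insert (length >= 1).
#' @param position 0-based insertion offset on `genome`.
#' @param duplication_len Length of the target-site duplication (>= 0).
#' @param core Optional 2-mer; when given and `duplication_len >= 2`, the
#'   central 2-mer of the duplicated segment in the returned pre-integration
#'   genome is overwritten with it, so the planted site carries this core.
#' @param seed Integer seed recorded in the truth (no randomness is used
#'   here unless `core` sampling is added by the caller).
#' @param window Attachment-site window width used for the recorded
#'   `true_attB`/`true_attP` (default 50 bp).
#' @return A list with `pre_genome`, `post_genome`, and `truth` (a
#'   `synthetic_truth` list: `genome_id`, `insertion_position`,
#'   `duplication`, `element`, `true_attB`, `true_attP`, `core`, `seed`).
#' @export
plant_integration <- function(genome, element, position, duplication_len = 0L,
                              core = NULL, seed = NULL, window = 50L) {
  genome <- .as_seq(genome)
  element <- .as_seq(element)
  stopifnot(nchar(element) >= 1, duplication_len >= 0)
  position <- as.integer(position)
  duplication_len <- as.integer(duplication_len)
  n <- nchar(genome)
  if (position < 0L || position + duplication_len > n) {
    stop("position out of range: insertion plus duplication must fit in the genome")
  }
  if (!is.null(core)) {
    stopifnot(nchar(core) == 2L)
    if (duplication_len >= 2L) {
      mid <- position + (duplication_len - 2L) %/% 2L
      substr(genome, mid + 1L, mid + 2L) <- toupper(core)
    } else {
      warning("core requested but duplication shorter than 2 bp; ignored")
    }
  }
  dup <- .substr0(genome, position, position + duplication_len)
  post <- paste0(
    .substr0(genome, 0L, position), dup, element,
    .substr0(genome, position, n)
  )

  # Canonicalize exactly as the boundary finder will: leftmost breakpoint,
  # duplication = maximal prefix of the inserted string matching the
  # reference at the breakpoint.
  canon <- .canonical_insertion(genome, post, position, nchar(element) + duplication_len)
  truth <- structure(
    list(
      genome_id = "synthetic",
      insertion_position = canon$position,
      duplication = canon$duplication,
      element = canon$element,
      true_attB = .att_window(genome, canon$position, nchar(canon$duplication), window),
      true_attP = .attp_window(canon$element, canon$duplication, window),
      core = NA_character_,
      seed = seed
    ),
    class = "synthetic_truth"
  )
  dlen <- nchar(canon$duplication)
  nl_off <- if (dlen >= window) 0L else (window - dlen) %/% 2L
  ctr <- .anchored_center(truth$true_attB, truth$true_attP, nl_off, min(dlen, window))
  if (is.null(ctr)) {
    ctr <- tryCatch(
      find_center(truth$true_attB, truth$true_attP),
      error = function(e) NULL
    )
  }
  if (!is.null(ctr)) truth$core <- ctr$core
  list(pre_genome = genome, post_genome = post, truth = truth)
}

# Shift a planted insertion (position p, inserted length L on the query) to
# its canonical-leftmost equivalent and split off the duplication.
.canonical_insertion <- function(ref, query, p, L) {
  r <- charToRaw(ref)
  q <- charToRaw(query)
  # leftmost: shift while the base before the breakpoint equals the last
  # base of the inserted string
  while (p > 0L && r[p] == q[p + L]) {
    p <- p - 1L
  }
  inserted <- .substr0(query, p, p + L)
  d <- .lcp(charToRaw(inserted), r, 0L, p)
  d <- min(d, L - 1L, nchar(ref) - p)
  list(
    position = p,
    duplication = .substr0(inserted, 0L, d),
    element = .substr0(inserted, d, L)
  )
}

# attB window: `window` bp of the pre-integration genome centered on the
# duplicated segment (or the breakpoint when |D| = 0).
.att_window <- function(genome, position, dup_len, window) {
  if (dup_len >= window) {
    off <- position + (dup_len - window) %/% 2L
    return(.substr0(genome, off, off + window))
  }
  nl <- (window - dup_len) %/% 2L
  nr <- window - dup_len - nl
  lo <- max(0L, position - nl)
  hi <- min(nchar(genome), position + dup_len + nr)
  .substr0(genome, lo, hi)
}

# attP window: element suffix + duplication + element prefix, trimmed the
# same way (the element circularizes, joining its two ends around D).
.attp_window <- function(element, dup, window) {
  d <- nchar(dup)
  if (d >= window) {
    off <- (d - window) %/% 2L
    return(.substr0(dup, off, off + window))
  }
  nl <- (window - d) %/% 2L
  nr <- window - d - nl
  ne <- nchar(element)
  left <- .substr0(element, max(0L, ne - nl), ne)
  right <- .substr0(element, 0L, min(ne, nr))
  paste0(left, dup, right)
}

#' Simulate donor-genome junction reads
#'
#' Generates single-end junction reads (with paired genome-side mates) for a
#' set of planted integration sites, as produced by a unidirectional
#' targeted sequencing assay: each junction read starts at the donor primer,
#' runs through the donor attachment site up to the crossover core, and
#' continues into the genome at the planted site. The implied alignments
#' against a composite donor+genome reference are returned directly as a
#' junction-read record table (the form consumed by [filter_reads()]),
#' alongside the raw reads. A configurable fraction of donor-only
#' (unintegrated, attD-intact) reads is mixed in to exercise the read
#' filters.
#'
#' @param genome Target genome (character scalar, single contig) or a named
#'   character vector of contigs.
#' @param sites Data frame with columns `chrom`, `pos` (0-based genomic
#'   coordinate of the core 2-mer) and `strand` (`"+"`/`"-"`). For a single
#'   unnamed contig use chrom `"chr"`.
#' @param donor Donor sequence containing the primer and the attD site.
#' @param primer Primer sequence; must be a substring of `donor`.
#' @param core_offset 0-based offset of the crossover core 2-mer in `donor`.
#' @param n_reads Number of junction read pairs to simulate.
#' @param error_rate Per-base substitution error rate.
#' @param read_len Read length in bp.
#' @param background_frac Fraction of extra donor-only reads added on top of
#'   `n_reads` (these fail the attD-intact filter).
#' @param umi Logical; attach a per-molecule UMI to each record.
#' @param seed Integer seed.
#' @return List with `reads` (data frame: `read_id`, `seq`, `qual`),
#'   `records` (junction-read record table), and `truth` (the `sites` table
#'   with per-site read counts).
#' @export
simulate_junction_reads <- function(genome, sites, donor, primer, core_offset,
                                    n_reads = 2000L, error_rate = 0.001,
                                    read_len = 150L, background_frac = 0.05,
                                    umi = FALSE, seed = NULL) {
  if (is.null(names(genome))) {
    genome <- c(chr = .as_seq(genome))
  } else {
    genome <- vapply(genome, .as_seq, character(1))
  }
  donor <- .as_seq(donor)
  primer <- .as_seq(primer)
  pr_start <- as.integer(regexpr(primer, donor, fixed = TRUE)) - 1L
  if (pr_start < 0L) stop("primer absent from donor")
  stopifnot(core_offset >= pr_start, core_offset + 2L <= nchar(donor))
  stopifnot(is.data.frame(sites), all(c("chrom", "pos", "strand") %in% names(sites)))
  n_reads <- as.integer(n_reads)

  donor_part <- .substr0(donor, pr_start, core_offset) # primer .. core start

  with_seed(seed, {
    if (n_reads == 0L || nrow(sites) == 0L) {
      truth <- sites
      truth$n_reads <- rep(0L, nrow(sites))
      return(list(
        reads = data.frame(read_id = character(0), seq = character(0), qual = character(0)),
        records = .empty_junction_records(),
        truth = truth
      ))
    }
    site_of_read <- sample(nrow(sites), n_reads, replace = TRUE)
    recs <- vector("list", n_reads)
    reads <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      s <- sites[site_of_read[i], ]
      g <- genome[[s$chrom]]
      glen_avail <- read_len - nchar(donor_part)
      stopifnot(glen_avail >= 20L)
      # jitter the genome-side extent so duplicates are distinguishable
      gl <- max(20L, glen_avail - sample(0:10, 1L))
      if (s$strand == "+") {
        gseq <- .substr0(g, s$pos, min(nchar(g), s$pos + gl))
        pos <- s$pos
        aln_len <- nchar(gseq)
      } else {
        hi <- s$pos + 2L
        lo <- max(0L, hi - gl)
        gseq <- revcomp(.substr0(g, lo, hi))
        pos <- lo
        aln_len <- nchar(gseq)
      }
      seqi <- paste0(donor_part, gseq)
      seqi <- .apply_errors(seqi, error_rate)
      mate_pos <- if (s$strand == "+") pos + aln_len + sample(50:400, 1L) else max(0L, pos - sample(50:400, 1L))
      recs[[i]] <- data.frame(
        read_id = sprintf("jx%05d", i),
        chrom = s$chrom, pos = pos, strand = s$strand, aln_len = aln_len,
        mapq = 60L,
        insert_size = abs(mate_pos - pos) + read_len,
        maps_to_donor = TRUE, maps_to_genome = TRUE,
        begins_at_primer = TRUE, attd_intact = "disrupted",
        supplementary = FALSE, mate_pos = mate_pos,
        umi = if (umi) paste(sample(DNA_BASES4, 12L, replace = TRUE), collapse = "") else NA_character_,
        clip = .substr0(seqi, 0L, nchar(donor_part)),
        stringsAsFactors = FALSE
      )
      reads[[i]] <- data.frame(
        read_id = recs[[i]]$read_id, seq = seqi,
        qual = .sim_quals(nchar(seqi)), stringsAsFactors = FALSE
      )
    }
    records <- do.call(rbind, recs)
    reads <- do.call(rbind, reads)

    n_bg <- as.integer(round(n_reads * background_frac))
    if (n_bg > 0L) {
      bg <- vector("list", n_bg)
      for (i in seq_len(n_bg)) {
        seqi <- .apply_errors(.substr0(donor, pr_start, min(nchar(donor), pr_start + read_len)), error_rate)
        bg[[i]] <- data.frame(
          read_id = sprintf("bg%05d", i),
          chrom = NA_character_, pos = NA_integer_, strand = NA_character_,
          aln_len = NA_integer_, mapq = 60L, insert_size = 300L,
          maps_to_donor = TRUE, maps_to_genome = FALSE,
          begins_at_primer = TRUE, attd_intact = "intact",
          supplementary = FALSE, mate_pos = NA_integer_,
          umi = NA_character_, clip = NA_character_,
          stringsAsFactors = FALSE
        )
        reads <- rbind(reads, data.frame(
          read_id = bg[[i]]$read_id, seq = seqi,
          qual = .sim_quals(nchar(seqi)), stringsAsFactors = FALSE
        ))
      }
      records <- rbind(records, do.call(rbind, bg))
    }
    truth <- sites
    truth$n_reads <- tabulate(site_of_read, nbins = nrow(sites))
    list(reads = reads, records = records, truth = truth)
  })
}

.empty_junction_records <- function() {
  data.frame(
    read_id = character(0), chrom = character(0), pos = integer(0),
    strand = character(0), aln_len = integer(0), mapq = integer(0),
    insert_size = integer(0), maps_to_donor = logical(0),
    maps_to_genome = logical(0), begins_at_primer = logical(0),
    attd_intact = character(0), supplementary = logical(0),
    mate_pos = integer(0), umi = character(0), clip = character(0),
    stringsAsFactors = FALSE
  )
}

.apply_errors <- function(seq, error_rate) {
  if (error_rate <= 0) {
    return(seq)
  }
  n <- nchar(seq)
  hits <- which(stats::runif(n) < error_rate)
  if (length(hits) == 0L) {
    return(seq)
  }
  ch <- strsplit(seq, "")[[1]]
  for (h in hits) {
    ch[h] <- sample(setdiff(DNA_BASES4, ch[h]), 1L)
  }
  paste(ch, collapse = "")
}

# Q37 baseline with seeded per-base degradation (exercises Q30 filters).
.sim_quals <- function(n, baseline = 37L, degrade_prob = 0.01, degraded = 15L) {
  q <- rep(baseline, n)
  bad <- which(stats::runif(n) < degrade_prob)
  q[bad] <- degraded
  intToUtf8(q + 33L)
}

#' Simulate barcode amplicon reads
#'
#' Each read is `prefix + barcode + suffix` with Q37-baseline qualities and
#' seeded per-base degradation; barcodes are drawn uniformly from the 4^k
#' universe at the requested mean depth.
#'
#' @param prefix,suffix Constant amplicon context around the barcode.
#' @param k Barcode length (default 6).
#' @param depth Mean reads per barcode (Poisson).
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @return List with `reads` (data frame `read_id`, `seq`, `qual`),
#'   `barcode_offset` (0-based), and `truth` (true count per barcode).
#' @export
simulate_barcode_reads <- function(prefix = "ACGTAC", suffix = "TGCATG", k = 6L,
                                   depth = 3, error_rate = 0, seed = NULL) {
  k <- as.integer(k)
  universe <- barcode_universe(k)
  with_seed(seed, {
    counts <- stats::rpois(length(universe), depth)
    bcs <- rep(universe, counts)
    if (length(bcs) > 0L) bcs <- sample(bcs)
    seqs <- vapply(
      bcs,
      function(b) .apply_errors(paste0(prefix, b, suffix), error_rate),
      character(1), USE.NAMES = FALSE
    )
    list(
      reads = data.frame(
        read_id = sprintf("bc%06d", seq_along(seqs)),
        seq = seqs,
        qual = vapply(nchar(seqs), .sim_quals, character(1)),
        stringsAsFactors = FALSE
      ),
      barcode_offset = nchar(prefix),
      truth = stats::setNames(counts, universe)
    )
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(
    "Planted integration (", x$genome_id, ")\n",
    "  position: ", x$insertion_position,
    "  |D| = ", nchar(x$duplication),
    "  |E| = ", nchar(x$element), "\n",
    "  attB: ", x$true_attB, "\n",
    "  attP: ", x$true_attP, "\n",
    "  core: ", x$core, "\n",
    sep = ""
  )
  invisible(x)
}
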