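base_record <- function(...) {
  defaults <- list(
    read_id = "r1", chrom = "chr", pos = 1000L, strand = "+", aln_len = 100L,
    mapq = 60L, insert_size = 300L, maps_to_donor = TRUE,
    maps_to_genome = TRUE, begins_at_primer = TRUE,
    attd_intact = "disrupted", supplementary = FALSE, mate_pos = 1400L,
    umi = NA_character_, clip = "ACGTACGT", stringsAsFactors = FALSE
  )
  do.call(data.frame, utils::modifyList(defaults, list(...)))
}

test_that("read filters apply the stated gates exactly and deduplicate", {
  recs <- rbind(
    base_record(read_id = "keep30", mapq = 30L),
    base_record(read_id = "drop29", mapq = 29L, pos = 1001L),
    base_record(read_id = "keep1500", insert_size = 1500L, pos = 1002L),
    base_record(read_id = "drop1501", insert_size = 1501L, pos = 1003L),
    base_record(read_id = "drop_intact", attd_intact = "intact", pos = 1004L),
    base_record(read_id = "keep_undet", attd_intact = "undeterminable", pos = 1005L),
    base_record(read_id = "drop_suppl", supplementary = TRUE, pos = 1006L),
    base_record(read_id = "drop_donor_only", maps_to_genome = FALSE, pos = 1007L),
    base_record(read_id = "drop_no_primer", begins_at_primer = FALSE, pos = 1008L)
  )
  kept <- filter_reads(recs)
  expect_setequal(kept$read_id, c("keep30", "keep1500", "keep_undet"))

  # positional duplicate collapse on (chrom, pos, strand, mate)
  dups <- rbind(
    base_record(read_id = "a"),
    base_record(read_id = "b"), # same key as a
    base_record(read_id = "c", mate_pos = 1500L)
  )
  kept2 <- filter_reads(dups)
  expect_equal(nrow(kept2), 2)
  expect_equal(attr(kept2, "filter_stats")[["duplicates"]], 1)

  # UMI-aware collapse keeps distinct molecules at one position
  umis <- rbind(
    base_record(read_id = "a", umi = "AAAA"),
    base_record(read_id = "b", umi = "AAAA"),
    base_record(read_id = "c", umi = "CCCC")
  )
  expect_equal(nrow(filter_reads(umis)), 2)

  # idempotence
  once <- filter_reads(recs)
  twice <- filter_reads(once)
  attr(once, "filter_stats") <- NULL
  attr(twice, "filter_stats") <- NULL
  expect_identical(once, twice)

  expect_error(filter_reads(data.frame(read_id = "x")), "malformed")
})

test_that("clip consensus takes per-position majority with N on ties", {
  recs <- rbind(
    base_record(read_id = "a", clip = "ACGTACGT"),
    base_record(read_id = "b", clip = "ACGTACGT"),
    base_record(read_id = "c", clip = "ACGAACGT")
  )
  cons <- consensus_clips(recs)
  expect_equal(nrow(cons), 1)
  expect_identical(cons$consensus, "ACGTACGT")
  expect_equal(cons$n_reads, 3)

  tied <- rbind(
    base_record(read_id = "a", clip = "ACGT"),
    base_record(read_id = "b", clip = "ACTT")
  )
  expect_identical(consensus_clips(tied)$consensus, "ACNT")

  expect_identical(
    consensus_clips(base_record(clip = "GATTACA"))$consensus, "GATTACA"
  )
})

test_that("site calling applies k-mer, identity and core-distance gates", {
  attd_sub <- make_genome(80, seed = 81)
  core_pos <- 40L
  anchor <- function(consensus, strand = "+", jpos = 5000L) {
    data.frame(
      chrom = "chr", junction_pos = jpos, strand = strand,
      n_reads = 3L, consensus = consensus, stringsAsFactors = FALSE
    )
  }

  # consensus sharing no 9-mer with the attD subsequence is discarded
  res <- call_sites(anchor(make_genome(40, seed = 82)), attd_sub, core_pos)
  expect_equal(nrow(res$sites), 0)
  expect_identical(res$rejections$reason, "no_shared_kmer")

  # identity gate at 0.80: a consensus matching the attD prefix exactly in
  # one 12-bp stretch but heavily mutated elsewhere fails; light mutation passes
  prefix <- substr(attd_sub, 1, 42)
  set.seed(83)
  heavy <- paste0(substr(prefix, 1, 12), substitute_fraction(substr(prefix, 13, 42), 0.5))
  res_heavy <- call_sites(anchor(heavy), attd_sub, core_pos)
  expect_equal(nrow(res_heavy$sites), 0)
  light <- paste0(substr(prefix, 1, 12), substitute_fraction(substr(prefix, 13, 42), 0.1))
  res_light <- call_sites(anchor(light), attd_sub, core_pos)
  expect_equal(nrow(res_light$sites), 1)

  # crossover distance gate: alignment ending 15 bp from the core end is
  # kept, 16 bp is rejected
  cons15 <- substr(attd_sub, 1, core_pos + 2 - 15)
  cons16 <- substr(attd_sub, 1, core_pos + 2 - 16)
  expect_equal(nrow(call_sites(anchor(cons15), attd_sub, core_pos)$sites), 1)
  rej16 <- call_sites(anchor(cons16), attd_sub, core_pos)
  expect_equal(nrow(rej16$sites), 0)
  expect_identical(rej16$rejections$reason, "crossover_far_from_core")

  # orientation converts the junction coordinate to the core position
  full <- substr(attd_sub, 1, core_pos + 2)
  plus <- call_sites(anchor(full, "+", 7000L), attd_sub, core_pos)$sites
  minus <- call_sites(anchor(full, "-", 7000L), attd_sub, core_pos)$sites
  expect_equal(plus$position, 7000)
  expect_equal(minus$position, 6998)

  # support floor
  res_min <- call_sites(anchor(full), attd_sub, core_pos, min_support = 5)
  expect_identical(res_min$rejections$reason, "insufficient_support")
})

test_that("locus merging is single-linkage at 500 bp with normalized shares", {
  sites <- data.frame(
    chrom = "chr",
    position = c(100L, 550L, 1200L),
    orientation = c("+", "-", "+"),
    support = c(6L, 3L, 1L), stringsAsFactors = FALSE
  )
  loci <- merge_loci(sites)
  expect_equal(nrow(loci), 2) # 100 and 550 merge (gap 450), 1200 separate
  expect_equal(loci$read_count, c(9, 1))
  expect_equal(loci$percent, c(90, 10))
  expect_equal(sum(loci$percent), 100, tolerance = 0.01)

  # opposite orientations 10 bp apart form one locus
  close_pair <- data.frame(
    chrom = "chr", position = c(100L, 110L),
    orientation = c("+", "-"), support = c(1L, 1L), stringsAsFactors = FALSE
  )
  expect_equal(nrow(merge_loci(close_pair)), 1)

  # counting conservation
  expect_equal(sum(loci$read_count), sum(sites$support))
})

test_that("locus motifs honor orientation and one-site-per-locus selection", {
  genome <- c(chr = make_genome(4000, seed = 91))
  sites <- data.frame(
    chrom = "chr", position = c(1000L, 1010L, 3000L),
    orientation = c("+", "+", "-"),
    support = c(5L, 2L, 4L), stringsAsFactors = FALSE
  )
  loci <- merge_loci(sites)
  m <- locus_motif(loci, sites, genome, flank_bp = 10)
  expect_equal(nrow(m$freq), 22)

  # single + site: motif is the one-hot of its window
  s1 <- sites[1, , drop = FALSE]
  m1 <- locus_motif(merge_loci(s1), s1, genome, flank_bp = 5)
  win <- substr(genome[["chr"]], 1000 - 5 + 1, 1000 + 2 + 5)
  expect_identical(
    paste(colnames(m1$freq)[apply(m1$freq, 1, which.max)], collapse = ""),
    win
  )

  # single - site: window reverse-complemented before stacking
  s3 <- sites[3, , drop = FALSE]
  m3 <- locus_motif(merge_loci(s3), s3, genome, flank_bp = 5)
  win3 <- revcomp(substr(genome[["chr"]], 3000 - 5 + 1, 3000 + 2 + 5))
  expect_identical(
    paste(colnames(m3$freq)[apply(m3$freq, 1, which.max)], collapse = ""),
    win3
  )

  # out-of-bounds windows are skipped with a warning
  edge <- data.frame(
    chrom = "chr", position = 2L, orientation = "+",
    support = 1L, stringsAsFactors = FALSE
  )
  both <- rbind(edge, s1)
  expect_warning(
    locus_motif(merge_loci(both), both, genome, flank_bp = 10),
    "bounds"
  )
})

test_that("integration sites recover a planted target motif", {
  # 50 sites drawn at positions whose windows share a planted 20-bp pattern
  target <- make_genome(20, seed = 95)
  genome <- make_genome(300000, seed = 96)
  pos <- seq(3000L, 297000L, length.out = 50)
  pos <- as.integer(round(pos))
  gch <- strsplit(genome, "")[[1]]
  tch <- strsplit(target, "")[[1]]
  set.seed(97)
  for (p in pos) {
    copy <- tch
    idx <- which(runif(20) < 0.1) # slight per-site divergence
    for (j in idx) copy[j] <- sample(c("A", "C", "G", "T"), 1)
    gch[(p - 8):(p + 11)] <- copy
  }
  genome <- paste(gch, collapse = "")
  sites <- data.frame(
    chrom = "chr", position = pos, orientation = "+",
    support = 2L, stringsAsFactors = FALSE
  )
  m <- locus_motif(merge_loci(sites), sites, c(chr = genome), flank_bp = 9)
  # generator-recovery: per-cell frequency error below 0.1 against the
  # generating composition (0.9 planted base, ~0.033 others)
  gen <- matrix(0.1 / 3, nrow = 20, ncol = 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in 1:20) gen[i, tch[i]] <- 0.9 + 0.1 / 3
  expect_lt(max(abs(m$freq[1:20, ] - gen)), 0.1)
})

test_that("accessibility enrichment builds a seeded Fisher table", {
  sites <- data.frame(
    chrom = "chr", position = seq(10000L, 100000L, by = 10000L),
    stringsAsFactors = FALSE
  )
  peaks <- data.frame(
    chrom = "chr", start = sites$position - 50L, end = sites$position + 50L
  )
  res <- accessibility_enrichment(sites, peaks, seed = 5)
  expect_equal(res$table["in_peak", "sites"], 10)
  expect_lt(res$p_value, 0.01)
  expect_identical(res$odds_ratio, Inf)

  # reproducible under the same seed
  res2 <- accessibility_enrichment(sites, peaks, seed = 5)
  expect_identical(res$table, res2$table)

  # unknown chromosomes are counted out-of-peak with a warning
  off <- data.frame(chrom = "chrX", position = 5000L, stringsAsFactors = FALSE)
  expect_warning(
    res3 <- accessibility_enrichment(rbind(sites, off), peaks, seed = 5),
    "absent"
  )
  expect_equal(res3$table["out_peak", "sites"], 1)
})

test_that("the junction pipeline recovers planted sites end to end", {
  sc <- junction_scenario(8, genome_len = 200000L, seed = 301L)
  sim <- simulate_junction_reads(sc$genome, sc$sites, sc$donor, sc$primer,
    sc$core_off,
    n_reads = 600, error_rate = 0.001, seed = 302
  )
  kept <- filter_reads(sim$records)
  cons <- consensus_clips(kept)
  res <- call_sites(cons, sc$attd_subseq, sc$core_in_subseq)
  hit <- vapply(sc$sites$pos, function(p) {
    any(abs(res$sites$position - p) <= 1)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
  stray <- vapply(res$sites$position, function(x) min(abs(x - sc$sites$pos)), numeric(1))
  expect_lte(max(stray), 15)
  loci <- merge_loci(res$sites)
  expect_equal(sum(loci$percent), 100, tolerance = 0.01)
  expect_equal(sum(loci$read_count), sum(res$sites$support))
})

test_that("SAM alignments are parsed into junction records", {
  skip_if_not_installed("Rsamtools")
  tmp <- withr::local_tempdir()
  sam <- file.path(tmp, "jx.sam")
  # read r1: 8S12M at chr:101 (1-based), forward; clip GATTACAG
  # read r2: 12M8S at chr:201, reverse (stored revcomp'd)
  # read r3: donor-only alignment spanning the attD interval
  r1_seq <- paste0("GATTACAG", "AAAACCCCGGGG")
  r2_read <- paste0("GATTACAG", "TTTTGGGGCCCC") # read orientation
  r2_stored <- revcomp(r2_read)
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr\tLN:10000",
    "@SQ\tSN:donor\tLN:500",
    paste("r1", 0, "chr", 101, 60, "8S12M", "*", 0, 0, r1_seq,
      strrep("I", 20),
      sep = "\t"
    ),
    paste("r1", 2048, "donor", 11, 60, "8M12S", "*", 0, 0, r1_seq,
      strrep("I", 20),
      sep = "\t"
    ),
    paste("r2", 16, "chr", 201, 45, "12M8S", "*", 0, 0, r2_stored,
      strrep("I", 20),
      sep = "\t"
    ),
    paste("r3", 0, "donor", 1, 60, "40M", "*", 0, 0, strrep("A", 40),
      strrep("I", 40),
      sep = "\t"
    )
  ), sam)
  recs <- read_junction_sam(sam, primer = "GATTACA", attd_interval = c(5L, 30L))
  expect_equal(nrow(recs), 2) # genome-anchored reads only
  r1 <- recs[recs$read_id == "r1", ]
  expect_equal(r1$pos, 100)
  expect_identical(r1$strand, "+")
  expect_identical(r1$clip, "GATTACAG")
  expect_true(r1$maps_to_donor)
  expect_true(r1$begins_at_primer)
  r2 <- recs[recs$read_id == "r2", ]
  expect_identical(r2$strand, "-")
  expect_identical(r2$clip, "GATTACAG")
  expect_false(r2$maps_to_donor)
  expect_equal(r2$aln_len, 12)
})
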