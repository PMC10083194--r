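test_that("core dinucleotide scoring balances conservation and centrality", {
  # identical sequences: the exact central pair wins with score 1
  rows <- rep(make_genome(20, seed = 1), 5)
  ranked <- score_core_dinucleotides(rows)
  expect_equal(ranked$col_left[1], 10)
  expect_equal(ranked$score[1], 1.0)
  expect_equal(ranked$conservation[1], 1.0)

  # one perfectly conserved central TT among otherwise random sequences
  set.seed(2)
  n <- 20
  rows <- vapply(seq_len(n), function(i) {
    s <- make_genome(20, seed = 100 + i)
    substr(s, 10, 11) <- "TT"
    s
  }, character(1))
  ranked <- score_core_dinucleotides(rows)
  # brute-force recomputation of every pair score
  mat <- do.call(rbind, strsplit(rows, ""))
  brute <- vapply(1:19, function(i) {
    cons <- mean(c(
      max(table(mat[, i])) / n,
      max(table(mat[, i + 1])) / n
    ))
    dist <- abs((i + 0.5) - 10.5) / 10
    0.5 * cons + 0.5 * (1 - dist)
  }, numeric(1))
  expect_equal(ranked$col_left[1], which.max(brute))
  expect_equal(ranked$col_left[1], 10)
  expect_equal(ranked$score, sort(brute, decreasing = TRUE), tolerance = 1e-12)
})

test_that("core anchoring pads flanks without internal gaps", {
  # equal-length centered cores: alignment equals the input stack
  rows <- c("AAATTGGG", "CCCTTAAA")
  al <- align_on_core(rows, c(3, 3))
  expect_identical(al$rows, rows)
  expect_equal(al$core_col, 4)

  # offsets 3 and 7 in 10-mers: width 2 + max(3,7) + max(5,1) = 14
  al2 <- align_on_core(c("AAACCGGGTT", "TTTTTTTCCA"), c(3, 7))
  expect_equal(al2$width, 14)
  expect_equal(unique(nchar(al2$rows)), 14)
  # the core columns coincide
  expect_identical(substr(al2$rows[1], 8, 9), "CC")
  expect_identical(substr(al2$rows[2], 8, 9), "CC")

  single <- align_on_core("ACGTAC", 2)
  expect_equal(single$width, 6)

  expect_error(align_on_core("ACGT", 3), "out of bounds")
})

test_that("motif frequencies are pseudocount-smoothed and normalized", {
  m <- build_motif(c("AAA", "AAA", "AAA"), pseudocount = 0.01)
  expect_equal(unname(m$freq[1, "A"]), 3.01 / 3.04)
  expect_true(all(abs(rowSums(m$freq) - 1) < 1e-9))

  # sampling tolerance at 10,000 uniform rows
  set.seed(3)
  rows <- vapply(1:10000, function(i) {
    paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
  }, character(1))
  mu <- build_motif(rows)
  expect_true(all(abs(mu$freq - 0.25) < 0.02))

  # all-gap column flagged uniform
  expect_warning(mg <- build_motif(c("A-A", "A-A")), "uniform")
  expect_equal(mg$freq[2, ], c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  expect_equal(mg$uniform_cols, 2)
})

test_that("post hoc motif construction applies identity floors and redundancy caps", {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  query_prot <- paste(rep(aa, 15), collapse = "") # 150 aa
  mutate_prot <- function(frac, seed) {
    set.seed(seed)
    ch <- strsplit(query_prot, "")[[1]]
    idx <- sample(length(ch), round(frac * length(ch)))
    ch[idx] <- "W"
    paste(ch, collapse = "")
  }
  query_attB <- make_genome(50, seed = 10)

  # relative below the 30% identity floor contributes nothing
  db_low <- data.frame(
    lsr_id = "rel1", protein = mutate_prot(0.71, 1),
    attB = make_genome(50, seed = 11), stringsAsFactors = FALSE
  )
  expect_warning(
    m_low <- build_posthoc_motif(query_prot, query_attB, db_low),
    "query attB alone"
  )
  expect_equal(m_low$n_sites_used, 0)

  # attB more than 95% identical to an already-selected site is skipped
  near_dup <- query_attB
  substr(near_dup, 25, 25) <- setdiff(c("A", "C", "G", "T"), substr(near_dup, 25, 25))[1]
  set.seed(12)
  distinct <- substitute_fraction(query_attB, 0.2)
  db <- data.frame(
    lsr_id = c("rel1", "rel2"),
    protein = c(mutate_prot(0.1, 2), mutate_prot(0.2, 3)),
    attB = c(near_dup, distinct),
    stringsAsFactors = FALSE
  )
  m <- build_posthoc_motif(query_prot, query_attB, db)
  expect_equal(m$n_sites_used, 1)
  expect_identical(m$relatives_used, "rel2")

  # 25 planted relatives sharing a 30-bp block: the motif consensus
  # recovers the block over its columns
  block <- make_genome(30, seed = 20)
  query_attB2 <- paste0(make_genome(10, seed = 21), block, make_genome(10, seed = 22))
  set.seed(23)
  rel_attBs <- vapply(1:25, function(i) {
    paste0(
      make_genome(10, seed = 30 + i),
      substitute_fraction(block, 0.05),
      make_genome(10, seed = 60 + i)
    )
  }, character(1))
  db2 <- data.frame(
    lsr_id = sprintf("rel%02d", 1:25),
    protein = vapply(1:25, function(i) mutate_prot(0.3, 100 + i), character(1)),
    attB = rel_attBs, stringsAsFactors = FALSE
  )
  m2 <- build_posthoc_motif(query_prot, query_attB2, db2, n_sites = 25)
  expect_gte(m2$n_sites_used, 20)
  block_cols <- which(m2$query_positions %in% 10:39)
  consensus <- colnames(m2$freq)[apply(m2$freq[block_cols, , drop = FALSE], 1, which.max)]
  expected <- strsplit(block, "")[[1]][m2$query_positions[block_cols] - 10 + 1]
  expect_identical(consensus, expected)
})

test_that("log-odds scanning matches hand computation and strand symmetry", {
  uniform <- build_motif(c("ACGT", "CGTA", "GTAC", "TACG"))
  # uniform motif, uniform background: all scores 0
  sc <- scan_motif(
    structure(
      list(
        freq = matrix(0.25, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T"))),
        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
      ),
      class = "nucleotide_motif"
    ),
    c(x = make_genome(30, seed = 5))
  )
  expect_equal(sc$score, 0)

  m <- structure(
    list(
      freq = matrix(rep(c(0.7, 0.1, 0.1, 0.1), 3),
        nrow = 3, byrow = TRUE,
        dimnames = list(NULL, c("A", "C", "G", "T"))
      ),
      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
    ),
    class = "nucleotide_motif"
  )
  expect_equal(scan_motif(m, "AAA")$score, 3 * log2(2.8))

  # a reverse-complemented sequence scores identically
  s <- make_genome(60, seed = 6)
  expect_equal(scan_motif(m, s)$score, scan_motif(m, revcomp(s))$score)

  # scanning the motif built solely from one sequence peaks at the source
  src <- make_genome(12, seed = 7)
  host <- paste0(make_genome(20, seed = 8), src, make_genome(20, seed = 9))
  m1 <- build_motif(src)
  hit <- scan_motif(m1, host)
  expect_equal(hit$position, 20)
  max_possible <- sum(log2(apply(m1$freq, 1, max) / 0.25))
  expect_equal(hit$score, max_possible)
})

test_that("ROC equals the Mann-Whitney statistic with trapezoidal ties", {
  expect_equal(roc_auc(c(5, 6, 7), c(1, 2, 3))$auc, 1.0)
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)

  set.seed(8)
  for (trial in 1:50) {
    n1 <- sample(5:40, 1)
    n2 <- sample(5:40, 1)
    pos <- round(rnorm(n1, mean = runif(1, -1, 1)), sample(0:2, 1))
    neg <- round(rnorm(n2), sample(0:2, 1))
    r <- roc_auc(pos, neg)
    u <- suppressWarnings(wilcox.test(pos, neg)$statistic)
    expect_equal(r$auc, unname(u) / (n1 * n2), tolerance = 1e-12)
    # complement symmetry and monotone curve
    expect_equal(roc_auc(neg, pos)$auc, 1 - r$auc, tolerance = 1e-12)
    expect_true(all(diff(r$tpr) >= 0))
    expect_true(all(diff(r$fpr) >= 0))
  }
})

test_that("MEME serialization writes a parseable frequency matrix", {
  m <- build_motif(c("ACGT", "ACGT", "ACGA"))
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(m, path, name = "demo")
  lines <- readLines(path)
  expect_true(any(grepl("^MOTIF demo", lines)))
  hdr <- grep("letter-probability matrix", lines)
  mat <- read.table(text = lines[(hdr + 1):(hdr + 4)])
  expect_equal(as.matrix(mat), unname(m$freq), tolerance = 1e-5, ignore_attr = TRUE)
})
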