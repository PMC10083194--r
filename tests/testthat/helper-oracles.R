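# Shared generators and independent oracles used across the suite.

# Brute-force longest common substring by enumerating all substrings of the
# shorter sequence (quadratic; fine at test scale).
brute_lcs <- function(a, b) {
  if (nchar(a) > nchar(b)) {
    tmp <- a
    a <- b
    b <- tmp
  }
  best <- ""
  for (len in nchar(a):1) {
    for (s in 1:(nchar(a) - len + 1)) {
      sub <- substr(a, s, s + len - 1)
      if (grepl(sub, b, fixed = TRUE)) {
        return(sub)
      }
    }
  }
  best
}

# Exhaustive hypergeometric enumeration of the two-sided Fisher p for a
# 2x2 table (sum of probabilities of tables at most as probable).
enumerate_fisher_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Direct, loop-based application of the site-specific rule: target clusters
# hit by >= 3 LSR clusters are retained; LSR clusters whose retained edges
# cover exactly one target cluster are site-specific.
brute_site_specific <- function(edges) {
  edges <- unique(edges)
  kept_targets <- character(0)
  for (t in unique(edges$target_cluster)) {
    lsrs <- unique(edges$lsr_cluster[edges$target_cluster == t])
    if (length(lsrs) >= 3) kept_targets <- c(kept_targets, t)
  }
  out <- character(0)
  for (l in unique(edges$lsr_cluster)) {
    targets <- unique(edges$target_cluster[
      edges$lsr_cluster == l & edges$target_cluster %in% kept_targets
    ])
    if (length(targets) == 1) out <- c(out, l)
  }
  sort(out)
}

# Direct application of the multi-targeting binning rules at 90% and 50%
# cluster levels.
brute_multi_targeting <- function(edges90, map) {
  edges90 <- unique(edges90)
  map_v <- setNames(as.character(map$lsr50_cluster), as.character(map$lsr90_cluster))
  bins <- list()
  for (l in unique(edges90$lsr90_cluster)) {
    n <- length(unique(edges90$target_cluster[edges90$lsr90_cluster == l]))
    if (n < 2) next
    bin <- if (n > 3) ">3" else as.character(n)
    l50 <- map_v[[as.character(l)]]
    bins[[l50]] <- c(bins[[l50]], bin)
  }
  if (length(bins) == 0) {
    return(setNames(character(0), character(0)))
  }
  lvl <- c("2", "3", ">3")
  out <- vapply(bins, function(b) lvl[max(match(b, lvl))], character(1))
  out[base::order(names(out))]
}

# A random bipartite LSR-target toy graph.
random_bipartite <- function(n_lsr, n_target, n_edges) {
  data.frame(
    lsr_cluster = paste0("L", sample(n_lsr, n_edges, replace = TRUE)),
    target_cluster = paste0("T", sample(n_target, n_edges, replace = TRUE)),
    stringsAsFactors = FALSE
  )
}

# A family of sequences mutated from a common ancestor.
mutated_family <- function(base, n, sub_rate) {
  vapply(seq_len(n), function(i) {
    ch <- strsplit(base, "")[[1]]
    idx <- which(runif(length(ch)) < sub_rate)
    for (j in idx) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
    paste(ch, collapse = "")
  }, character(1))
}

# Substitute an exact fraction of positions (used for identity-threshold
# boundary cases).
substitute_fraction <- function(seq, fraction) {
  ch <- strsplit(seq, "")[[1]]
  idx <- sample(length(ch), round(fraction * length(ch)))
  for (j in idx) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
  paste(ch, collapse = "")
}

# Standard junction-sequencing scenario: a donor carrying an attD, planted
# genomic sites whose core 2-mer matches the donor core.
junction_scenario <- function(n_sites, genome_len = 500000L, seed = 101L) {
  donor_left <- make_genome(80, seed = seed + 1L)
  attd <- make_genome(50, seed = seed + 2L)
  donor <- paste0(donor_left, attd, make_genome(60, seed = seed + 3L))
  primer <- substr(donor_left, 11, 30)
  core_off <- 80L + 24L
  core <- substr(donor, core_off + 1L, core_off + 2L)
  genome <- make_genome(genome_len, seed = seed)
  pos <- sort(sample(seq(10000L, genome_len - 10000L, by = 1000L), n_sites))
  gch <- strsplit(genome, "")[[1]]
  for (p in pos) {
    gch[p + 1L] <- substr(core, 1, 1)
    gch[p + 2L] <- substr(core, 2, 2)
  }
  genome <- paste(gch, collapse = "")
  pr_start <- as.integer(regexpr(primer, donor, fixed = TRUE)) - 1L
  list(
    genome = genome, donor = donor, primer = primer, core_off = core_off,
    sites = data.frame(
      chrom = "chr", pos = pos,
      strand = sample(c("+", "-"), n_sites, replace = TRUE),
      stringsAsFactors = FALSE
    ),
    attd_subseq = substr(donor, pr_start + 1L, 80L + 50L + 25L),
    core_in_subseq = core_off - pr_start
  )
}
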