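test_that("greedy clustering partitions inputs at the identity threshold", {
  s <- make_genome(100, seed = 1)
  two <- cluster_sequences(c(a = s, b = s), 0.9)
  expect_equal(length(unique(two$cluster)), 1)

  distinct <- c(
    a = make_genome(60, seed = 2), b = make_genome(60, seed = 3),
    c = make_genome(60, seed = 4)
  )
  singletons <- cluster_sequences(distinct, 1.0)
  expect_equal(length(unique(singletons$cluster)), 3)

  # three planted families: within-family identity > 0.8, between < 0.4
  set.seed(5)
  fams <- lapply(1:3, function(i) {
    mutated_family(make_genome(120, seed = 10 * i), 10, 0.1)
  })
  seqs <- setNames(unlist(fams), sprintf("s%02d", 1:30))
  cl <- cluster_sequences(seqs, 0.5)
  expect_equal(length(unique(cl$cluster)), 3)
  # membership agrees with the planted families
  fam_of <- rep(1:3, each = 10)
  names(fam_of) <- names(seqs)
  for (k in unique(cl$cluster)) {
    members <- cl$member_id[cl$cluster == k]
    expect_equal(length(unique(fam_of[members])), 1)
  }
  # partition invariant: every input appears exactly once
  expect_setequal(cl$member_id, names(seqs))
  expect_equal(anyDuplicated(cl$member_id), 0)
  # every member meets the threshold against its representative
  reps <- setNames(cl$representative_id, cl$member_id)
  for (m in cl$member_id) {
    expect_gte(seq_identity(seqs[[m]], seqs[[reps[[m]]]]), 0.5)
  }

  empty <- cluster_sequences(character(0), 0.5)
  expect_equal(nrow(empty), 0)
})

test_that("site-specific classification follows the stated rules", {
  # three LSR clusters sharing one target, each exclusive to it
  edges <- data.frame(
    lsr_cluster = c("L1", "L2", "L3"),
    target_cluster = "T1", stringsAsFactors = FALSE
  )
  expect_setequal(classify_site_specific(edges), c("L1", "L2", "L3"))

  # a target hit by only two LSR clusters is excluded from consideration
  edges2 <- data.frame(
    lsr_cluster = c("L1", "L2"),
    target_cluster = "T1", stringsAsFactors = FALSE
  )
  expect_length(classify_site_specific(edges2), 0)

  # an LSR cluster covering two surviving targets is not site-specific
  edges3 <- data.frame(
    lsr_cluster = c("L1", "L2", "L3", "L4", "L5", "L1", "L1"),
    target_cluster = c("T1", "T1", "T1", "T2", "T2", "T2", "T1"),
    stringsAsFactors = FALSE
  )
  # T1 has 3 LSR clusters, T2 has 3; L1 covers both -> excluded
  expect_false("L1" %in% classify_site_specific(edges3))
})

test_that("multi-targeting bins follow counts with max-bin promotion to 50% clusters", {
  e90 <- data.frame(
    lsr90_cluster = c(rep("A", 4), rep("B", 2), "C"),
    target_cluster = c("t1", "t2", "t3", "t4", "t5", "t6", "t7"),
    stringsAsFactors = FALSE
  )
  map <- data.frame(
    lsr90_cluster = c("A", "B", "C"),
    lsr50_cluster = c("X", "X", "Y"), stringsAsFactors = FALSE
  )
  calls <- classify_multi_targeting(e90, map)
  # C targets one cluster: removed entirely; X promoted to A's ">3"
  expect_equal(nrow(calls), 1)
  expect_identical(calls$lsr50_cluster, "X")
  expect_identical(as.character(calls$bin), ">3")
  expect_identical(calls$label, "multi-targeting")
  expect_equal(calls$n_target_clusters, 4)

  # bins {2} stay unclassified (not fully multi-targeting)
  e2 <- data.frame(
    lsr90_cluster = rep("B", 2), target_cluster = c("t1", "t2"),
    stringsAsFactors = FALSE
  )
  c2 <- classify_multi_targeting(e2, map)
  expect_identical(as.character(c2$bin), "2")
  expect_identical(c2$label, "unclassified")

  expect_error(
    classify_multi_targeting(
      data.frame(lsr90_cluster = "Z", target_cluster = "t1"),
      map
    ),
    "orphan"
  )
})

test_that("classification agrees with brute-force rule application on random graphs", {
  set.seed(23)
  for (trial in 1:40) {
    edges <- random_bipartite(
      n_lsr = sample(3:8, 1), n_target = sample(2:6, 1),
      n_edges = sample(5:25, 1)
    )
    expect_identical(
      sort(classify_site_specific(edges)),
      brute_site_specific(edges)
    )

    e90 <- edges
    names(e90)[1] <- "lsr90_cluster"
    lsr_ids <- unique(e90$lsr90_cluster)
    map <- data.frame(
      lsr90_cluster = lsr_ids,
      lsr50_cluster = paste0("F", sample(1:3, length(lsr_ids), replace = TRUE)),
      stringsAsFactors = FALSE
    )
    got <- classify_multi_targeting(e90, map)
    oracle <- brute_multi_targeting(e90, map)
    expect_identical(setNames(as.character(got$bin), got$lsr50_cluster), oracle)
    # label exclusivity: no cluster is both site-specific and multi-targeting
    ss <- classify_site_specific(edges)
    mt50 <- got$lsr50_cluster[got$label == "multi-targeting"]
    mt_members <- map$lsr90_cluster[map$lsr50_cluster %in% mt50]
    fully_mt <- vapply(mt_members, function(l) {
      length(unique(e90$target_cluster[e90$lsr90_cluster == l])) > 3
    }, logical(1))
    expect_length(intersect(ss, mt_members[fully_mt]), 0)
  }
})

test_that("motif eligibility needs more than ten attBs or target clusters", {
  tab <- function(n_att, n_clust) {
    data.frame(
      candidate_id = "c1",
      attB = paste0("ATT", seq_len(n_att)),
      target_cluster = paste0("T", rep_len(seq_len(n_clust), n_att)),
      stringsAsFactors = FALSE
    )
  }
  expect_equal(nrow(select_motif_eligible(tab(10, 10))), 0)
  expect_gt(nrow(select_motif_eligible(tab(11, 11))), 0)

  # duplicate attBs collapse before counting
  dup <- tab(11, 11)
  dup$attB <- rep("SAME", 11)
  dup$target_cluster <- paste0("T", 1:11) # 11 clusters: still eligible
  expect_equal(nrow(select_motif_eligible(dup)), 11)
  dup$target_cluster <- paste0("T", rep_len(1:5, 11)) # 1 attB, 5 clusters
  expect_equal(nrow(select_motif_eligible(dup)), 0)

  # 12 attBs over 4 target clusters on an eligible candidate: 4 forwarded
  big <- tab(12, 12)
  small <- tab(12, 4)
  small$candidate_id <- "c2"
  both <- rbind(big, small)
  out <- select_motif_eligible(both)
  expect_equal(sum(out$candidate_id == "c1"), 12)
  expect_equal(sum(out$candidate_id == "c2"), 4)
})
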