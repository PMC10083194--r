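# Greedy identity clustering of LSR and target-gene sequences, and
# target-site specificity classification of LSR clusters.

#' Greedy centroid clustering at an identity threshold
#'
#' Sequences are sorted by length descending (ties lexicographic by id) and
#' processed in order: each sequence joins the first existing centroid to
#' which its global-alignment identity meets the threshold, otherwise it
#' founds a new cluster. Deterministic; every member is at least
#' `threshold` identical to its cluster representative, and memberships
#' partition the input.
#'
#' @param seqs Named character vector of sequences (protein or nucleotide).
#' @param threshold Identity threshold in `(0, 1]`.
#' @param identity_fun Pairwise identity function (default [seq_identity()]:
#'   matches / global alignment length).
#' @return Data frame with columns `member_id`, `representative_id`,
#'   `cluster` (integer), with attribute `threshold`.
#' @export
cluster_sequences <- function(seqs, threshold, identity_fun = seq_identity) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(seqs) == 0L) {
    out <- data.frame(
      member_id = character(0), representative_id = character(0),
      cluster = integer(0), stringsAsFactors = FALSE
    )
    attr(out, "threshold") <- threshold
    return(out)
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("seqs must carry unique names")
  }
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character(0)
  assignment <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- 0L
    for (j in seq_along(reps)) {
      if (identity_fun(seqs[[i]], seqs[[reps[j]]]) >= threshold) {
        placed <- j
        break
      }
    }
    if (placed == 0L) {
      reps <- c(reps, names(seqs)[i])
      placed <- length(reps)
    }
    assignment[i] <- placed
  }
  out <- data.frame(
    member_id = names(seqs),
    representative_id = reps[assignment],
    cluster = assignment,
    stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- threshold
  out
}

#' Identify site-specific LSR clusters
#'
#' Operating on deduplicated (LSR 50%-cluster, target-gene 50%-cluster)
#' pairs: target clusters hit by at least three distinct LSR clusters are
#' retained; among the edges restricted to those targets, the LSR clusters
#' whose edge set covers exactly one target cluster are called
#' site-specific.
#'
#' @param lsr_to_target Data frame with columns `lsr_cluster`,
#'   `target_cluster`.
#' @return Character (or integer) vector of site-specific LSR cluster ids.
#' @export
classify_site_specific <- function(lsr_to_target) {
  stopifnot(all(c("lsr_cluster", "target_cluster") %in% names(lsr_to_target)))
  edges <- unique(lsr_to_target[, c("lsr_cluster", "target_cluster")])
  if (nrow(edges) == 0L) {
    return(edges$lsr_cluster)
  }
  per_target <- tapply(edges$lsr_cluster, edges$target_cluster, function(x) length(unique(x)))
  keep_targets <- names(per_target)[per_target >= 3L]
  edges <- edges[as.character(edges$target_cluster) %in% keep_targets, , drop = FALSE]
  if (nrow(edges) == 0L) {
    return(edges$lsr_cluster)
  }
  per_lsr <- tapply(edges$target_cluster, edges$lsr_cluster, function(x) length(unique(x)))
  ids <- names(per_lsr)[per_lsr == 1L]
  if (is.numeric(lsr_to_target$lsr_cluster)) as.numeric(ids) else ids
}

.bin_levels <- c("2", "3", ">3")

#' Classify multi-targeting LSR clusters
#'
#' Counts distinct target-gene clusters per 90%-identity LSR cluster,
#' removes clusters that target a single gene cluster, bins the rest as 2,
#' 3, or >3 targets (">3" is fully multi-targeting), and assigns each
#' 50%-identity LSR cluster the highest bin attained by any of its member
#' 90% clusters.
#'
#' @param lsr90_to_target Data frame with columns `lsr90_cluster`,
#'   `target_cluster` (deduplicated pairs).
#' @param lsr90_to_lsr50 Data frame with columns `lsr90_cluster`,
#'   `lsr50_cluster` mapping every 90% cluster to its 50% cluster.
#' @return Data frame of specificity calls: `lsr50_cluster`,
#'   `n_target_clusters` (maximum over member 90% clusters),
#'   `bin` (factor with levels 2, 3, >3), `label`
#'   ("multi-targeting" iff bin is ">3", else "unclassified").
#' @export
classify_multi_targeting <- function(lsr90_to_target, lsr90_to_lsr50) {
  stopifnot(
    all(c("lsr90_cluster", "target_cluster") %in% names(lsr90_to_target)),
    all(c("lsr90_cluster", "lsr50_cluster") %in% names(lsr90_to_lsr50))
  )
  if (anyDuplicated(lsr90_to_lsr50$lsr90_cluster)) {
    stop("each 90% cluster must map to exactly one 50% cluster")
  }
  edges <- unique(lsr90_to_target[, c("lsr90_cluster", "target_cluster")])
  orphan <- setdiff(edges$lsr90_cluster, lsr90_to_lsr50$lsr90_cluster)
  if (length(orphan) > 0L) {
    stop("orphan 90% cluster(s) with no 50% cluster mapping: ",
      paste(unique(orphan), collapse = ", "))
  }
  counts <- tapply(edges$target_cluster, edges$lsr90_cluster, function(x) length(unique(x)))
  counts <- counts[counts >= 2L] # single-target 90% clusters removed
  if (length(counts) == 0L) {
    return(data.frame(
      lsr50_cluster = character(0), n_target_clusters = integer(0),
      bin = factor(character(0), levels = .bin_levels),
      label = character(0), stringsAsFactors = FALSE
    ))
  }
  map <- stats::setNames(
    as.character(lsr90_to_lsr50$lsr50_cluster),
    as.character(lsr90_to_lsr50$lsr90_cluster)
  )
  df <- data.frame(
    lsr50_cluster = map[names(counts)],
    n_targets = as.integer(counts),
    bin_idx = ifelse(counts > 3L, 3L, counts - 1L), # 2 -> 1, 3 -> 2, >3 -> 3
    stringsAsFactors = FALSE
  )
  agg_n <- tapply(df$n_targets, df$lsr50_cluster, max)
  agg_bin <- tapply(df$bin_idx, df$lsr50_cluster, max)
  out <- data.frame(
    lsr50_cluster = names(agg_n),
    n_target_clusters = as.integer(agg_n),
    bin = factor(.bin_levels[agg_bin], levels = .bin_levels),
    stringsAsFactors = FALSE
  )
  out$label <- ifelse(out$bin == ">3", "multi-targeting", "unclassified")
  rownames(out) <- NULL
  out[order(out$lsr50_cluster), , drop = FALSE]
}

#' Select candidates eligible for motif building
#'
#' A candidate qualifies when it targets more than ten unique attB
#' sequences or more than ten distinct target-gene clusters. For each
#' eligible candidate, one attachment site per target-gene cluster is
#' forwarded (the first observed), avoiding redundancy in downstream
#' motifs.
#'
#' @param attB_table Data frame with columns `candidate_id`, `attB`,
#'   `target_cluster`.
#' @return Data frame of forwarded rows (`candidate_id`, `target_cluster`,
#'   `attB`), one per (candidate, target cluster).
#' @export
select_motif_eligible <- function(attB_table) {
  stopifnot(all(c("candidate_id", "attB", "target_cluster") %in% names(attB_table)))
  if (nrow(attB_table) == 0L) {
    return(attB_table[, c("candidate_id", "target_cluster", "attB")])
  }
  eligible <- vapply(split(attB_table, attB_table$candidate_id), function(d) {
    length(unique(d$attB)) > 10L || length(unique(d$target_cluster)) > 10L
  }, logical(1))
  keep <- attB_table[attB_table$candidate_id %in% names(eligible)[eligible], , drop = FALSE]
  first <- !duplicated(keep[, c("candidate_id", "target_cluster")])
  out <- keep[first, c("candidate_id", "target_cluster", "attB"), drop = FALSE]
  rownames(out) <- NULL
  out
}
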