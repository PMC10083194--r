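# Target-gene feature enrichment (Fisher exact + Benjamini-Hochberg) and
# anti-phage proximity statistics.

#' Feature enrichment of target genes over background genes
#'
#' For every feature annotated on at least `min_target_genes` distinct
#' target genes, a two-sided Fisher's exact test compares its
#' target-vs-background gene counts; p values are FDR-adjusted with
#' Benjamini-Hochberg across tested features. Features below the floor are
#' reported untested with a reason.
#'
#' @param target_features,background_features Either a named list mapping
#'   gene id to a character vector of features (Pfam domains, GO terms,
#'   ...), or a data frame with columns `gene`, `feature`.
#' @param min_target_genes Minimum distinct target genes per tested
#'   feature (default 5).
#' @return Data frame with one row per feature: `feature`, `n_target`,
#'   `n_background`, `target_total`, `background_total`, `odds_ratio`
#'   (sample OR, `Inf` sentinel allowed), `p`, `fdr`, `tested`, `reason`.
#' @export
feature_enrichment <- function(target_features, background_features,
                               min_target_genes = 5L) {
  as_map <- function(x) {
    if (is.data.frame(x)) {
      stopifnot(all(c("gene", "feature") %in% names(x)))
      x <- split(as.character(x$feature), x$gene)
    }
    lapply(x, unique)
  }
  tf <- as_map(target_features)
  bf <- as_map(background_features)
  if (length(bf) == 0L) stop("empty background")
  nt <- length(tf)
  nb <- length(bf)
  feats <- sort(unique(unlist(tf)))
  rows <- lapply(feats, function(f) {
    a <- sum(vapply(tf, function(g) f %in% g, logical(1)))
    c_ <- sum(vapply(bf, function(g) f %in% g, logical(1)))
    tested <- a >= min_target_genes
    p <- NA_real_
    or <- NA_real_
    if (tested) {
      tab <- matrix(c(a, nt - a, c_, nb - c_), nrow = 2)
      p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
      or <- if ((nt - a) * c_ == 0) {
        if (a * (nb - c_) == 0) NaN else Inf
      } else {
        (a * (nb - c_)) / ((nt - a) * c_)
      }
    }
    data.frame(
      feature = f, n_target = a, n_background = c_,
      target_total = nt, background_total = nb,
      odds_ratio = or, p = p,
      tested = tested,
      reason = if (tested) NA_character_ else sprintf("fewer than %d target genes", min_target_genes),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  out$fdr[out$tested] <- stats::p.adjust(out$p[out$tested], method = "BH")
  out[order(out$p, out$feature), c(
    "feature", "n_target", "n_background", "target_total",
    "background_total", "odds_ratio", "p", "fdr", "tested", "reason"
  )]
}

#' Anti-phage proximity rank-sum test
#'
#' Compares the distances from target genes to their nearest anti-phage
#' defense gene against the same distances for background genes, using a
#' Wilcoxon rank-sum test: exact for combined sample sizes up to 25
#' (without ties), normal approximation with continuity correction
#' otherwise. Fully tied degenerate input returns p = 1 with a flag. The
#' statistic depends only on ranks, so it is invariant under monotone
#' transforms of the distances.
#'
#' @param target_distances,background_distances Numeric distance vectors
#'   (nt), each non-empty.
#' @return List with `statistic` (rank-sum W), `p_value`, `method`,
#'   `degenerate` flag.
#' @export
antiphage_proximity_test <- function(target_distances, background_distances) {
  stopifnot(length(target_distances) >= 1L, length(background_distances) >= 1L)
  all_vals <- c(target_distances, background_distances)
  if (length(unique(all_vals)) == 1L) {
    return(list(
      statistic = length(target_distances) * length(background_distances) / 2,
      p_value = 1, method = "degenerate (all values tied)", degenerate = TRUE
    ))
  }
  exact <- length(all_vals) <= 25L
  wt <- suppressWarnings(stats::wilcox.test(
    target_distances, background_distances,
    alternative = "two.sided", exact = exact, correct = TRUE
  ))
  list(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    method = wt$method,
    degenerate = FALSE
  )
}
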