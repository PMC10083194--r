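# Comparative boundary detection: locate insertions in a query genome
# relative to a close reference, and decompose each locus into flanks,
# target-site duplication and element.

#' Find insertions in a query genome relative to a reference
#'
#' Walks both genomes in parallel, anchoring on exact-match seed k-mers.
#' When the query carries an extra segment relative to the reference, the
#' breakpoint is canonicalized leftmost (microhomology permitting) and the
#' inserted segment is decomposed into the target-site duplication `D`
#' (the maximal prefix of the inserted string that matches the reference at
#' the breakpoint) and the element `E`. Multiple insertions are handled by
#' iterative re-anchoring. Identical genomes yield an empty list; a
#' difference that cannot be explained by an insertion (substitution or
#' deletion in the query) stops the scan with a warning.
#'
#' @param reference Pre-integration genome (character scalar).
#' @param query Post-integration genome (character scalar).
#' @param min_flank Minimum exact match required on each side of a
#'   breakpoint when re-anchoring (bp); must be >= `seed_k`.
#' @param max_element_len Elements longer than this are still reported here
#'   (policy filtering belongs to the QC stage); recorded for reference.
#' @param seed_k Anchor seed k-mer length (default 21).
#' @param flank_context Number of flanking bases retained in the reported
#'   `b1_flank`/`b2_flank` and terminal `p1`/`p2` segments.
#' @return A list of `insertion_call` objects sorted by `site_position`,
#'   each with fields `reference_id`, `query_id`, `site_position` (0-based
#'   on the reference), `b1_flank`, `duplication`, `p1_terminal`, `element`,
#'   `p2_terminal`, `b2_flank`, and `element_interval` (0-based half-open on
#'   the query).
#' @examples
#' ref <- make_genome(2000, seed = 4)
#' pl <- plant_integration(ref, make_genome(600, seed = 5), 900, 3)
#' find_insertion(pl$pre_genome, pl$post_genome)
#' @export
find_insertion <- function(reference, query, min_flank = 21L,
                           max_element_len = 200000L, seed_k = 21L,
                           flank_context = 100L) {
  reference <- .as_seq(reference)
  query <- .as_seq(query)
  stopifnot(nchar(reference) > 0L, nchar(query) > 0L)
  if (min_flank < seed_k) stop("min_flank must be at least the seed k-mer length")
  r <- charToRaw(reference)
  q <- charToRaw(query)
  lr <- length(r)
  lq <- length(q)

  calls <- list()
  ri <- 0L
  qi <- 0L
  p_floor <- 0L # calls may not start before this reference offset
  repeat {
    a <- .lcp(r, q, ri, qi)
    ra <- ri + a
    qa <- qi + a
    if (ra == lr && qa == lq) break
    if ((lq - qa) <= (lr - ra)) {
      warning("query/reference difference at reference offset ", ra,
        " is not an insertion; stopping scan",
        call. = FALSE
      )
      break
    }
    if (ra == lr) {
      # insertion past the end of the reference
      hit <- list(p = lr, L = lq - qa)
    } else {
      b <- .lcs(r, q, ri, qi)
      if (b >= lr - ra) {
        # exactly one insertion remains; leftmost valid breakpoint
        L <- (lq - qa) - (lr - ra)
        p <- max(p_floor, lr - b)
        if (p > ra) {
          warning("inconsistent terminal insertion near reference offset ", ra,
            "; stopping scan",
            call. = FALSE
          )
          break
        }
        hit <- list(p = p, L = L)
      } else {
        hit <- .reanchor(r, q, reference, query, ra, qa, seed_k, min_flank, p_floor)
        if (is.null(hit)) {
          warning("could not re-anchor after reference offset ", ra,
            "; stopping scan",
            call. = FALSE
          )
          break
        }
      }
    }
    p <- hit$p
    L <- hit$L
    qp <- p + (qi - ri) # query offset of reference position p
    inserted <- .substr0(query, qp, qp + L)
    d <- .lcp(charToRaw(inserted), r, 0L, p)
    d <- min(d, L - 1L, lr - p)
    call <- .make_insertion_call(
      reference, query, p, d, L, qp,
      flank_context = flank_context
    )
    calls[[length(calls) + 1L]] <- call
    # resume after the insertion: reference p aligns with query qp + L
    ri <- p
    qi <- qp + L
    p_floor <- p + d
  }
  calls
}

# Re-anchor after a mismatch at reference offset ra / query offset qa by
# locating the next exact occurrence of the reference seed in the query.
.reanchor <- function(r, q, reference, query, ra, qa, seed_k, min_flank, p_floor) {
  lr <- length(r)
  lq <- length(q)
  k <- min(seed_k, lr - ra)
  anchor <- .substr0(reference, ra, ra + k)
  m <- gregexpr(anchor, query, fixed = TRUE)[[1]]
  if (m[1] == -1L) {
    return(NULL)
  }
  cand <- as.integer(m) - 1L # 0-based query offsets
  cand <- cand[cand > qa]
  for (j in cand) {
    ext <- min(min_flank, lr - ra, lq - j)
    if (.lcp(r, q, ra, j) >= ext) {
      L <- j - qa
      # leftmost shift through microhomology
      t <- 0L
      max_t <- min(ra - p_floor, qa)
      while (t < max_t && r[ra - t] == q[j - t]) t <- t + 1L
      return(list(p = ra - t, L = L))
    }
  }
  NULL
}

.make_insertion_call <- function(reference, query, p, d, L, qp, flank_context = 100L) {
  lr <- nchar(reference)
  dup <- .substr0(reference, p, p + d)
  element <- .substr0(query, qp + d, qp + L)
  el <- nchar(element)
  term <- min(flank_context, el)
  structure(
    list(
      reference_id = "reference",
      query_id = "query",
      site_position = p,
      b1_flank = .substr0(reference, max(0L, p - flank_context), p),
      duplication = dup,
      p1_terminal = .substr0(element, 0L, term),
      element = element,
      p2_terminal = .substr0(element, el - term, el),
      b2_flank = .substr0(reference, p + d, min(lr, p + d + flank_context)),
      element_interval = c(qp + d, qp + L)
    ),
    class = "insertion_call"
  )
}

#' @export
print.insertion_call <- function(x, ...) {
  cat(
    "Insertion call at reference offset ", x$site_position,
    " (|D| = ", nchar(x$duplication),
    ", |E| = ", nchar(x$element),
    ", query interval [", x$element_interval[1], ", ", x$element_interval[2], "))\n",
    sep = ""
  )
  invisible(x)
}

#' Fragment-level average nucleotide identity
#'
#' Chops `genome_a` into non-overlapping fragments, locates each fragment in
#' `genome_b` by modal exact k-mer seeding, and computes the ungapped
#' identity at the matched offset. ANI is the mean identity over matched
#' fragments, averaged over both directions for symmetry. Returns `NA` (the
#' no-match sentinel) when no fragment can be anchored, as for unrelated
#' genomes.
#'
#' @param genome_a,genome_b Genomes (character scalars), each at least
#'   `fragment_len` long.
#' @param fragment_len Fragment length in bp (default 1000).
#' @param seed_k Seed k-mer length for fragment anchoring.
#' @param stride Spacing between sampled seed k-mers within a fragment.
#' @return Percent identity in `[0, 100]`, or `NA_real_` when no fragment
#'   matches.
#' @export
measure_ani <- function(genome_a, genome_b, fragment_len = 1000L,
                        seed_k = 15L, stride = 7L) {
  genome_a <- .as_seq(genome_a)
  genome_b <- .as_seq(genome_b)
  if (nchar(genome_a) < fragment_len || nchar(genome_b) < fragment_len) {
    stop("both genomes must be at least fragment_len long")
  }
  one_way <- function(a, b) {
    bk <- .kmers(b, seed_k)
    rb <- charToRaw(b)
    n <- nchar(a)
    starts <- seq(0L, n - fragment_len, by = fragment_len)
    ids <- vapply(starts, function(s) {
      frag <- .substr0(a, s, s + fragment_len)
      kpos <- seq(1L, fragment_len - seed_k + 1L, by = stride)
      hits <- match(substring(frag, kpos, kpos + seed_k - 1L), bk)
      ok <- !is.na(hits)
      if (!any(ok)) {
        return(NA_real_)
      }
      offsets <- hits[ok] - kpos[ok] # 0-based offset of fragment start in b
      off <- as.integer(names(sort(table(offsets), decreasing = TRUE))[1])
      lo <- max(0L, off)
      hi <- min(nchar(b), off + fragment_len)
      if (hi - lo < seed_k) {
        return(NA_real_)
      }
      fa <- charToRaw(frag)[(lo - off + 1L):(hi - off)]
      fb <- rb[(lo + 1L):hi]
      mean(fa == fb)
    }, numeric(1))
    if (all(is.na(ids))) NA_real_ else mean(ids, na.rm = TRUE)
  }
  ab <- one_way(genome_a, genome_b)
  ba <- one_way(genome_b, genome_a)
  if (is.na(ab) && is.na(ba)) {
    return(NA_real_)
  }
  100 * mean(c(ab, ba), na.rm = TRUE)
}
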