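# Internal sequence helpers shared across modules.

DNA_BASES4 <- c("A", "C", "G", "T")

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so seeded generators do not perturb the caller's
#' random stream. A `NULL` seed evaluates `code` against the current state.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.as_seq <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
  stopifnot(is.character(x))
  toupper(x)
}

#' Reverse complement of a DNA string
#'
#' @param x A character scalar (or vector) over the DNA alphabet.
#' @return Character of the same length with each element reverse-complemented.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(.as_seq(x))))
}

# Longest common prefix length of a[(ia+1):] and b[(ib+1):] (raw vectors,
# 0-based offsets).
.lcp <- function(a, b, ia = 0L, ib = 0L) {
  n <- min(length(a) - ia, length(b) - ib)
  if (n <= 0L) {
    return(0L)
  }
  mism <- which(a[(ia + 1L):(ia + n)] != b[(ib + 1L):(ib + n)])
  if (length(mism) == 0L) n else mism[1L] - 1L
}

# Longest common suffix length of a[(ia+1):] and b[(ib+1):].
.lcs <- function(a, b, ia = 0L, ib = 0L) {
  n <- min(length(a) - ia, length(b) - ib)
  if (n <= 0L) {
    return(0L)
  }
  la <- length(a)
  lb <- length(b)
  mism <- which(a[(la - n + 1L):la] != b[(lb - n + 1L):lb])
  if (length(mism) == 0L) n else n - max(mism)
}

.substr0 <- function(x, start, end) {
  # 0-based half-open substring
  if (end <= start) {
    return("")
  }
  substr(x, start + 1L, end)
}

# Unit-match substitution matrix over the residues seen in the inputs.
.unit_submat <- function(..., match = 1, mismatch = 0) {
  chars <- unique(unlist(strsplit(toupper(c(...)), "")))
  chars <- sort(unique(c(chars, "A", "C", "G", "T")))
  m <- matrix(mismatch, length(chars), length(chars), dimnames = list(chars, chars))
  diag(m) <- match
  m
}

#' Pairwise global sequence identity
#'
#' Identity is computed as matches divided by alignment length (gap columns
#' included) under a global alignment with unit match score, zero mismatch,
#' and affine gap penalties (open 10, extend 1). This is the identity
#' definition used for greedy clustering and relative selection; the scoring
#' scheme is configurable through the `...` arguments passed to
#' [Biostrings::pairwiseAlignment()].
#'
#' @param a,b Character scalars (nucleotide or amino-acid sequences).
#' @param gap_opening,gap_extension Affine gap penalties.
#' @param ... Further arguments to [Biostrings::pairwiseAlignment()].
#' @return Numeric identity in `[0, 1]`.
#' @export
seq_identity <- function(a, b, gap_opening = 10, gap_extension = 1, ...) {
  a <- .as_seq(a)
  b <- .as_seq(b)
  if (identical(a, b)) {
    return(1)
  }
  if (nchar(a) == 0L || nchar(b) == 0L) {
    return(0)
  }
  aln <- Biostrings::pairwiseAlignment(
    a, b,
    type = "global",
    substitutionMatrix = .unit_submat(a, b),
    gapOpening = gap_opening, gapExtension = gap_extension, ...
  )
  width <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / width
}

# Global-alignment score under a simple nucleotide scheme; used to orient
# attachment sites.
.global_score <- function(a, b, match = 1, mismatch = -1, gap = 2) {
  Biostrings::pairwiseAlignment(
    .as_seq(a), .as_seq(b),
    type = "global",
    substitutionMatrix = .unit_submat(a, b, match = match, mismatch = mismatch),
    gapOpening = 0, gapExtension = gap,
    scoreOnly = TRUE
  )
}

.kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) {
    return(character(0))
  }
  substring(x, 1:(n - k + 1L), k:n)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path Input path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write reads with qualities to a FASTQ file (Phred+33)
#'
#' @param seqs Named character vector of read sequences.
#' @param quals Character vector of quality strings, same lengths as `seqs`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, quals, path) {
  stopifnot(length(seqs) == length(quals), all(nchar(seqs) == nchar(quals)))
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  x <- Biostrings::QualityScaledDNAStringSet(
    stats::setNames(Biostrings::DNAStringSet(unname(seqs)), ids),
    Biostrings::PhredQuality(quals)
  )
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path Input path.
#' @return List with `seq` (named character) and `qual` (character).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  list(
    seq = stats::setNames(as.character(x), names(x)),
    qual = as.character(S4Vectors::mcols(x)$qualities)
  )
}
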