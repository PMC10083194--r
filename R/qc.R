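# Candidate quality-control filters and MGE-category plurality voting.

#' Default QC thresholds
#'
#' Thresholds follow the published candidate-selection criteria: "more than
#' X"-removed rules are strict (exactly X passes) and "between A and B" is
#' inclusive.
#'
#' @param min_ani Minimum genome-pair ANI percent (>= passes).
#' @param max_center_len Maximum attachment-site center length in bp
#'   (centers above this are removed).
#' @param max_ambiguous_nt Maximum fraction of ambiguous nucleotides in the
#'   attachment sites.
#' @param min_protein_len,max_protein_len Inclusive LSR length bounds (aa).
#' @param required_domains Pfam domains of which at least one must be
#'   present.
#' @param max_ambiguous_aa Maximum fraction of ambiguous amino acids.
#' @param max_element_len Elements must be strictly shorter than this (bp).
#' @param max_distance Maximum LSR distance to its attachment site (nt).
#' @return A named list of thresholds.
#' @export
qc_config <- function(min_ani = 95,
                      max_center_len = 20L,
                      max_ambiguous_nt = 0.05,
                      min_protein_len = 400L,
                      max_protein_len = 650L,
                      required_domains = c("Resolvase", "Recombinase", "Zn_ribbon_recom"),
                      max_ambiguous_aa = 0.05,
                      max_element_len = 200000L,
                      max_distance = 500L) {
  list(
    min_ani = min_ani, max_center_len = max_center_len,
    max_ambiguous_nt = max_ambiguous_nt,
    min_protein_len = min_protein_len, max_protein_len = max_protein_len,
    required_domains = required_domains,
    max_ambiguous_aa = max_ambiguous_aa,
    max_element_len = max_element_len, max_distance = max_distance
  )
}

#' Construct an LSR candidate record
#'
#' @param lsr_id Identifier.
#' @param protein_seq Amino-acid sequence (may be `NA` if `protein_len`
#'   given).
#' @param pfam_domains Character vector of Pfam domain names.
#' @param distance_to_site Distance from the LSR gene to its attachment
#'   site (nt).
#' @param element_length Element length (bp).
#' @param ani_percent ANI of the genome comparison that yielded the call.
#' @param att_pair Optional `att_pair` (supplies the center length).
#' @param center_length Center length in bp (overrides `att_pair`).
#' @param ambiguous_nt_fraction,ambiguous_aa_fraction Ambiguity fractions.
#' @return A list of class `lsr_candidate`.
#' @export
lsr_candidate <- function(lsr_id, protein_seq = NA_character_,
                          pfam_domains = character(0),
                          distance_to_site = NA_integer_,
                          element_length = NA_integer_,
                          ani_percent = NA_real_,
                          att_pair = NULL,
                          center_length = NULL,
                          ambiguous_nt_fraction = NA_real_,
                          ambiguous_aa_fraction = NA_real_) {
  if (is.null(center_length)) {
    center_length <- if (!is.null(att_pair)) nchar(att_pair$center) else NA_integer_
  }
  structure(
    list(
      lsr_id = lsr_id, protein_seq = protein_seq,
      pfam_domains = pfam_domains,
      distance_to_site = distance_to_site,
      element_length = element_length,
      ani_percent = ani_percent,
      center_length = center_length,
      ambiguous_nt_fraction = ambiguous_nt_fraction,
      ambiguous_aa_fraction = ambiguous_aa_fraction
    ),
    class = "lsr_candidate"
  )
}

#' Apply the candidate quality-control filters
#'
#' Eight filters: genome-pair ANI >= 95%; attachment-site center <= 20 bp;
#' attachment-site ambiguous nucleotides <= 5%; LSR length 400-650 aa
#' (inclusive); at least one of the Resolvase / Recombinase /
#' Zn_ribbon_recom domains; ambiguous amino acids <= 5%; element < 200 kb;
#' LSR within 500 nt of its attachment site. A candidate passes overall iff
#' every filter passes; a missing field marks that filter indeterminate
#' (`NA`) and fails the candidate.
#'
#' @param candidate An [lsr_candidate()] (or a compatible named list).
#' @param config Thresholds from [qc_config()].
#' @return A `qc_report`: data frame with columns `filter`, `value`,
#'   `threshold`, `pass`, plus attribute `overall`.
#' @export
apply_filters <- function(candidate, config = qc_config()) {
  val <- function(x) if (is.null(x) || length(x) == 0L) NA else x
  protein_len <- if (!is.null(candidate$protein_len)) {
    candidate$protein_len
  } else if (!is.null(candidate$protein_seq) && !is.na(candidate$protein_seq)) {
    nchar(candidate$protein_seq)
  } else {
    NA_integer_
  }
  domains <- candidate$pfam_domains
  has_domain <- if (is.null(domains)) NA else length(intersect(domains, config$required_domains)) > 0L

  rows <- list(
    list("ani", val(candidate$ani_percent), sprintf(">= %s", config$min_ani),
      val(candidate$ani_percent) >= config$min_ani),
    list("center_length", val(candidate$center_length), sprintf("<= %s bp", config$max_center_len),
      val(candidate$center_length) <= config$max_center_len),
    list("ambiguous_nt", val(candidate$ambiguous_nt_fraction), sprintf("<= %s", config$max_ambiguous_nt),
      val(candidate$ambiguous_nt_fraction) <= config$max_ambiguous_nt),
    list("protein_length", protein_len,
      sprintf("[%s, %s] aa", config$min_protein_len, config$max_protein_len),
      protein_len >= config$min_protein_len & protein_len <= config$max_protein_len),
    list("pfam_domain", if (is.null(domains)) NA_real_ else length(domains),
      paste(config$required_domains, collapse = "|"), has_domain),
    list("ambiguous_aa", val(candidate$ambiguous_aa_fraction), sprintf("<= %s", config$max_ambiguous_aa),
      val(candidate$ambiguous_aa_fraction) <= config$max_ambiguous_aa),
    list("element_length", val(candidate$element_length), sprintf("< %s bp", config$max_element_len),
      val(candidate$element_length) < config$max_element_len),
    list("distance_to_site", val(candidate$distance_to_site), sprintf("<= %s nt", config$max_distance),
      val(candidate$distance_to_site) <= config$max_distance)
  )
  report <- data.frame(
    filter = vapply(rows, function(r) r[[1]], character(1)),
    value = vapply(rows, function(r) as.numeric(r[[2]]), numeric(1)),
    threshold = vapply(rows, function(r) r[[3]], character(1)),
    pass = vapply(rows, function(r) as.logical(r[[4]]), logical(1)),
    stringsAsFactors = FALSE
  )
  overall <- all(report$pass) # NA-propagating: indeterminate => not TRUE
  attr(report, "overall") <- isTRUE(overall)
  class(report) <- c("qc_report", class(report))
  report
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (overall ", if (attr(x, "overall")) "PASS" else "FAIL", ")\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

MGE_CATEGORIES <- c("dsDNA Phage", "ICE/IME", "Plasmid", "Other replicon")

#' Assign an MGE category by plurality vote
#'
#' Plurality winner over the annotation multiset, with ties resolved in the
#' priority order dsDNA Phage, ICE/IME, Plasmid, Other replicon. An empty
#' annotation set yields "Other".
#'
#' @param annotations Character vector of annotations, each one of
#'   "dsDNA Phage", "ICE/IME", "Plasmid", "Other replicon".
#' @return A single category string.
#' @export
vote_mge_category <- function(annotations) {
  if (length(annotations) == 0L) {
    return("Other")
  }
  bad <- setdiff(annotations, MGE_CATEGORIES)
  if (length(bad) > 0L) {
    stop("unknown MGE annotation label(s): ", paste(unique(bad), collapse = ", "))
  }
  counts <- table(factor(annotations, levels = MGE_CATEGORIES))
  MGE_CATEGORIES[which.max(counts)] # which.max takes the first maximum: priority order
}
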