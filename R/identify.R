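#' Domain architecture of a protein
#'
#' The architecture is the ordered tuple of domain accessions along the
#' protein: hits of the same accession that overlap or are adjacent are merged
#' first, merged intervals are ordered by start (ties by end, then accession),
#' and consecutive repeats of the same accession collapse to one. Overlapping
#' hits of different accessions are both kept.
#'
#' @param hits domain-hit tibble for one protein (`accession`, `start`,
#'   `end`).
#' @param protein_length optional length used to validate hit coordinates.
#' @return character vector of accessions (possibly empty).
#' @export
architecture_of <- function(hits, protein_length = NULL) {
  if (is.null(hits) || nrow(hits) == 0L) return(character(0))
  check_columns(hits, c("accession", "start", "end"), "hits")
  if (any(hits$start < 1L) || any(hits$end < hits$start)) {
    stopf("invalid domain hit coordinates (need 1 <= start <= end)")
  }
  if (!is.null(protein_length) && any(hits$end > protein_length)) {
    stopf("domain hit exceeds protein length (%d)", protein_length)
  }
  merged <- hits |>
    group_by(.data$accession) |>
    dplyr::group_modify(function(g, key) {
      g <- arrange(g, .data$start, .data$end)
      r <- IRanges::reduce(IRanges::IRanges(g$start, g$end), min.gapwidth = 1L)
      tibble(start = IRanges::start(r), end = IRanges::end(r))
    }) |>
    ungroup() |>
    arrange(.data$start, .data$end, .data$accession)
  acc <- merged$accession
  acc[c(TRUE, acc[-1] != acc[-length(acc)])]
}

#' Canonical string key of an architecture
#'
#' @param architecture character vector of accessions.
#' @return a single string (empty for an empty architecture).
#' @export
architecture_key <- function(architecture) {
  paste(architecture, collapse = "|")
}

#' Compare a candidate architecture with a subtype architecture
#'
#' Exact ordered-tuple equality; domain order is functionally meaningful, so
#' `(A,B)` does not match `(B,A)`.
#'
#' @param candidate character vector (candidate architecture).
#' @param subtype character vector (subtype architecture, non-empty).
#' @return `TRUE` or `FALSE`.
#' @export
match_architecture <- function(candidate, subtype) {
  if (length(subtype) == 0L) stopf("subtype architecture must be non-empty")
  length(candidate) == length(subtype) && all(candidate == subtype)
}

#' Candidate length filter
#'
#' Keeps candidates whose protein length lies within 90%-110% of the
#' reference length, boundaries inclusive; candidates outside that window
#' are filtered out.
#'
#' @param candidate_len,reference_len positive lengths (vectorized).
#' @return logical vector.
#' @export
length_filter <- function(candidate_len, reference_len) {
  if (any(candidate_len <= 0) || any(reference_len <= 0)) {
    stopf("lengths must be positive")
  }
  candidate_len >= 0.9 * reference_len & candidate_len <= 1.1 * reference_len
}

#' Identify family members by domain architecture
#'
#' Every protein whose architecture equals a matchable subtype architecture
#' yields a candidate match. The best reference within the subtype is the
#' member with the highest similarity score to the candidate when a
#' similarity table is provided, otherwise the member of nearest length; ties
#' break by smaller `|length_ratio - 1|`, then lexicographic symbol. The
#' length filter is evaluated against that reference. Candidates failing the
#' filter are returned with `passed_length_filter = FALSE`; the identified
#' set is the subset with `passed_length_filter = TRUE`.
#'
#' @param subtypes subtype tibble from [build_subtypes()].
#' @param proteome protein tibble (`id`, `species`, `sequence`, `length`).
#' @param hits domain-hit tibble for the proteome.
#' @param similarity optional similarity tibble whose `query_id` are proteome
#'   ids and whose `subject_id` are reference protein ids.
#' @param length_window half-width of the length-retention window (0.1
#'   keeps candidates within 90%-110% of the reference, the published
#'   criterion).
#' @return tibble of candidate matches: `protein_id`, `species`,
#'   `subtype_id`, `reference_symbol`, `length_ratio`, `domain_coverage`,
#'   `coverage_class`, `passed_length_filter`.
#' @export
identify_family_members <- function(subtypes, proteome, hits,
                                    similarity = NULL, length_window = 0.1) {
  check_columns(subtypes, c("subtype_id", "architecture_key", "members"),
                "subtypes")
  check_columns(proteome, c("id", "length"), "proteome")
  subtypes <- subtypes[subtypes$matchable %||% TRUE, , drop = FALSE]
  if (!"species" %in% names(proteome)) proteome$species <- NA_character_

  hit_split <- if (nrow(hits) > 0L) split(hits, hits$protein_id) else list()
  prot_arch <- vapply(seq_len(nrow(proteome)), function(i) {
    h <- hit_split[[proteome$id[i]]]
    if (is.null(h)) return("")
    architecture_key(architecture_of(h, protein_length = proteome$length[i]))
  }, character(1))

  m <- match(prot_arch, subtypes$architecture_key)
  cand_idx <- which(!is.na(m) & prot_arch != "")
  if (length(cand_idx) == 0L) {
    return(tibble(protein_id = character(), species = character(),
                  subtype_id = character(), reference_symbol = character(),
                  length_ratio = double(), domain_coverage = double(),
                  coverage_class = character(),
                  passed_length_filter = logical()))
  }

  sim_lookup <- NULL
  if (!is.null(similarity) && nrow(similarity) > 0L) {
    sim_lookup <- similarity |>
      group_by(.data$query_id, .data$subject_id) |>
      summarise(score = max(.data$bitscore), .groups = "drop")
  }

  rows <- lapply(cand_idx, function(i) {
    st <- subtypes[m[i], ]
    members <- st$members[[1]]
    clen <- proteome$length[i]
    ratio <- clen / members$length
    score <- rep(NA_real_, nrow(members))
    if (!is.null(sim_lookup)) {
      sl <- sim_lookup[sim_lookup$query_id == proteome$id[i], ]
      score <- sl$score[match(members$protein_id, sl$subject_id)]
    }
    ord <- order(-ifelse(is.na(score), -Inf, score), abs(ratio - 1),
                 members$symbol)
    best <- ord[1]
    h <- hit_split[[proteome$id[i]]]
    cov <- interval_union_width(h$start, h$end, 1L, clen) / clen
    arch_n <- length(st$architecture[[1]])
    tibble(protein_id = proteome$id[i], species = proteome$species[i],
           subtype_id = st$subtype_id,
           reference_symbol = members$symbol[best],
           length_ratio = clen / members$length[best],
           domain_coverage = cov,
           coverage_class = if (arch_n >= 2L) "multi_domain"
             else if (cov >= 0.5) "single_high" else "single_low",
           passed_length_filter =
             clen >= (1 - length_window) * members$length[best] &
             clen <= (1 + length_window) * members$length[best])
  })
  arrange(bind_rows(rows), .data$species, .data$protein_id)
}

#' Write candidate matches as a per-species TSV
#'
#' @param candidates tibble from [identify_family_members()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(candidates, path) {
  readr::write_tsv(candidates, path, progress = FALSE)
  invisible(path)
}
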