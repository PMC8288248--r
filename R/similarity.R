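#' Pairwise alignment scoring scheme
#'
#' Bundles the substitution matrix and affine gap penalties used throughout
#' the package. Defaults follow the classical protein-alignment setup:
#' BLOSUM62, opening gap penalty 10, extending gap penalty 0.05, end gap
#' penalty 10. A gap of length L costs `gap_open + L * gap_extend`; in global
#' mode end gaps are charged like internal gaps, which requires
#' `end_gap == gap_open`.
#'
#' @param matrix substitution matrix name (`"BLOSUM62"`, `"BLOSUM45"`,
#'   `"BLOSUM50"`, `"BLOSUM80"`, `"BLOSUM100"`, `"PAM30"`, `"PAM40"`,
#'   `"PAM70"`, `"PAM120"`, `"PAM250"`) or a symmetric numeric matrix.
#' @param gap_open gap opening penalty (>= 0).
#' @param gap_extend gap extension penalty per gap position (>= 0).
#' @param end_gap end gap opening penalty (global mode); must equal
#'   `gap_open` in this implementation.
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 10,
                           gap_extend = 0.05, end_gap = gap_open) {
  if (is.character(matrix)) {
    name <- matrix
    matrix <- substitution_matrix(name)
  } else {
    name <- "custom"
    if (!is.matrix(matrix) || !isTRUE(all.equal(matrix, t(matrix)))) {
      stopf("substitution matrix must be symmetric")
    }
  }
  if (gap_open < 0 || gap_extend < 0 || end_gap < 0) {
    stopf("gap penalties must be >= 0")
  }
  if (end_gap != gap_open) {
    stopf("end_gap must equal gap_open (end gaps are charged like internal gaps)")
  }
  structure(list(matrix_name = name, matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, end_gap = end_gap),
            class = "scoring_scheme")
}

substitution_matrix <- function(name) {
  key <- paste0("submat_", name)
  if (is.null(the[[key]])) {
    e <- new.env()
    ok <- tryCatch({
      utils::data(list = name, package = "Biostrings", envir = e)
      TRUE
    }, warning = function(w) FALSE, error = function(e) FALSE)
    if (!ok || is.null(e[[name]])) stopf("unknown substitution matrix: %s", name)
    the[[key]] <- e[[name]]
  }
  the[[key]]
}

#' BLAST-like search scoring scheme
#'
#' The scheme used by the similarity-search stand-ins ([all_vs_all()],
#' internal [conserved_pairs()] alignments): BLOSUM62 with gap opening 11
#' and extension 1, the standard protein-search gapping. This differs from
#' the [scoring_scheme()] default (opening 10, extension 0.05), which is
#' the classical multiple-alignment parameter set: near-free gap extension
#' is appropriate for aligning homologs in an MSA but degenerate for
#' database-style searching, where it lets unrelated sequences splice
#' high-scoring fragments together. The Karlin-Altschul bitscore
#' conversion used for hit significance is calibrated for this scheme.
#'
#' @return a [scoring_scheme()].
#' @export
search_scheme <- function() {
  scoring_scheme(gap_open = 11, gap_extend = 1)
}

# BLAST-style bitscore from a raw gapped local-alignment score, using the
# standard gapped BLOSUM62 Karlin-Altschul constants (lambda = 0.267,
# K = 0.041). bits = (lambda * S - ln K) / ln 2. A bitscore of ~50
# approximates the customary E < 1e-5 significance cut for proteome-scale
# searches without requiring database-size-dependent E-value computation.
raw_to_bitscore <- function(score, lambda = 0.267, K = 0.041) {
  (lambda * score - log(K)) / log(2)
}

check_sequences <- function(...) {
  for (s in list(...)) {
    if (!is.character(s) || length(s) != 1L || is.na(s) || nchar(s) == 0L) {
      stopf("sequences must be non-empty character scalars")
    }
  }
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch alignment with affine gaps (end gaps penalized).
#' Identity is the percentage of matching residues among alignment columns
#' holding a residue in both rows; coverage is the percentage of each
#' sequence spanned by its aligned region (always 100 in global mode).
#'
#' @param a,b amino-acid sequences (non-empty strings).
#' @param scheme a [scoring_scheme()].
#' @return one-row tibble with `aligned_a`, `aligned_b`, `score`, `identity`,
#'   `query_cov`, `subject_cov`.
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  align_pair(a, b, scheme, type = "global")
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman alignment with affine gaps; the score is never negative
#' (an empty alignment scores 0).
#'
#' @inheritParams global_align
#' @return one-row tibble as in [global_align()].
#' @export
local_align <- function(a, b, scheme = scoring_scheme()) {
  align_pair(a, b, scheme, type = "local")
}

align_pair <- function(a, b, scheme, type) {
  check_sequences(a, b)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    type = type)
  sc <- Biostrings::score(pa)
  aligned_a <- as.character(Biostrings::alignedPattern(pa))
  aligned_b <- as.character(Biostrings::alignedSubject(pa))
  if (type == "local" && sc < 0) {
    sc <- 0
    aligned_a <- ""
    aligned_b <- ""
  }
  nm <- Biostrings::nmatch(pa)
  nmm <- Biostrings::nmismatch(pa)
  identity <- if (nm + nmm == 0) 0 else nm / (nm + nmm) * 100
  span_a <- nchar(gsub("-", "", aligned_a, fixed = TRUE))
  span_b <- nchar(gsub("-", "", aligned_b, fixed = TRUE))
  tibble(aligned_a = unname(aligned_a), aligned_b = unname(aligned_b),
         score = sc, identity = identity,
         query_cov = span_a / nchar(a) * 100,
         subject_cov = span_b / nchar(b) * 100)
}

#' All-vs-all protein similarity search
#'
#' Computes local alignments between candidate protein pairs and reports, for
#' each query, its best `max_targets` non-self subjects by alignment score.
#' The engine produces no database E-values; raw alignment scores are
#' converted to BLAST-style bitscores (standard gapped BLOSUM62
#' Karlin-Altschul constants) and hits are retained when the bitscore
#' reaches `min_score` — bitscore 50 approximates the customary E < 1e-5
#' cut. An exact shared-k-mer screen restricts dynamic programming
#' to pairs sharing at least `min_shared_kmers` length-`kmer_size` words;
#' unrelated sequences essentially never share such words, while any pair
#' able to reach `min_score` does.
#'
#' @param proteins tibble with columns `id`, `sequence` (and optionally
#'   `species`).
#' @param scheme a [scoring_scheme()]; defaults to the BLAST-like
#'   [search_scheme()].
#' @param max_targets hits retained per query (>= 1).
#' @param min_score minimum bitscore for a reportable hit.
#' @param kmer_size word size of the candidate-pair screen.
#' @param min_shared_kmers minimum shared words for a pair to be aligned;
#'   set to 0 to disable the screen (all pairs aligned).
#' @return a similarity tibble (same shape as [read_similarity_table()],
#'   `evalue` is `NA`).
#' @export
all_vs_all <- function(proteins, scheme = search_scheme(), max_targets = 2,
                       min_score = 50, kmer_size = 5, min_shared_kmers = 3) {
  check_columns(proteins, c("id", "sequence"), "proteins")
  if (max_targets < 1) stopf("max_targets must be >= 1")
  if (anyDuplicated(proteins$id)) stopf("protein ids must be unique")
  n <- nrow(proteins)
  if (n < 2L) return(empty_similarity_tbl())

  pairs <- candidate_pairs(proteins$sequence, kmer_size, min_shared_kmers)
  if (nrow(pairs) == 0L) return(empty_similarity_tbl())

  seq_a <- proteins$sequence[pairs$i]
  seq_b <- proteins$sequence[pairs$j]
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(seq_a), Biostrings::AAStringSet(seq_b),
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    type = "local")
  sc <- Biostrings::score(pa)
  nm <- Biostrings::nmatch(pa)
  nmm <- Biostrings::nmismatch(pa)
  identity <- ifelse(nm + nmm == 0, 0, nm / (nm + nmm) * 100)
  aligned_a <- as.character(Biostrings::alignedPattern(pa))
  aligned_b <- as.character(Biostrings::alignedSubject(pa))
  span_a <- nchar(gsub("-", "", aligned_a, fixed = TRUE))
  span_b <- nchar(gsub("-", "", aligned_b, fixed = TRUE))
  align_length <- nchar(aligned_a)  # alignment columns

  half <- tibble(
    qi = pairs$i, si = pairs$j, identity = identity,
    align_length = as.integer(align_length),
    score = raw_to_bitscore(sc), query_cov = span_a / nchar(seq_a) * 100,
    subject_cov = span_b / nchar(seq_b) * 100)
  both <- bind_rows(
    half,
    tibble(qi = half$si, si = half$qi, identity = half$identity,
           align_length = half$align_length, score = half$score,
           query_cov = half$subject_cov, subject_cov = half$query_cov))
  both <- both[both$score >= min_score, , drop = FALSE]
  if (nrow(both) == 0L) return(empty_similarity_tbl())
  both$query_id <- proteins$id[both$qi]
  both$subject_id <- proteins$id[both$si]
  kept <- both |>
    group_by(.data$query_id) |>
    arrange(desc(.data$score), .data$subject_id, .by_group = TRUE) |>
    slice_head(n = max_targets) |>
    ungroup()
  tibble(query_id = kept$query_id, subject_id = kept$subject_id,
         identity = kept$identity, align_length = kept$align_length,
         mismatches = NA_integer_, gap_opens = NA_integer_,
         qstart = NA_integer_, qend = NA_integer_,
         sstart = NA_integer_, send = NA_integer_,
         evalue = NA_real_, bitscore = kept$score,
         query_cov = kept$query_cov, subject_cov = kept$subject_cov)
}

# Unordered candidate pairs (i < j) sharing at least min_shared k-mers.
candidate_pairs <- function(seqs, k, min_shared) {
  n <- length(seqs)
  if (min_shared <= 0 || any(nchar(seqs) < k)) {
    idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    return(tibble(i = idx[, "row"], j = idx[, "col"]))
  }
  kmers <- lapply(seqs, function(s) {
    unique(substring(s, seq_len(nchar(s) - k + 1L),
                     seq_len(nchar(s) - k + 1L) + k - 1L))
  })
  df <- tibble(protein = rep.int(seq_len(n), lengths(kmers)),
               kmer = unlist(kmers, use.names = FALSE))
  hits <- inner_join(df, df, by = "kmer", relationship = "many-to-many")
  hits <- hits[hits$protein.x < hits$protein.y, c("protein.x", "protein.y")]
  if (nrow(hits) == 0L) return(tibble(i = integer(), j = integer()))
  counts <- dplyr::count(hits, .data$protein.x, .data$protein.y)
  counts <- counts[counts$n >= min_shared, , drop = FALSE]
  tibble(i = counts$protein.x, j = counts$protein.y)
}
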