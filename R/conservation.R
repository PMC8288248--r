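#' Construct a multiple alignment object
#'
#' @param ids member ids (unique, same length as `rows`).
#' @param rows equal-length gapped sequences (gap character `-`).
#' @return an object of class `multiple_alignment`.
#' @export
multiple_alignment <- function(ids, rows) {
  rows <- unname(rows)
  if (length(ids) != length(rows)) stopf("ids and rows differ in length")
  if (anyDuplicated(ids)) stopf("member ids must be unique")
  if (length(unique(nchar(rows))) > 1L) {
    stopf("all alignment rows must have the same length")
  }
  structure(list(member_ids = as.character(ids), rows = rows,
                 column_count = if (length(rows)) nchar(rows[1]) else 0L),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("<multiple_alignment: %d sequences x %d columns>\n",
              length(x$member_ids), x$column_count))
  invisible(x)
}

#' Read an aligned FASTA file as a multiple alignment
#'
#' Accepts alignments produced by any aligner, as long as rows share one
#' length.
#'
#' @param path path to aligned FASTA.
#' @return a `multiple_alignment`.
#' @export
read_alignment_fasta <- function(path) {
  rec <- read_protein_fasta(path)
  multiple_alignment(rec$id, rec$sequence)
}

#' Write a multiple alignment as aligned FASTA
#'
#' @param msa a `multiple_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(msa, path) {
  write_fasta(tibble(id = msa$member_ids, sequence = msa$rows), path)
}

#' Progressive multiple sequence alignment
#'
#' Builds a guide tree by nearest-pair agglomeration (average linkage) of
#' pairwise global-alignment distances (1 - identity), then merges profiles
#' by global profile-profile alignment with the scheme's substitution matrix
#' and affine gap penalties. The procedure is deterministic and invariant to
#' the order of the input sequences: members are processed (and returned) in
#' lexicographic id order and distance ties are broken by smallest member id.
#'
#' @param seqs named character vector of sequences, or a tibble with `id` and
#'   `sequence` columns; at least two sequences.
#' @param scheme a [scoring_scheme()].
#' @return a `multiple_alignment`.
#' @export
progressive_msa <- function(seqs, scheme = scoring_scheme()) {
  if (is.data.frame(seqs)) {
    check_columns(seqs, c("id", "sequence"), "seqs")
    ids <- seqs$id
    seqs <- setNames(seqs$sequence, ids)
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stopf("sequences must be named")
  }
  if (length(seqs) < 2L) stopf("progressive_msa needs at least 2 sequences")
  if (anyDuplicated(names(seqs))) stopf("sequence ids must be unique")
  ord <- order(names(seqs))
  seqs <- seqs[ord]
  n <- length(seqs)

  # pairwise identity distances
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(unname(seqs[idx[, "row"]])),
    Biostrings::AAStringSet(unname(seqs[idx[, "col"]])),
    substitutionMatrix = scheme$matrix, gapOpening = scheme$gap_open,
    gapExtension = scheme$gap_extend, type = "global")
  nm <- Biostrings::nmatch(pa)
  nmm <- Biostrings::nmismatch(pa)
  ident <- ifelse(nm + nmm == 0, 0, nm / (nm + nmm))
  D <- matrix(0, n, n)
  D[cbind(idx[, "row"], idx[, "col"])] <- 1 - ident
  D <- D + t(D)

  # clusters: list of (member indices, alignment matrix rows x cols)
  code <- residue_codes(rownames(scheme$matrix))
  clusters <- lapply(seq_len(n), function(i) {
    list(members = i,
         mat = matrix(code[strsplit(seqs[[i]], "")[[1]]], nrow = 1L))
  })
  keys <- names(seqs)
  cluster_key <- keys

  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- NULL
    best_d <- Inf
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        d <- mean(D[clusters[[a]]$members, clusters[[b]]$members])
        pair_key <- sort(c(cluster_key[a], cluster_key[b]))
        if (d < best_d - 1e-12 ||
            (abs(d - best_d) <= 1e-12 && !is.null(best) &&
             (pair_key[1] < best$key[1] ||
              (pair_key[1] == best$key[1] && pair_key[2] < best$key[2])))) {
          best_d <- d
          best <- list(a = a, b = b, key = pair_key)
        }
      }
    }
    merged <- merge_profiles(clusters[[best$a]]$mat, clusters[[best$b]]$mat,
                             scheme)
    new_cluster <- list(
      members = c(clusters[[best$a]]$members, clusters[[best$b]]$members),
      mat = merged)
    new_key <- min(cluster_key[best$a], cluster_key[best$b])
    keep <- setdiff(seq_len(k), c(best$a, best$b))
    clusters <- c(clusters[keep], list(new_cluster))
    cluster_key <- c(cluster_key[keep], new_key)
  }

  final <- clusters[[1]]
  row_order <- order(final$members)
  mat <- final$mat[row_order, , drop = FALSE]
  letters_tab <- c("-", rownames(scheme$matrix))
  rows <- apply(mat, 1L, function(r) paste(letters_tab[r + 1L], collapse = ""))
  multiple_alignment(names(seqs), rows)
}

residue_codes <- function(alphabet) {
  setNames(seq_along(alphabet), alphabet)
}

merge_profiles <- function(mat_a, mat_b, scheme) {
  res <- .profile_align_cpp(mat_a, mat_b, scheme$matrix,
                            scheme$gap_open, scheme$gap_extend)
  ncols <- length(res$a)
  out <- matrix(0L, nrow = nrow(mat_a) + nrow(mat_b), ncol = ncols)
  a_cols <- res$a
  b_cols <- res$b
  out[seq_len(nrow(mat_a)), a_cols > 0L] <- mat_a[, a_cols[a_cols > 0L],
                                                  drop = FALSE]
  out[nrow(mat_a) + seq_len(nrow(mat_b)), b_cols > 0L] <-
    mat_b[, b_cols[b_cols > 0L], drop = FALSE]
  out
}

#' Conservation profile of a family alignment
#'
#' The column score is the frequency of the modal (most common) residue among
#' the column's non-gap symbols, divided by the total number of rows, so gaps
#' count against conservation. The family score is the mean column score (as
#' a percentage); each member's score is the percentage of its non-gap
#' columns where it carries the modal residue. Modal ties resolve to the
#' alphabetically smallest residue.
#'
#' @param msa a `multiple_alignment` with at least `min_members` rows.
#' @param min_members minimum number of copies required (families with fewer
#'   copies are not scored).
#' @return an object of class `conservation_profile` with elements
#'   `column_scores`, `family_score`, `per_gene_scores`, `n_members`.
#' @export
conservation_profile <- function(msa, min_members = 3) {
  if (!inherits(msa, "multiple_alignment")) stopf("msa must be a multiple_alignment")
  n <- length(msa$member_ids)
  if (n < min_members) {
    stopf("conservation_profile requires at least %d members (got %d)",
          min_members, n)
  }
  mat <- do.call(rbind, strsplit(msa$rows, ""))
  ncols <- ncol(mat)
  modal <- character(ncols)
  column_scores <- numeric(ncols)
  for (j in seq_len(ncols)) {
    col <- mat[, j]
    res <- col[col != "-"]
    if (length(res) == 0L) {
      modal[j] <- NA_character_
      column_scores[j] <- 0
    } else {
      tab <- table(res)
      best <- sort(names(tab)[tab == max(tab)])[1]
      modal[j] <- best
      column_scores[j] <- tab[[best]] / n
    }
  }
  per_gene <- vapply(seq_len(n), function(i) {
    non_gap <- mat[i, ] != "-"
    if (!any(non_gap)) return(0)
    mean(mat[i, non_gap] == modal[non_gap], na.rm = TRUE) * 100
  }, numeric(1))
  structure(list(column_scores = column_scores,
                 family_score = mean(column_scores) * 100,
                 per_gene_scores = setNames(per_gene, msa$member_ids),
                 n_members = n),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile: %d members, %d columns, family score %.2f%%>\n",
              x$n_members, length(x$column_scores), x$family_score))
  invisible(x)
}

#' Length-variation profile of a family
#'
#' For each window half-width `w`, the retained fraction is the share of
#' member lengths inside `[(1 - w) * ref, (1 + w) * ref]` (inclusive). The
#' retained fraction is non-decreasing in `w`.
#'
#' @param family_lengths member protein lengths.
#' @param reference_len reference (template) protein length (> 0).
#' @param cutoffs ordered window half-widths.
#' @param family_id optional label carried through.
#' @return tibble with `family_id`, `cutoff`, `retained_fraction`.
#' @export
length_variation_profile <- function(family_lengths, reference_len,
                                     cutoffs = c(0.01, 0.02, 0.05, 0.10,
                                                 0.15, 0.20, 0.25),
                                     family_id = NA_character_) {
  if (reference_len <= 0) stopf("reference_len must be > 0")
  retained <- vapply(cutoffs, function(w) {
    mean(family_lengths >= (1 - w) * reference_len &
           family_lengths <= (1 + w) * reference_len)
  }, numeric(1))
  tibble(family_id = family_id, cutoff = cutoffs,
         retained_fraction = retained)
}

#' Cluster families by their length-variation profiles
#'
#' Families are clustered by complete-linkage agglomeration on the Euclidean
#' distance between retained-fraction vectors and the tree is cut at `k`
#' clusters. Clusters are labeled 1..k by ascending mean retained fraction,
#' so cluster 1 collects the most length-variable families. Families with
#' identical profiles always land in the same cluster; if fewer than `k`
#' distinct profiles exist, each distinct profile forms its own cluster and
#' fewer than `k` labels are used.
#'
#' @param profiles tibble from [length_variation_profile()] rows (long form:
#'   `family_id`, `cutoff`, `retained_fraction`).
#' @param k number of clusters.
#' @return tibble with `family_id` and `cluster`.
#' @export
cluster_length_profiles <- function(profiles, k = 7) {
  check_columns(profiles, c("family_id", "cutoff", "retained_fraction"),
                "profiles")
  wide <- tidyr::pivot_wider(profiles, id_cols = "family_id",
                             names_from = "cutoff",
                             values_from = "retained_fraction")
  if (nrow(wide) < k) {
    stopf("need at least k = %d profiles (got %d)", k, nrow(wide))
  }
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$family_id
  prof_key <- apply(m, 1L, paste, collapse = ",")
  uniq <- !duplicated(prof_key)
  mu <- m[uniq, , drop = FALSE]
  if (nrow(mu) <= k) {
    raw <- seq_len(nrow(mu))
  } else {
    hc <- hclust(dist(mu), method = "complete")
    raw <- cutree(hc, k = k)
  }
  raw_all <- raw[match(prof_key, prof_key[uniq])]
  cluster_mean <- tapply(rowMeans(m), raw_all, mean)
  relabel <- rank(cluster_mean, ties.method = "first")
  tibble(family_id = wide$family_id,
         cluster = as.integer(relabel[as.character(raw_all)]))
}

#' Filter families by conservation score
#'
#' Retains families whose family score is strictly greater than the
#' threshold.
#'
#' @param scores tibble with `family_id` and `family_score` (percent).
#' @param threshold percent threshold (strict).
#' @return the retained subset of `scores`.
#' @export
filter_by_conservation <- function(scores, threshold = 50) {
  check_columns(scores, c("family_id", "family_score"), "scores")
  scores[scores$family_score > threshold, , drop = FALSE]
}
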