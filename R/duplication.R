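#' Assign per-chromosome gene ranks
#'
#' Genes on each chromosome get consecutive 0-based ranks ordered by start
#' coordinate (ties by end, then gene id). Strand is ignored.
#'
#' @param loci gene-locus tibble for one species (see [read_gene_models()]).
#' @return tibble with `gene_id`, `species`, `chromosome`, `start`, `end`,
#'   `rank`.
#' @export
assign_gene_ranks <- function(loci) {
  check_columns(loci, c("gene_id", "chromosome", "start", "end"), "loci")
  if (anyDuplicated(loci$gene_id)) {
    stopf("duplicate gene id: %s", loci$gene_id[duplicated(loci$gene_id)][1])
  }
  if (!"species" %in% names(loci)) loci$species <- NA_character_
  loci |>
    group_by(.data$chromosome) |>
    arrange(.data$start, .data$end, .data$gene_id, .by_group = TRUE) |>
    mutate(rank = row_number() - 1L) |>
    ungroup() |>
    select("gene_id", "species", "chromosome", "start", "end", "rank") |>
    arrange(.data$chromosome, .data$rank)
}

#' Build anchor pairs from similarity hits and gene ranks
#'
#' An anchor is a qualifying similarity hit between two distinct ranked
#' genes. Hits are filtered like in [classify_duplications()] (E-value when
#' available, otherwise the score surrogate, then top `max_targets` per
#' query) and each unordered pair is kept once, with chromosomes ordered so
#' that `chrom_a <= chrom_b` (ties by gene id).
#'
#' @param hits similarity tibble.
#' @param ranks rank tibble from [assign_gene_ranks()].
#' @param evalue_max maximum E-value for hits that carry E-values.
#' @param min_score minimum score for hits without E-values.
#' @param max_targets hits retained per query gene.
#' @return tibble with `gene_a`, `gene_b`, `chrom_a`, `chrom_b`, `rank_a`,
#'   `rank_b`, `score`.
#' @export
make_anchor_pairs <- function(hits, ranks, evalue_max = 1e-5, min_score = 50,
                              max_targets = 2) {
  kept <- retain_hits(hits, evalue_max, min_score, max_targets)
  if (nrow(kept) == 0L) return(empty_anchor_tbl())
  ra <- match(kept$query_id, ranks$gene_id)
  rb <- match(kept$subject_id, ranks$gene_id)
  ok <- !is.na(ra) & !is.na(rb)
  kept <- kept[ok, ]; ra <- ra[ok]; rb <- rb[ok]
  if (nrow(kept) == 0L) return(empty_anchor_tbl())
  anchors <- tibble(
    gene_a = kept$query_id, gene_b = kept$subject_id,
    chrom_a = ranks$chromosome[ra], chrom_b = ranks$chromosome[rb],
    rank_a = ranks$rank[ra], rank_b = ranks$rank[rb],
    score = kept$score)
  flip <- anchors$chrom_a > anchors$chrom_b |
    (anchors$chrom_a == anchors$chrom_b & anchors$gene_a > anchors$gene_b)
  anchors[flip, c("gene_a", "gene_b", "chrom_a", "chrom_b",
                  "rank_a", "rank_b")] <-
    anchors[flip, c("gene_b", "gene_a", "chrom_b", "chrom_a",
                    "rank_b", "rank_a")]
  anchors |>
    group_by(.data$gene_a, .data$gene_b) |>
    summarise(chrom_a = first(.data$chrom_a), chrom_b = first(.data$chrom_b),
              rank_a = first(.data$rank_a), rank_b = first(.data$rank_b),
              score = max(.data$score), .groups = "drop") |>
    arrange(.data$chrom_a, .data$chrom_b, .data$rank_a, .data$rank_b)
}

empty_anchor_tbl <- function() {
  tibble(gene_a = character(), gene_b = character(), chrom_a = character(),
         chrom_b = character(), rank_a = integer(), rank_b = integer(),
         score = double())
}

# Filter hits to non-self qualifying hits, top max_targets per query.
retain_hits <- function(hits, evalue_max, min_score, max_targets) {
  if (nrow(hits) == 0L) {
    return(tibble(query_id = character(), subject_id = character(),
                  score = double()))
  }
  check_columns(hits, c("query_id", "subject_id", "bitscore"), "hits")
  h <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  has_e <- !is.na(h$evalue %||% NA_real_)
  qual <- ifelse(has_e, h$evalue <= evalue_max, h$bitscore >= min_score)
  h <- h[qual, , drop = FALSE]
  if (nrow(h) == 0L) {
    return(tibble(query_id = character(), subject_id = character(),
                  score = double()))
  }
  h |>
    group_by(.data$query_id) |>
    arrange(desc(.data$bitscore), .data$subject_id, .by_group = TRUE) |>
    slice_head(n = max_targets) |>
    ungroup() |>
    distinct(.data$query_id, .data$subject_id, .keep_all = TRUE) |>
    select("query_id", "subject_id", score = "bitscore")
}

#' Detect collinear blocks from anchor pairs
#'
#' Within each chromosome pair, maximal chains of anchors are extracted by
#' dynamic programming: chains are strictly monotone in both rank axes
#' (increasing on both for `same` orientation, increasing/decreasing for
#' `inverted`) with consecutive anchors at most `max_gap` ranks apart on each
#' axis. The longest chain (preferring `same` orientation on ties, then the
#' lexicographically smallest anchor-index chain) is reported if it has at
#' least `min_anchors` anchors; its anchors are then removed and the search
#' repeats.
#'
#' @param anchors anchor tibble from [make_anchor_pairs()].
#' @param min_anchors minimum anchors per reported block (>= 2).
#' @param max_gap maximum rank gap between consecutive anchors.
#' @return tibble with `block_id`, `chrom_a`, `chrom_b`, `orientation`,
#'   `n_anchors`, and `anchors` (list of anchor tibbles).
#' @export
detect_collinear_blocks <- function(anchors, min_anchors = 5, max_gap = 25) {
  if (min_anchors < 2) stopf("min_anchors must be >= 2")
  if (nrow(anchors) == 0L) return(empty_block_tbl())
  pieces <- split(anchors,
                  paste(anchors$chrom_a, anchors$chrom_b, sep = "\r"))
  blocks <- list()
  for (piece in pieces) {
    piece <- arrange(piece, .data$rank_a, .data$rank_b, .data$gene_a,
                     .data$gene_b)
    repeat {
      if (nrow(piece) < min_anchors) break
      chain <- best_chain(piece$rank_a, piece$rank_b, max_gap)
      if (length(chain$idx) < min_anchors) break
      blocks[[length(blocks) + 1L]] <- tibble(
        chrom_a = piece$chrom_a[1], chrom_b = piece$chrom_b[1],
        orientation = chain$orientation,
        n_anchors = length(chain$idx),
        anchors = list(piece[chain$idx, , drop = FALSE]))
      piece <- piece[-chain$idx, , drop = FALSE]
    }
  }
  if (length(blocks) == 0L) return(empty_block_tbl())
  out <- bind_rows(blocks) |>
    arrange(.data$chrom_a, .data$chrom_b, desc(.data$n_anchors))
  out$block_id <- sprintf("block%04d", seq_len(nrow(out)))
  relocate(out, "block_id")
}

empty_block_tbl <- function() {
  tibble(block_id = character(), chrom_a = character(), chrom_b = character(),
         orientation = character(), n_anchors = integer(), anchors = list())
}

# Longest strictly monotone chain (rows pre-sorted by rank_a, rank_b);
# returns the lexicographically smallest index chain among maximal ones,
# preferring 'same' orientation when lengths tie.
best_chain <- function(rank_a, rank_b, max_gap) {
  same <- lex_smallest_chain(rank_a, rank_b, max_gap, inverted = FALSE)
  inv <- lex_smallest_chain(rank_a, rank_b, max_gap, inverted = TRUE)
  if (length(same) >= length(inv)) {
    list(idx = same, orientation = "same")
  } else {
    list(idx = inv, orientation = "inverted")
  }
}

lex_smallest_chain <- function(rank_a, rank_b, max_gap, inverted) {
  n <- length(rank_a)
  rb <- if (inverted) -rank_b else rank_b
  # f[i]: length of the longest valid chain starting at i (reverse DP)
  f <- rep(1L, n)
  for (i in n:1) {
    for (j in seq_len(n)) {
      if (j <= i) next
      da <- rank_a[j] - rank_a[i]
      db <- rb[j] - rb[i]
      if (da > 0 && da <= max_gap && db > 0 && db <= max_gap) {
        if (f[j] + 1L > f[i]) f[i] <- f[j] + 1L
      }
    }
  }
  if (n == 0L) return(integer(0))
  total <- max(f)
  chain <- integer(0)
  need <- total
  prev <- NA_integer_
  for (step in seq_len(total)) {
    for (i in seq_len(n)) {
      if (f[i] != need) next
      if (!is.na(prev)) {
        da <- rank_a[i] - rank_a[prev]
        db <- rb[i] - rb[prev]
        if (!(da > 0 && da <= max_gap && db > 0 && db <= max_gap)) next
      }
      chain <- c(chain, i)
      prev <- i
      need <- need - 1L
      break
    }
  }
  chain
}

#' Classify gene duplication origins
#'
#' MCScanX-style precedence: a gene anchored in any collinear block is
#' `wgd_segmental`; otherwise `tandem` if any retained hit partner is
#' rank-adjacent on the same chromosome; otherwise `proximal` when a partner
#' lies within `proximal_window` ranks; otherwise `dispersed` if any retained
#' hit exists; otherwise `singleton`. Genes appearing in hits but missing
#' from `ranks` are `unassigned`. Hits are first filtered (E-value when
#' available, otherwise score), then the top `max_targets` non-self subjects
#' are retained per query; partnership is symmetric over retained hits.
#'
#' @param ranks rank tibble from [assign_gene_ranks()] (defines the gene
#'   universe).
#' @param hits similarity tibble.
#' @param blocks block tibble from [detect_collinear_blocks()] (or `NULL`).
#' @param proximal_window maximum rank distance for `proximal`.
#' @param evalue_max maximum E-value for hits carrying E-values.
#' @param min_score score surrogate for hits without E-values.
#' @param max_targets retained subjects per query.
#' @return tibble with `gene_id`, `species`, `class`.
#' @export
classify_duplications <- function(ranks, hits, blocks = NULL,
                                  proximal_window = 10, evalue_max = 1e-5,
                                  min_score = 50, max_targets = 2) {
  check_columns(ranks, c("gene_id", "chromosome", "rank"), "ranks")
  kept <- retain_hits(hits, evalue_max, min_score, max_targets)
  partners <- bind_rows(
    select(kept, gene = "query_id", partner = "subject_id"),
    select(kept, gene = "subject_id", partner = "query_id")) |>
    distinct()

  wgd_genes <- character(0)
  if (!is.null(blocks) && nrow(blocks) > 0L) {
    wgd_genes <- unique(unlist(lapply(blocks$anchors, function(a) {
      c(a$gene_a, a$gene_b)
    })))
  }

  gene_chrom <- setNames(ranks$chromosome, ranks$gene_id)
  gene_rank <- setNames(ranks$rank, ranks$gene_id)
  partners$chrom_g <- gene_chrom[partners$gene]
  partners$chrom_p <- gene_chrom[partners$partner]
  partners$drank <- abs(gene_rank[partners$gene] - gene_rank[partners$partner])
  same_chrom <- !is.na(partners$chrom_g) & !is.na(partners$chrom_p) &
    partners$chrom_g == partners$chrom_p

  tandem_genes <- unique(partners$gene[same_chrom & partners$drank == 1L])
  proximal_genes <- unique(partners$gene[same_chrom &
                                           partners$drank <= proximal_window])
  hit_genes <- unique(partners$gene)

  classify_one <- function(g) {
    if (g %in% wgd_genes) "wgd_segmental"
    else if (g %in% tandem_genes) "tandem"
    else if (g %in% proximal_genes) "proximal"
    else if (g %in% hit_genes) "dispersed"
    else "singleton"
  }
  calls <- tibble(
    gene_id = ranks$gene_id,
    species = ranks$species %||% NA_character_,
    class = vapply(ranks$gene_id, classify_one, character(1)))

  orphan <- setdiff(unique(c(hits$query_id, hits$subject_id)), ranks$gene_id)
  if (length(orphan) > 0L) {
    calls <- bind_rows(calls, tibble(gene_id = orphan,
                                     species = NA_character_,
                                     class = "unassigned"))
  }
  calls$class <- factor(calls$class, levels = duplication_classes())
  calls
}

#' Duplication class labels
#'
#' @return character vector of the class levels in precedence order.
#' @export
duplication_classes <- function() {
  c("singleton", "dispersed", "proximal", "tandem", "wgd_segmental",
    "unassigned")
}

#' Per-species duplication class counts
#'
#' One row per species with one column per class plus a `total` column equal
#' to the row sum (the shape of published duplication-classification
#' tables).
#'
#' @param calls tibble from [classify_duplications()].
#' @return tibble with `species`, the six class counts, and `total`.
#' @export
duplication_summary <- function(calls) {
  check_columns(calls, c("gene_id", "species", "class"), "calls")
  if (nrow(calls) == 0L) {
    out <- tibble(species = NA_character_)
    for (cl in duplication_classes()) out[[cl]] <- 0L
    out$total <- 0L
    return(out)
  }
  calls$class <- factor(as.character(calls$class),
                        levels = duplication_classes())
  counts <- calls |>
    count(.data$species, .data$class, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
  counts$total <- rowSums(counts[, duplication_classes()])
  counts
}

#' Write collinear blocks in a collinearity text format
#'
#' Block header lines (`## block id ...`) followed by one anchor pair per
#' line.
#'
#' @param blocks tibble from [detect_collinear_blocks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_collinearity <- function(blocks, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(blocks))) {
    writeLines(sprintf("## %s %s vs %s orientation=%s n=%d",
                       blocks$block_id[i], blocks$chrom_a[i],
                       blocks$chrom_b[i], blocks$orientation[i],
                       blocks$n_anchors[i]), con, sep = "\n")
    a <- blocks$anchors[[i]]
    writeLines(sprintf("%s\t%s\t%d\t%d", a$gene_a, a$gene_b, a$rank_a,
                       a$rank_b), con, sep = "\n")
  }
  invisible(path)
}
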