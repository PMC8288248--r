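#' Extract the flanking region of a focal gene
#'
#' Returns the focal gene together with up to `n` neighbouring genes on each
#' side of the same chromosome (order by start coordinate), truncated
#' silently at chromosome ends. The region span runs from the smallest start
#' to the largest end among member genes.
#'
#' @param focal_id gene id present in `loci`.
#' @param loci gene-locus tibble for one species.
#' @param n flank size in genes per side.
#' @return a tibble of member loci (class `flank_region`) with attributes
#'   `focal_gene`, `species`, `chromosome`, `span_start`, `span_end`.
#' @export
extract_flank_region <- function(focal_id, loci, n = 20) {
  check_columns(loci, c("gene_id", "chromosome", "start", "end"), "loci")
  if (!focal_id %in% loci$gene_id) stopf("unknown focal gene: %s", focal_id)
  if (n < 0) stopf("n must be >= 0")
  focal <- loci[loci$gene_id == focal_id, ][1, ]
  chrom <- loci |>
    filter(.data$chromosome == focal$chromosome) |>
    arrange(.data$start, .data$end, .data$gene_id)
  pos <- which(chrom$gene_id == focal_id)
  lo <- max(1L, pos - n)
  hi <- min(nrow(chrom), pos + n)
  genes <- chrom[lo:hi, , drop = FALSE]
  structure(genes,
            class = c("flank_region", class(genes)),
            focal_gene = focal_id,
            species = if ("species" %in% names(focal)) focal$species else NA_character_,
            chromosome = focal$chromosome,
            span_start = min(genes$start),
            span_end = max(genes$end))
}

#' Conserved gene pairs between two flanking regions
#'
#' A pair is conserved when amino-acid identity and both coverages are
#' strictly above their thresholds and the hit's E-value is strictly below
#' `evalue_max` (when a precomputed similarity table with E-values is
#' supplied) or its alignment score reaches `min_score` (when similarity is
#' computed internally). Many-to-many matches are resolved one-to-one
#' greedily by best score.
#'
#' @param region_a,region_b `flank_region` objects (see
#'   [extract_flank_region()]).
#' @param proteins protein tibble covering all member genes (ids match gene
#'   ids).
#' @param hits optional precomputed similarity tibble; when `NULL`, local
#'   alignments are computed internally with `scheme`.
#' @param scheme a [scoring_scheme()]; defaults to the BLAST-like
#'   [search_scheme()].
#' @param id_min identity threshold in percent (strict).
#' @param cov_min coverage threshold in percent (strict, both sequences).
#' @param evalue_max E-value threshold (strict) for external hits.
#' @param min_score bitscore threshold for internal hits (see
#'   [all_vs_all()]).
#' @return tibble with `gene_a`, `gene_b`, `identity`, `query_cov`,
#'   `subject_cov`, `score`.
#' @export
conserved_pairs <- function(region_a, region_b, proteins, hits = NULL,
                            scheme = search_scheme(), id_min = 60,
                            cov_min = 60, evalue_max = 1e-10,
                            min_score = 50) {
  ids_a <- region_a$gene_id
  ids_b <- region_b$gene_id
  if (is.null(hits)) {
    seq_a <- proteins$sequence[match(ids_a, proteins$id)]
    seq_b <- proteins$sequence[match(ids_b, proteins$id)]
    if (anyNA(seq_a) || anyNA(seq_b)) {
      stopf("missing protein sequence for a region gene")
    }
    grid <- expand.grid(i = seq_along(ids_a), j = seq_along(ids_b))
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(seq_a[grid$i]),
      Biostrings::AAStringSet(seq_b[grid$j]),
      substitutionMatrix = scheme$matrix, gapOpening = scheme$gap_open,
      gapExtension = scheme$gap_extend, type = "local")
    nm <- Biostrings::nmatch(pa); nmm <- Biostrings::nmismatch(pa)
    al_a <- as.character(Biostrings::alignedPattern(pa))
    al_b <- as.character(Biostrings::alignedSubject(pa))
    span_a <- nchar(gsub("-", "", al_a, fixed = TRUE))
    span_b <- nchar(gsub("-", "", al_b, fixed = TRUE))
    cand <- tibble(
      gene_a = ids_a[grid$i], gene_b = ids_b[grid$j],
      identity = ifelse(nm + nmm == 0, 0, nm / (nm + nmm) * 100),
      query_cov = span_a / nchar(seq_a[grid$i]) * 100,
      subject_cov = span_b / nchar(seq_b[grid$j]) * 100,
      score = raw_to_bitscore(Biostrings::score(pa)))
    cand <- cand[cand$score >= min_score, , drop = FALSE]
  } else {
    h <- hits[hits$query_id %in% ids_a & hits$subject_id %in% ids_b, ,
              drop = FALSE]
    cand <- tibble(gene_a = h$query_id, gene_b = h$subject_id,
                   identity = h$identity,
                   query_cov = h$query_cov %||% NA_real_,
                   subject_cov = h$subject_cov %||% NA_real_,
                   score = h$bitscore)
    ok_e <- if ("evalue" %in% names(h)) {
      ifelse(is.na(h$evalue), cand$score >= min_score, h$evalue < evalue_max)
    } else cand$score >= min_score
    cand <- cand[ok_e, , drop = FALSE]
  }
  cov_ok <- (is.na(cand$query_cov) | cand$query_cov > cov_min) &
    (is.na(cand$subject_cov) | cand$subject_cov > cov_min)
  cand <- cand[cand$identity > id_min & cov_ok & cand$gene_a != cand$gene_b, ,
               drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  # one-to-one by best score
  cand <- arrange(cand, desc(.data$score), .data$gene_a, .data$gene_b)
  used_a <- character(0); used_b <- character(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$gene_a[i] %in% used_a || cand$gene_b[i] %in% used_b) next
    keep[i] <- TRUE
    used_a <- c(used_a, cand$gene_a[i])
    used_b <- c(used_b, cand$gene_b[i])
  }
  cand[keep, , drop = FALSE]
}

#' Syntenic-region statistics
#'
#' Computes, for one flanking region, the total gene count, the number of
#' member genes without a conserved partner, the intergenic proportion
#' (1 minus the fraction of the region span covered by the union of gene
#' spans) and the repeat density (fraction of the span covered by the union
#' of repeat features on the region's chromosome).
#'
#' @param region a `flank_region`.
#' @param pairs conserved-pair tibble from [conserved_pairs()] (may be
#'   empty).
#' @param repeats optional repeat tibble (see [read_repeat_annotations()]).
#' @return one-row tibble with `focal_gene`, `total_genes`,
#'   `genes_without_collinearity`, `intergenic_proportion`, `repeat_density`.
#' @export
region_stats <- function(region, pairs, repeats = NULL) {
  span_start <- attr(region, "span_start")
  span_end <- attr(region, "span_end")
  span <- span_end - span_start + 1
  if (is.null(span) || length(span) == 0L || span <= 0) {
    stopf("region has a zero-length span")
  }
  paired <- unique(c(pairs$gene_a, pairs$gene_b))
  genic <- interval_union_width(region$start, region$end, span_start, span_end)
  rep_width <- 0
  if (!is.null(repeats) && nrow(repeats) > 0L) {
    reps <- repeats[repeats$chromosome == attr(region, "chromosome"), ,
                    drop = FALSE]
    rep_width <- interval_union_width(reps$start, reps$end, span_start,
                                      span_end)
  }
  tibble(focal_gene = attr(region, "focal_gene"),
         total_genes = nrow(region),
         genes_without_collinearity = sum(!region$gene_id %in% paired),
         intergenic_proportion = 1 - genic / span,
         repeat_density = rep_width / span)
}
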