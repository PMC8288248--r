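#' Pipeline configuration
#'
#' Collects the file paths and thresholds of a full run. All thresholds
#' default to the values used by the individual stages.
#'
#' @param proteins,cds,gff3,domains path to the per-species inputs.
#' @param catalog,ref_proteins,ref_domains reference catalog TSV and its
#'   sequence/domain resources.
#' @param repeats optional repeat GFF3.
#' @param similarity optional precomputed all-vs-all similarity table
#'   (BLAST outfmt-6 dialect); computed internally when absent.
#' @param output_dir report directory.
#' @param species species label.
#' @param focal_genes gene ids for microsynteny analysis (may be empty).
#' @param evalue_max,identity_min,coverage_min,min_score thresholds shared
#'   by the similarity-driven stages.
#' @param length_window half-width of the identification length window.
#' @param min_anchors,max_gap,proximal_window collinearity parameters.
#' @param min_copies minimum family size scored for conservation.
#' @param clusters number of length-variation clusters.
#' @param flank_n flank size (genes per side) for microsynteny.
#' @param redundancy_identity proteome-cleaning identity cutoff.
#' @param seed seed for any stochastic step.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(proteins, cds, gff3, domains, catalog,
                            ref_proteins, ref_domains, repeats = NULL,
                            similarity = NULL, output_dir = tempfile("polyflor_run"),
                            species = NA_character_,
                            focal_genes = character(0), evalue_max = 1e-5,
                            identity_min = 60, coverage_min = 60,
                            min_score = 50, length_window = 0.1,
                            min_anchors = 5, max_gap = 25,
                            proximal_window = 10, min_copies = 3,
                            clusters = 7, flank_n = 20,
                            redundancy_identity = 1.0, seed = 1L) {
  cfg <- list(proteins = proteins, cds = cds, gff3 = gff3, domains = domains,
              catalog = catalog, ref_proteins = ref_proteins,
              ref_domains = ref_domains, repeats = repeats,
              similarity = similarity, output_dir = output_dir,
              species = species, focal_genes = focal_genes,
              evalue_max = evalue_max, identity_min = identity_min,
              coverage_min = coverage_min, min_score = min_score,
              length_window = length_window, min_anchors = min_anchors,
              max_gap = max_gap, proximal_window = proximal_window,
              min_copies = min_copies, clusters = clusters,
              flank_n = flank_n, redundancy_identity = redundancy_identity,
              seed = as.integer(seed))
  required <- c("proteins", "cds", "gff3", "domains", "catalog",
                "ref_proteins", "ref_domains")
  for (p in required) {
    if (!file.exists(cfg[[p]])) stopf("input file for '%s' not found: %s",
                                      p, cfg[[p]])
  }
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes proteome cleaning, reference catalog loading and subtype
#' construction, domain-architecture identification, conservation scoring
#' and length-variation clustering, collinearity-based duplication
#' classification, optional microsynteny around focal genes, reciprocal
#' similarity-network grouping, and within-family synonymous-distance
#' estimation. All reports are written as TSV files under the configured
#' output directory together with a plain-text run log; a rerun of the same
#' configuration rewrites identical reports.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a named list of result tibbles (the report bundle).
#' @export
run_full <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stopf("config must come from pipeline_config()")
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  scheme <- scoring_scheme()

  proteins <- run_stage("read_proteins",
                        read_protein_fasta(config$proteins, config$species))
  cds <- run_stage("read_cds", read_cds_fasta(config$cds, config$species))
  loci <- run_stage("read_gene_models",
                    read_gene_models(config$gff3, config$species))
  hits_dom <- run_stage("read_domains",
                        read_domain_annotations(config$domains))
  repeats <- if (is.null(config$repeats)) NULL else
    run_stage("read_repeats", read_repeat_annotations(config$repeats))

  proteins <- run_stage("clean_proteome",
                        clean_proteome(proteins, config$redundancy_identity,
                                       scheme))

  ref_prot <- run_stage("read_reference",
                        read_protein_fasta(config$ref_proteins))
  ref_hits <- run_stage("read_reference",
                        read_domain_annotations(config$ref_domains))
  refgenes <- run_stage("catalog",
                        load_reference_catalog(config$catalog, ref_prot,
                                               ref_hits))
  subtypes <- run_stage("catalog", build_subtypes(refgenes))

  lengths_map <- setNames(proteins$length, proteins$id)
  similarity <- if (is.null(config$similarity)) {
    run_stage("all_vs_all",
              all_vs_all(proteins, max_targets = 2,
                         min_score = config$min_score))
  } else {
    run_stage("read_similarity",
              read_similarity_table(config$similarity,
                                    query_lengths = lengths_map,
                                    subject_lengths = lengths_map))
  }

  candidates <- run_stage("identify",
                          identify_family_members(
                            subtypes, proteins, hits_dom,
                            length_window = config$length_window))
  identified <- candidates[candidates$passed_length_filter, , drop = FALSE]

  # conservation on identified families with enough copies
  fam_assign <- tibble(gene_id = identified$protein_id,
                       family_id = identified$subtype_id)
  fam_sizes <- count(fam_assign, .data$family_id)
  big_fams <- fam_sizes$family_id[fam_sizes$n >= config$min_copies]
  ref_len_map <- setNames(refgenes$length, refgenes$symbol)
  cons_rows <- list()
  lv_rows <- list()
  for (fid in big_fams) {
    ids <- fam_assign$gene_id[fam_assign$family_id == fid]
    seqs <- setNames(sub("\\*$", "", proteins$sequence[match(ids, proteins$id)]),
                     ids)
    msa <- run_stage("conservation", progressive_msa(seqs, scheme))
    prof <- run_stage("conservation",
                      conservation_profile(msa, config$min_copies))
    cons_rows[[fid]] <- tibble(family_id = fid,
                               n_members = prof$n_members,
                               family_score = prof$family_score)
    ref_len <- unname(ref_len_map[fid])
    if (!is.na(ref_len)) {
      lv_rows[[fid]] <- length_variation_profile(
        proteins$length[match(ids, proteins$id)], ref_len, family_id = fid)
    }
  }
  conservation <- bind_rows(cons_rows)
  length_profiles <- bind_rows(lv_rows)
  clusters_tbl <- if (nrow(length_profiles) > 0L &&
                      length(unique(length_profiles$family_id)) >=
                        config$clusters) {
    run_stage("conservation",
              cluster_length_profiles(length_profiles, config$clusters))
  } else tibble(family_id = character(), cluster = integer())
  conserved_families <- if (nrow(conservation) > 0L) {
    filter_by_conservation(conservation)
  } else conservation

  # duplication classification
  ranks <- run_stage("duplication", assign_gene_ranks(loci))
  anchors <- run_stage("duplication",
                       make_anchor_pairs(similarity, ranks,
                                         evalue_max = config$evalue_max,
                                         min_score = config$min_score))
  blocks <- run_stage("duplication",
                      detect_collinear_blocks(anchors,
                                              min_anchors = config$min_anchors,
                                              max_gap = config$max_gap))
  calls <- run_stage("duplication",
                     classify_duplications(ranks, similarity, blocks,
                                           proximal_window = config$proximal_window,
                                           evalue_max = config$evalue_max,
                                           min_score = config$min_score))
  dup_summary <- duplication_summary(calls)

  # microsynteny around focal genes
  synteny <- list()
  for (focal in config$focal_genes) {
    partner_hits <- similarity[similarity$query_id == focal &
                                 similarity$subject_id != focal, ]
    if (nrow(partner_hits) == 0L) next
    partner <- partner_hits$subject_id[which.max(partner_hits$bitscore)]
    region_a <- extract_flank_region(focal, loci, config$flank_n)
    region_b <- extract_flank_region(partner, loci, config$flank_n)
    pairs <- conserved_pairs(region_a, region_b, proteins,
                             id_min = config$identity_min,
                             cov_min = config$coverage_min,
                             min_score = config$min_score)
    synteny[[focal]] <- bind_rows(
      mutate(region_stats(region_a, pairs, repeats), side = "focal"),
      mutate(region_stats(region_b, pairs, repeats), side = "partner"))
  }
  synteny_stats <- bind_rows(synteny)

  # similarity network over identified genes
  net_records <- similarity[similarity$query_id %in% identified$protein_id &
                              similarity$subject_id %in% identified$protein_id, ]
  network <- run_stage("network",
                       build_network(net_records,
                                     id_min = config$identity_min,
                                     cov_min = config$coverage_min,
                                     min_score = config$min_score,
                                     nodes = identified$protein_id))
  groups <- run_stage("network",
                      group_stats(network_components(network), proteins,
                                  calls))

  # synonymous distances within identified families
  ks_tbl <- run_stage("ks",
                      pairwise_ks_for_families(fam_assign, proteins, cds,
                                               scheme))

  prop <- proportion_table(tibble(species = config$species %||% NA_character_,
                                  copy_number = nrow(identified),
                                  total_genes = nrow(proteins)))

  bundle <- list(candidates = candidates, identified = identified,
                 subtypes = subtypes, conservation = conservation,
                 length_profiles = length_profiles,
                 length_clusters = clusters_tbl,
                 conserved_families = conserved_families,
                 similarity = similarity, ranks = ranks, anchors = anchors,
                 blocks = blocks, duplication_calls = calls,
                 duplication_summary = dup_summary,
                 synteny_stats = synteny_stats, network = network,
                 network_groups = groups, ks = ks_tbl, proportion = prop)

  out <- config$output_dir
  write_candidates_tsv(candidates, file.path(out, "candidates.tsv"))
  readr::write_tsv(conservation, file.path(out, "conservation.tsv"),
                   progress = FALSE)
  readr::write_tsv(length_profiles, file.path(out, "length_profiles.tsv"),
                   progress = FALSE)
  readr::write_tsv(clusters_tbl, file.path(out, "length_clusters.tsv"),
                   progress = FALSE)
  readr::write_tsv(mutate(calls, class = as.character(.data$class)),
                   file.path(out, "duplication_calls.tsv"), progress = FALSE)
  readr::write_tsv(dup_summary, file.path(out, "duplication_summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(synteny_stats, file.path(out, "synteny_stats.tsv"),
                   progress = FALSE)
  write_network_edgelist(network, file.path(out, "network_edges.tsv"))
  readr::write_tsv(select(groups, "group_id", "n_members", "major",
                          "mean_length"),
                   file.path(out, "network_groups.tsv"), progress = FALSE)
  write_ks_tsv(ks_tbl, file.path(out, "ks_pairs.tsv"))
  readr::write_tsv(prop, file.path(out, "proportion.tsv"), progress = FALSE)
  write_collinearity(blocks, file.path(out, "collinearity.txt"))
  log_lines <- c(
    sprintf("polyflor %s", as.character(utils::packageVersion("polyflor"))),
    sprintf("seed: %d", config$seed),
    sprintf("species: %s", config$species),
    sprintf("thresholds: evalue_max=%g identity_min=%g coverage_min=%g min_score=%g",
            config$evalue_max, config$identity_min, config$coverage_min,
            config$min_score),
    sprintf("collinearity: min_anchors=%d max_gap=%d proximal_window=%d",
            config$min_anchors, config$max_gap, config$proximal_window),
    sprintf("identified: %d of %d candidate matches pass the length filter",
            nrow(identified), nrow(candidates)))
  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(bundle)
}

#' Per-species copy-number proportion table
#'
#' Adds the percentage of each species' genes identified as family members
#' (rounded half-up to 2 decimals) and appends a total row summing copy and
#' gene numbers (its proportion is `NA`, as printed in published tables).
#'
#' @param counts tibble with `species`, `copy_number`, `total_genes` (and
#'   optionally `family`).
#' @return tibble of rows plus a `Total` row.
#' @export
proportion_table <- function(counts) {
  check_columns(counts, c("species", "copy_number", "total_genes"), "counts")
  if (any(counts$total_genes <= 0)) {
    stopf("total_genes must be positive for every species")
  }
  if (any(counts$copy_number < 0)) stopf("copy_number must be >= 0")
  out <- mutate(counts, proportion = round_half_up(
    .data$copy_number / .data$total_genes * 100, 2))
  total <- tibble(species = "Total",
                  copy_number = sum(counts$copy_number),
                  total_genes = sum(counts$total_genes),
                  proportion = NA_real_)
  if ("family" %in% names(counts)) total <- mutate(total, family = "-")
  bind_rows(out, total)
}

#' Identification accuracy against simulator truth
#'
#' Compares the identified set (candidates passing the length filter,
#' assigned to the reference symbol of their subtype) with the planted
#' family membership: precision is the fraction of identified genes whose
#' assigned family matches the truth, recall the fraction of planted genes
#' recovered with the correct family.
#'
#' @param candidates tibble from [identify_family_members()].
#' @param truth truth tibble of a `synthetic_dataset`.
#' @return one-row tibble with `precision`, `recall`, `n_identified`,
#'   `n_truth`.
#' @export
identification_metrics <- function(candidates, truth) {
  identified <- candidates[candidates$passed_length_filter, , drop = FALSE]
  fam <- truth$family_id[match(identified$protein_id, truth$gene_id)]
  correct <- !is.na(fam) & identified$reference_symbol == fam
  recovered <- truth$gene_id %in% identified$protein_id[correct]
  tibble(precision = if (nrow(identified)) mean(correct) else NA_real_,
         recall = mean(recovered),
         n_identified = nrow(identified), n_truth = nrow(truth))
}

#' Duplication-classification accuracy against simulator truth
#'
#' @param calls tibble from [classify_duplications()].
#' @param truth truth tibble of a `synthetic_dataset`.
#' @return one-row tibble with `accuracy` and `n`.
#' @export
classification_accuracy <- function(calls, truth) {
  m <- inner_join(select(truth, "gene_id", "duplication_class"),
                  mutate(calls, class = as.character(.data$class)),
                  by = "gene_id")
  tibble(accuracy = mean(m$duplication_class == m$class), n = nrow(m))
}
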