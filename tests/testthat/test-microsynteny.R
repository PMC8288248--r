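region_loci <- function(n = 45, chrom = "c1", gap = 1000L, width = 500L,
                        offset = 0L) {
  starts <- offset + seq_len(n) * (gap + width)
  tibble::tibble(gene_id = sprintf("%s_g%02d", chrom, seq_len(n)),
                 chromosome = chrom, start = starts,
                 end = starts + width - 1L, strand = "+", species = "sp")
}

test_that("flank extraction truncates at chromosome ends", {
  loci <- region_loci(45)
  mid <- extract_flank_region("c1_g23", loci, n = 20)
  expect_equal(nrow(mid), 41L)
  expect_equal(attr(mid, "focal_gene"), "c1_g23")

  near_start <- extract_flank_region("c1_g03", loci, n = 20)
  expect_equal(nrow(near_start), 2L + 1L + 20L)

  alone <- extract_flank_region("c1_g10", loci, n = 0)
  expect_equal(nrow(alone), 1L)

  expect_error(extract_flank_region("nope", loci), "unknown focal gene")
})

test_that("conserved pairs resolve one-to-one with strict thresholds", {
  loci_a <- region_loci(5, "c1")
  loci_b <- region_loci(6, "c2")
  ra <- extract_flank_region("c1_g03", loci_a, n = 2)
  rb <- extract_flank_region("c2_g03", loci_b, n = 2)
  set.seed(44)
  seqs <- vapply(1:5, function(i) random_protein(80), character(1))
  proteins <- tibble::tibble(
    id = c(ra$gene_id, rb$gene_id),
    sequence = c(seqs, seqs),    # identical counterpart regions
    length = 80L)
  pairs <- conserved_pairs(ra, rb, proteins)
  expect_equal(nrow(pairs), 5L)
  expect_equal(sub("c1", "", pairs$gene_a), sub("c2", "", pairs$gene_b))

  # a gene present only in region_b stays unpaired
  proteins2 <- proteins
  proteins2$sequence[proteins2$id == "c2_g04"] <- random_protein(80)
  pairs2 <- conserved_pairs(ra, rb, proteins2)
  expect_false("c2_g04" %in% pairs2$gene_b)

  # identity exactly at the threshold is excluded (strict >)
  hits <- tibble::tibble(query_id = "c1_g02", subject_id = "c2_g02",
                         identity = 60, align_length = 80L,
                         mismatches = NA_integer_, gap_opens = NA_integer_,
                         qstart = NA_integer_, qend = NA_integer_,
                         sstart = NA_integer_, send = NA_integer_,
                         evalue = 1e-30, bitscore = 100,
                         query_cov = 100, subject_cov = 100)
  expect_equal(nrow(conserved_pairs(ra, rb, proteins, hits = hits)), 0L)
  hits$identity <- 60.1
  expect_equal(nrow(conserved_pairs(ra, rb, proteins, hits = hits)), 1L)
})

test_that("region statistics follow the union-interval arithmetic", {
  # span 10,000 bp with three genes covering 4,000 bp
  loci <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), chromosome = "c1",
    start = c(1L, 4001L, 8501L), end = c(1500L, 5000L, 10000L),
    strand = "+", species = "sp")
  region <- extract_flank_region("g2", loci, n = 5)
  stats <- region_stats(region, pairs = tibble::tibble(gene_a = character(),
                                                       gene_b = character()))
  expect_equal(stats$total_genes, 3L)
  expect_equal(stats$genes_without_collinearity, 3L)
  expect_equal(stats$intergenic_proportion, 0.6)
  expect_equal(stats$repeat_density, 0)

  tiling <- tibble::tibble(chromosome = "c1", start = 1L, end = 10000L,
                           class = "LTR")
  expect_equal(region_stats(region, tibble::tibble(gene_a = character(),
                                                   gene_b = character()),
                            tiling)$repeat_density, 1)

  # duplicated/overlapping gene features do not change the union
  loci_dup <- dplyr::bind_rows(
    loci, tibble::tibble(gene_id = "g2b", chromosome = "c1", start = 4001L,
                         end = 5000L, strand = "+", species = "sp"))
  region_dup <- extract_flank_region("g2", loci_dup, n = 5)
  expect_equal(region_stats(region_dup, tibble::tibble(
    gene_a = character(), gene_b = character()))$intergenic_proportion, 0.6)
})

test_that("intergenic and genic proportions sum to one and translate invariantly", {
  loci <- region_loci(9, "c3", gap = 700L, width = 350L)
  region <- extract_flank_region("c3_g05", loci, n = 4)
  stats <- region_stats(region, tibble::tibble(gene_a = character(),
                                               gene_b = character()))
  span <- attr(region, "span_end") - attr(region, "span_start") + 1
  genic <- sum(region$end - region$start + 1)
  expect_equal(stats$intergenic_proportion + genic / span, 1)

  shifted <- region_loci(9, "c3", gap = 700L, width = 350L, offset = 50000L)
  region2 <- extract_flank_region("c3_g05", shifted, n = 4)
  stats2 <- region_stats(region2, tibble::tibble(gene_a = character(),
                                                 gene_b = character()))
  expect_equal(stats$intergenic_proportion, stats2$intergenic_proportion)
})

test_that("synthetic flank regions count planted insertions as non-collinear", {
  ds <- small_dataset()
  hp <- ds$homeolog_pairs[1, ]
  region_a <- extract_flank_region(hp$id_a, ds$loci, n = 10)
  region_b <- extract_flank_region(hp$id_b, ds$loci, n = 10)
  pairs <- conserved_pairs(region_a, region_b, ds$proteins)
  stats <- region_stats(region_a, pairs, ds$repeats)
  expect_lte(stats$genes_without_collinearity, stats$total_genes)
  expect_gte(stats$intergenic_proportion, 0)
  expect_lte(stats$intergenic_proportion, 1)
})
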