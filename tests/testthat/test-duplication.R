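mkloci <- function(df) {
  tibble::tibble(gene_id = df$id, chromosome = df$chr, start = df$s,
                 end = df$s + 99L, strand = "+", species = "sp")
}

test_that("gene ranks are per-chromosome, start-ordered and input-order free", {
  loci <- mkloci(data.frame(id = c("a", "b", "c", "d", "e"),
                            chr = c("c1", "c1", "c1", "c2", "c2"),
                            s = c(100L, 500L, 900L, 300L, 50L)))
  r <- assign_gene_ranks(loci)
  expect_equal(r$rank[match(c("a", "b", "c"), r$gene_id)], 0:2)
  expect_equal(r$rank[match(c("e", "d"), r$gene_id)], 0:1)

  shuffled <- assign_gene_ranks(loci[c(4, 2, 5, 1, 3), ])
  expect_equal(dplyr::arrange(r, gene_id), dplyr::arrange(shuffled, gene_id))

  expect_error(assign_gene_ranks(loci[c(1, 1), ]), "duplicate")
})

diag_anchors <- function(n, chrom_b = "c2", jitter = 0L) {
  tibble::tibble(gene_a = paste0("a", seq_len(n)),
                 gene_b = paste0("b", seq_len(n)),
                 chrom_a = "c1", chrom_b = chrom_b,
                 rank_a = seq_len(n) - 1L,
                 rank_b = seq_len(n) - 1L + jitter, score = 100)
}

test_that("collinear blocks need min_anchors on a monotone chain", {
  six <- detect_collinear_blocks(diag_anchors(6), min_anchors = 5)
  expect_equal(nrow(six), 1L)
  expect_equal(six$n_anchors, 6L)
  expect_equal(six$orientation, "same")

  four <- detect_collinear_blocks(diag_anchors(4), min_anchors = 5)
  expect_equal(nrow(four), 0L)

  inv <- diag_anchors(6)
  inv$rank_b <- rev(inv$rank_b)
  blk <- detect_collinear_blocks(inv, min_anchors = 5)
  expect_equal(blk$orientation, "inverted")

  expect_error(detect_collinear_blocks(diag_anchors(6), min_anchors = 1),
               ">= 2")
})

test_that("block extraction matches exhaustive chain search on random layouts", {
  set.seed(31)
  for (trial in 1:60) {
    n <- sample(3:10, 1)
    anchors <- tibble::tibble(
      gene_a = paste0("a", seq_len(n)), gene_b = paste0("b", seq_len(n)),
      chrom_a = "c1", chrom_b = "c2",
      rank_a = sample(0:14, n), rank_b = sample(0:14, n), score = 100)
    max_gap <- sample(c(3, 8, 25), 1)
    min_anchors <- sample(2:4, 1)
    got <- detect_collinear_blocks(anchors, min_anchors, max_gap)
    expect_equal(got$n_anchors,
                 oracle_blocks(anchors, min_anchors, max_gap),
                 info = sprintf("trial %d", trial))
  }
})

test_that("raising min_anchors never increases wgd calls", {
  ds <- small_dataset()
  hits <- all_vs_all(ds$proteins)
  ranks <- assign_gene_ranks(ds$loci)
  anchors <- make_anchor_pairs(hits, ranks)
  n_wgd <- vapply(c(3, 5, 8, 12), function(m) {
    blocks <- detect_collinear_blocks(anchors, min_anchors = m)
    calls <- classify_duplications(ranks, hits, blocks)
    sum(calls$class == "wgd_segmental")
  }, numeric(1))
  expect_true(all(diff(n_wgd) <= 0))
})

test_that("classification follows the documented precedence", {
  loci <- mkloci(data.frame(id = c("a", "b", "c", "d"),
                            chr = "c1", s = c(100L, 300L, 2500L, 9900L)))
  ranks <- assign_gene_ranks(loci)
  # a-b adjacent near-identical pair; d has no hits
  hits <- tibble::tibble(query_id = c("a", "b", "a"),
                         subject_id = c("b", "a", "c"),
                         identity = 95, align_length = 100L,
                         mismatches = NA_integer_, gap_opens = NA_integer_,
                         qstart = NA_integer_, qend = NA_integer_,
                         sstart = NA_integer_, send = NA_integer_,
                         evalue = 1e-30, bitscore = c(300, 300, 200),
                         query_cov = 100, subject_cov = 100)
  calls <- classify_duplications(ranks, hits, blocks = NULL,
                                 proximal_window = 10)
  cls <- setNames(as.character(calls$class), calls$gene_id)
  expect_equal(cls[["a"]], "tandem")
  expect_equal(cls[["b"]], "tandem")
  expect_equal(cls[["c"]], "proximal")   # rank distance 2 from a
  expect_equal(cls[["d"]], "singleton")

  # genes with hits but no locus are unassigned
  hits2 <- dplyr::bind_rows(hits, tibble::tibble(
    query_id = "ghost", subject_id = "a", identity = 90,
    align_length = 100L, mismatches = NA_integer_, gap_opens = NA_integer_,
    qstart = NA_integer_, qend = NA_integer_, sstart = NA_integer_,
    send = NA_integer_, evalue = 1e-30, bitscore = 250, query_cov = 100,
    subject_cov = 100))
  calls2 <- classify_duplications(ranks, hits2, blocks = NULL)
  expect_equal(as.character(calls2$class[calls2$gene_id == "ghost"]),
               "unassigned")
})

test_that("a lossless WGD marks every gene wgd_segmental", {
  ds <- simulate_genome(simulation_config(
    seed = 5, n_chromosomes = 1, genes_per_chromosome = 25,
    wgd_rounds = list(c(ds = 0.05, loss = 0)), tandem_rate = 0,
    proximal_rate = 0, dispersed_rate = 0, substitution_rate = 0.01))
  hits <- all_vs_all(ds$proteins)
  ranks <- assign_gene_ranks(ds$loci)
  anchors <- make_anchor_pairs(hits, ranks)
  blocks <- detect_collinear_blocks(anchors)
  calls <- classify_duplications(ranks, hits, blocks)
  expect_true(all(calls$class == "wgd_segmental"))
  expect_true(all(ds$truth$duplication_class == "wgd_segmental"))
})

test_that("duplication summaries reproduce published row totals", {
  expand_calls <- function(species, counts) {
    tibble::tibble(
      gene_id = paste0(species, seq_len(sum(counts))),
      species = species,
      class = rep(duplication_classes(), counts))
  }
  at <- duplication_summary(expand_calls("Arabidopsis thaliana",
                                         c(78, 307, 20, 57, 295, 0)))
  expect_equal(at$total, 757)
  gm <- duplication_summary(expand_calls("Gossypium mustelinum",
                                         c(0, 89, 27, 21, 1804, 5)))
  expect_equal(gm$total, 1946)
  expect_equal(gm$wgd_segmental, 1804L)

  empty <- duplication_summary(
    tibble::tibble(gene_id = character(), species = character(),
                   class = character()))
  expect_equal(empty$total, 0)
})
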