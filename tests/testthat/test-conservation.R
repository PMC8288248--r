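test_that("progressive alignment handles identical, indel and permuted inputs", {
  two <- progressive_msa(c(a = "MKAVLWQ", b = "MKAVLWQ"))
  expect_false(any(grepl("-", two$rows)))

  three <- progressive_msa(c(x = "MKAVLWQ", y = "MKAVLWQ", z = "MKALWQ"))
  gap_cols <- sum(vapply(seq_len(three$column_count), function(j) {
    any(substr(three$rows, j, j) == "-")
  }, logical(1)))
  expect_equal(gap_cols, 1L)
  expect_equal(gsub("-", "", three$rows[3]), "MKALWQ")

  seqs <- c(x = "MKAVLWQ", y = "MKAVLWQ", z = "MKALWQ")
  permuted <- progressive_msa(seqs[c(3, 1, 2)])
  expect_equal(permuted$rows, three$rows)
  expect_equal(permuted$member_ids, three$member_ids)

  expect_error(progressive_msa(c(a = "MK")), "at least 2")
})

test_that("conservation scores follow the modal-residue definition", {
  identical3 <- multiple_alignment(c("a", "b", "c"),
                                   rep(strrep("MKAVLWQRTY", 1), 3))
  prof <- conservation_profile(identical3)
  expect_equal(prof$family_score, 100)
  expect_true(all(prof$per_gene_scores == 100))

  # one differing residue among 3 rows x 10 columns
  rows <- c("MKAVLWQRTY", "MKAVLWQRTY", "MKAVLWQRTW")
  prof2 <- conservation_profile(multiple_alignment(c("a", "b", "c"), rows))
  expect_equal(prof2$column_scores[10], 2 / 3)
  expect_equal(prof2$family_score, mean(c(rep(1, 9), 2 / 3)) * 100)
  expect_equal(round(prof2$family_score, 2), 96.67)

  expect_error(conservation_profile(
    multiple_alignment(c("a", "b"), c("MK", "MK"))), "at least 3")
})

test_that("family scores are invariant to row order and never drop with clones", {
  rows <- c("MKAVLWQRTY", "MKAVLWQRTY", "MKAVLWQRTW", "MKALLWQRTY")
  ids <- c("a", "b", "c", "d")
  base <- conservation_profile(multiple_alignment(ids, rows))
  perm <- sample(4)
  shuffled <- conservation_profile(multiple_alignment(ids[perm], rows[perm]))
  expect_equal(base$family_score, shuffled$family_score)
  expect_equal(sort(names(base$per_gene_scores)),
               sort(names(shuffled$per_gene_scores)))

  cloned <- conservation_profile(
    multiple_alignment(c(ids, "e"), c(rows, rows[1])))
  expect_gte(cloned$family_score, base$family_score)
  expect_true(all(base$column_scores >= 0 & base$column_scores <= 1))
})

test_that("length variation profiles retain the documented fractions", {
  all_ref <- length_variation_profile(rep(100, 5), 100)
  expect_true(all(all_ref$retained_fraction == 1))

  lv <- length_variation_profile(c(90, 100, 110), 100, cutoffs = 0.05)
  expect_equal(lv$retained_fraction, 1 / 3)

  sweep <- length_variation_profile(c(80, 95, 100, 118), 100)
  expect_true(all(diff(sweep$retained_fraction) >= 0))
})

test_that("profile clustering recovers archetypes and labels by variability", {
  cutoffs <- c(0.01, 0.05, 0.1, 0.2)
  flat <- lapply(1:4, function(i) length_variation_profile(
    rep(100, 6), 100, cutoffs, family_id = paste0("flat", i)))
  varying <- lapply(1:4, function(i) length_variation_profile(
    c(60, 80, 100, 120, 140, 150) + i, 100, cutoffs,
    family_id = paste0("var", i)))
  profiles <- dplyr::bind_rows(c(flat, varying))
  cl <- cluster_length_profiles(profiles, k = 2)
  expect_equal(length(unique(cl$cluster[grepl("flat", cl$family_id)])), 1L)
  expect_equal(length(unique(cl$cluster[grepl("var", cl$family_id)])), 1L)
  # cluster 1 is the most variable archetype
  expect_true(all(cl$cluster[grepl("var", cl$family_id)] == 1L))
  expect_true(all(cl$cluster[grepl("flat", cl$family_id)] == 2L))

  # identical profiles share one cluster
  same <- dplyr::bind_rows(lapply(1:5, function(i) length_variation_profile(
    rep(100, 3), 100, cutoffs, family_id = paste0("s", i))))
  cl_same <- cluster_length_profiles(same, k = 3)
  expect_equal(length(unique(cl_same$cluster)), 1L)

  expect_error(cluster_length_profiles(profiles, k = 20), "at least")
})

test_that("conservation filtering is strictly greater-than", {
  scores <- tibble::tibble(family_id = c("a", "b", "c"),
                           family_score = c(50, 96.67, 12))
  kept <- filter_by_conservation(scores, 50)
  expect_equal(kept$family_id, "b")
  expect_equal(nrow(filter_by_conservation(scores[0, ], 50)), 0L)
})

test_that("aligned FASTA round-trips through the readers", {
  msa <- progressive_msa(c(x = "MKAVLWQ", y = "MKAVLWQ", z = "MKALWQ"))
  path <- tempfile(fileext = ".fasta")
  write_alignment_fasta(msa, path)
  back <- read_alignment_fasta(path)
  expect_equal(back$rows, msa$rows)
  expect_equal(back$member_ids, msa$member_ids)
})
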