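mkhits <- function(...) {
  rows <- list(...)
  tibble::tibble(
    accession = vapply(rows, `[[`, character(1), 1),
    start = vapply(rows, function(r) as.integer(r[[2]]), integer(1)),
    end = vapply(rows, function(r) as.integer(r[[3]]), integer(1)),
    evalue = 1e-20)
}

test_that("architecture_of orders, merges and validates hits", {
  expect_equal(architecture_of(mkhits(list("IPR1", 5, 40), list("IPR2", 50, 90))),
               c("IPR1", "IPR2"))
  # same-accession overlap merges to one
  expect_equal(architecture_of(mkhits(list("IPR1", 5, 40), list("IPR1", 30, 80))),
               "IPR1")
  # overlapping hits of different accessions both kept, ordered by start
  expect_equal(architecture_of(mkhits(list("IPR2", 10, 60), list("IPR1", 5, 40))),
               c("IPR1", "IPR2"))
  expect_equal(architecture_of(NULL), character(0))
  expect_error(architecture_of(mkhits(list("IPR1", 5, 40)), protein_length = 30),
               "exceeds")
})

test_that("match_architecture is exact ordered equality", {
  expect_true(match_architecture(c("A", "B"), c("A", "B")))
  expect_false(match_architecture(c("B", "A"), c("A", "B")))
  expect_false(match_architecture("A", c("A", "B")))
  expect_error(match_architecture("A", character(0)), "non-empty")
})

test_that("length filter keeps the 90%-110% window inclusively", {
  expect_true(length_filter(95, 100))
  expect_false(length_filter(89, 100))
  expect_false(length_filter(111, 100))
  expect_true(length_filter(110, 100))
  expect_true(length_filter(90, 100))
  expect_error(length_filter(0, 100), "positive")
})

test_that("identification recovers planted families exactly at zero divergence", {
  ds <- simulate_genome(simulation_config(
    seed = 21, n_chromosomes = 2, genes_per_chromosome = 30,
    substitution_rate = 0, wgd_rounds = list(c(ds = 0, loss = 0.3))))
  subtypes <- build_subtypes(ds$reference)
  cand <- identify_family_members(subtypes, ds$proteins, ds$domain_hits)
  metrics <- identification_metrics(cand, ds$truth)
  expect_equal(metrics$precision, 1)
  expect_equal(metrics$recall, 1)
})

test_that("non-matching architectures are absent and truncation fails the filter", {
  ds <- small_dataset()
  subtypes <- build_subtypes(ds$reference)
  # foreign protein with an unknown architecture
  proteome <- dplyr::bind_rows(
    ds$proteins,
    tibble::tibble(id = "alien", species = "synthetica",
                   sequence = strrep("MKWQ", 75), length = 300L))
  hits <- dplyr::bind_rows(
    ds$domain_hits,
    tibble::tibble(protein_id = "alien", accession = "IPR777777",
                   start = 10L, end = 60L, evalue = 1e-10))
  cand <- identify_family_members(subtypes, proteome, hits)
  expect_false("alien" %in% cand$protein_id)

  # a paralog truncated to 60% of the reference length stays a candidate
  # but fails the length filter
  victim <- cand$protein_id[1]
  idx <- match(victim, proteome$id)
  keep <- floor(proteome$length[idx] * 0.6)
  proteome$sequence[idx] <- substr(proteome$sequence[idx], 1, keep)
  proteome$length[idx] <- keep
  hits2 <- hits[!(hits$protein_id == victim & hits$start > keep), ]
  hits2$end[hits2$protein_id == victim] <-
    pmin(hits2$end[hits2$protein_id == victim], keep)
  cand2 <- identify_family_members(subtypes, proteome, hits2)
  row <- cand2[cand2$protein_id == victim, ]
  if (nrow(row) == 1L) {           # architecture may change if a domain is cut
    expect_false(row$passed_length_filter)
  }
  expect_gte(nrow(cand2), sum(cand2$passed_length_filter))
})

test_that("identification does not depend on input ordering", {
  ds <- small_dataset()
  subtypes <- build_subtypes(ds$reference)
  cand1 <- identify_family_members(subtypes, ds$proteins, ds$domain_hits)
  perm <- sample(nrow(ds$proteins))
  cand2 <- identify_family_members(subtypes, ds$proteins[perm, ],
                                   ds$domain_hits)
  expect_equal(cand1, cand2)
})

test_that("coverage classes follow domain count and coverage", {
  subtypes <- tibble::tibble(
    subtype_id = c("S1", "S2"),
    architecture = list(c("IPR1", "IPR2"), "IPR3"),
    architecture_key = c("IPR1|IPR2", "IPR3"),
    members = list(tibble::tibble(symbol = "S1", protein_id = "S1",
                                  length = 100L),
                   tibble::tibble(symbol = "S2", protein_id = "S2",
                                  length = 100L)),
    n_members = 1L, matchable = TRUE)
  proteome <- tibble::tibble(id = c("x", "y", "z"), species = "sp",
                             sequence = strrep("M", 100), length = 100L)
  hits <- tibble::tibble(
    protein_id = c("x", "x", "y", "z"),
    accession = c("IPR1", "IPR2", "IPR3", "IPR3"),
    start = c(1L, 60L, 1L, 1L), end = c(40L, 100L, 60L, 20L),
    evalue = 1e-10)
  cand <- identify_family_members(subtypes, proteome, hits)
  expect_equal(cand$coverage_class[match(c("x", "y", "z"), cand$protein_id)],
               c("multi_domain", "single_high", "single_low"))
})
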