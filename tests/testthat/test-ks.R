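test_that("back-translation maps residues to codons and gaps to ---", {
  msa <- multiple_alignment(c("x", "y"), c("MKV", "MKV"))
  cds <- tibble::tibble(id = c("x", "y"),
                        sequence = c("ATGAAAGTT", "ATGAAAGTG"))
  ca <- back_translate(msa, cds)
  expect_equal(nchar(ca$rows), c(9L, 9L))
  expect_equal(ca$rows[1], "ATGAAAGTT")

  gapped <- multiple_alignment(c("x", "y"), c("MKV", "M-V"))
  cds2 <- tibble::tibble(id = c("x", "y"), sequence = c("ATGAAAGTT", "ATGGTG"))
  ca2 <- back_translate(gapped, cds2)
  expect_equal(ca2$rows[2], "ATG---GTG")

  bad <- tibble::tibble(id = c("x", "y"),
                        sequence = c("ATGAAAGTT", "CCCGTG"))  # P != M
  expect_error(back_translate(gapped, bad), "residue 1|mismatch")
  short <- tibble::tibble(id = c("x", "y"),
                          sequence = c("ATGAAAGT", "ATGGTG"))
  expect_error(back_translate(multiple_alignment("x", "MKV"), short),
               "divisible by 3")
})

test_that("NG86 counts match the enumerated single-codon cases", {
  same <- ng86_sites_and_differences("ATGAAA", "ATGAAA")
  expect_equal(same$syn_diffs, 0)
  expect_equal(same$nonsyn_diffs, 0)

  ggg <- ng86_sites_and_differences("GGG", "GGG")
  expect_equal(ggg$syn_sites, 1)      # third position fully synonymous

  ttt <- ng86_sites_and_differences("TTT", "TTC")
  expect_equal(ttt$syn_sites, 1 / 3)
  expect_equal(ttt$syn_diffs, 1)

  expect_error(ng86_sites_and_differences("ATG", "ATGAAA"), "length")
})

test_that("gap and stop codon columns are skipped pairwise", {
  counts <- ng86_sites_and_differences("ATG---AAA", "ATGGGGAAA")
  expect_equal(counts$n_codons, 2L)
  with_stop <- ng86_sites_and_differences("ATGTAAAAA", "ATGGGGAAA")
  expect_equal(with_stop$n_codons, 2L)
})

test_that("the Jukes-Cantor correction reproduces the worked example", {
  a <- paste0(strrep("GGG", 9), "TTT")
  b <- paste0(strrep("GGG", 9), "TTC")
  est <- ks_pair(a, b)
  expect_equal(est$syn_sites, 28 / 3)
  expect_equal(est$syn_diffs, 1)
  expect_equal(est$pS, 3 / 28, tolerance = 1e-9)
  expect_equal(est$ks, 0.1156, tolerance = 1e-3)

  zero <- ks(list(syn_sites = 10, nonsyn_sites = 20, syn_diffs = 0,
                  nonsyn_diffs = 0))
  expect_equal(zero$ks, 0)

  saturated <- ks(list(syn_sites = 10, nonsyn_sites = 20, syn_diffs = 7.5,
                       nonsyn_diffs = 0))
  expect_true(is.na(saturated$ks))
  expect_match(saturated$note, "saturation")

  no_sites <- ks(list(syn_sites = 0, nonsyn_sites = 0, syn_diffs = 0,
                      nonsyn_diffs = 0))
  expect_true(is.na(no_sites$ks))
})

test_that("ks is symmetric, zero on identity, and monotone in pS", {
  set.seed(61)
  codons <- sense_codons()
  a <- paste(sample(codons, 30, replace = TRUE), collapse = "")
  b <- paste(sample(codons, 30, replace = TRUE), collapse = "")
  expect_equal(ks_pair(a, b)$ks, ks_pair(b, a)$ks)
  expect_equal(ks_pair(a, a)$ks, 0)

  ps_grid <- seq(0.02, 0.7, by = 0.05)
  ks_grid <- vapply(ps_grid, function(p) {
    ks(list(syn_sites = 100, nonsyn_sites = 200, syn_diffs = 100 * p,
            nonsyn_diffs = 0))$ks
  }, numeric(1))
  expect_true(all(diff(ks_grid) > 0))
})

test_that("within-family pairs enumerate correctly", {
  set.seed(71)
  codons <- sense_codons()
  base <- sample(codons, 50, replace = TRUE)
  cds <- vapply(1:3, function(i) paste(base, collapse = ""), character(1))
  gc_map <- Biostrings::GENETIC_CODE
  prot <- paste(gc_map[base], collapse = "")
  fams <- tibble::tibble(gene_id = c("x", "y", "z", "w"),
                         family_id = c("f", "f", "f", "lonely"))
  proteins <- tibble::tibble(id = c("x", "y", "z", "w"),
                             sequence = c(prot, prot, prot, prot),
                             length = nchar(prot))
  cds_tbl <- tibble::tibble(id = c("x", "y", "z", "w"),
                            sequence = c(cds, cds[1]))
  out <- pairwise_ks_for_families(fams, proteins, cds_tbl)
  expect_equal(nrow(out), 3L)           # family of 3 -> 3 pairs, singleton -> 0
  expect_true(all(out$ks == 0))
})
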