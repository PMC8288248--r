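test_that("protein FASTA reading handles records, stops and empty files", {
  path <- write_temp_fasta(list(p1 = "MKAVLLQ", p2 = c("MKV", "AAQ")))
  rec <- read_protein_fasta(path, species = "sp")
  expect_equal(rec$id, c("p1", "p2"))
  expect_equal(rec$length, c(7L, 6L))
  expect_equal(rec$species, c("sp", "sp"))

  stop_path <- write_temp_fasta(list(p3 = "MKV*"))
  expect_equal(read_protein_fasta(stop_path)$length, 3L)

  empty <- tempfile()
  writeLines(character(0), empty)
  expect_equal(nrow(read_protein_fasta(empty)), 0L)

  bad <- tempfile()
  writeLines(c("MKV", ">p1"), bad)
  expect_error(read_protein_fasta(bad), "line 1")
})

test_that("FASTA writing round-trips records exactly", {
  rec <- tibble::tibble(id = c("a", "b"),
                        sequence = c(strrep("MKAVWQERTY", 13), "MW"))
  path <- tempfile(fileext = ".fasta")
  write_fasta(rec, path)
  back <- read_protein_fasta(path)
  expect_equal(back$id, rec$id)
  expect_equal(back$sequence, rec$sequence)
})

test_that("clean_proteome removes internal stops and redundant sequences", {
  rec <- tibble::tibble(id = c("bad", "good"), sequence = c("MK*V", "MKAV"))
  expect_equal(clean_proteome(rec)$id, "good")

  dup <- tibble::tibble(id = c("x", "y"), sequence = c("MKAV", "MKAV"))
  expect_equal(nrow(clean_proteome(dup)), 1L)

  expect_error(clean_proteome(dup, redundancy_identity = 0), "0, 1")
  expect_error(clean_proteome(dup, redundancy_identity = 1.5), "0, 1")
})

test_that("redundancy clustering thresholds behave like global identity", {
  a <- "MKAVLLQWERTY"                 # 12 aa
  b <- "MKAVLLQWERTF"                 # 1 substitution: 11/12 = 91.7%
  rec <- tibble::tibble(id = c("a", "b"), sequence = c(a, b))
  expect_equal(nrow(clean_proteome(rec, 0.90)), 1L)
  expect_equal(nrow(clean_proteome(rec, 0.95)), 2L)
})

test_that("clean_proteome is idempotent and keeps the longest of a cluster", {
  set.seed(5)
  recs <- tibble::tibble(
    id = paste0("p", 1:6),
    sequence = c("MKAVLLQWERTY", "MKAVLLQWERTY", "MKAVLLQWER",
                 random_protein(30), random_protein(30), "MK*AV"))
  once <- clean_proteome(recs, 0.9)
  twice <- clean_proteome(once, 0.9)
  expect_identical(once, twice)
  # the longest member of every redundancy cluster survives
  expect_true("p1" %in% once$id || "p2" %in% once$id)
  expect_true(max(nchar(once$sequence)) == max(nchar(recs$sequence[1:5])))
})

test_that("gene model reading sorts loci and validates the file", {
  path <- write_temp_gff3(toy_gff3_rows())
  loci <- read_gene_models(path, species = "sp")
  expect_equal(loci$gene_id, c("gA", "gB", "gC"))  # mRNA ignored
  expect_equal(loci$chromosome, c("chr1", "chr1", "chr2"))
  expect_true(all(diff(loci$start[loci$chromosome == "chr1"]) > 0))

  bad <- write_temp_gff3("chr1\ttest\tgene\t500\t100\t.\t+\t.\tID=gX")
  expect_error(read_gene_models(bad), "end < start")
  noid <- write_temp_gff3("chr1\ttest\tgene\t1\t10\t.\t+\t.\tName=gX")
  expect_error(read_gene_models(noid), "ID attribute")
})

test_that("gene model writing round-trips", {
  path <- write_temp_gff3(toy_gff3_rows())
  loci <- read_gene_models(path, species = "sp")
  out <- tempfile(fileext = ".gff3")
  write_gene_models(loci, out)
  expect_equal(read_gene_models(out, species = "sp"), loci)
})

test_that("domain annotation reading follows the InterProScan dialect", {
  mkrow <- function(id, acc, s, e, ev = "1e-20") {
    paste(c(id, "md5", "500", "Pfam", "PF1", "desc", s, e, ev, "T",
            "2020-01-01", acc, "name", "desc2", "-"), collapse = "\t")
  }
  path <- tempfile()
  writeLines(c(mkrow("p1", "IPR000001", 5, 40),
               mkrow("p1", "IPR000002", 50, 90),
               mkrow("p2", "-", 1, 10),           # no IPR accession
               mkrow("p1", "IPR000001", 5, 40)), path)
  hits <- read_domain_annotations(path)
  expect_equal(nrow(hits), 2L)                    # skipped + deduplicated
  expect_equal(hits$accession, c("IPR000001", "IPR000002"))

  bad <- tempfile()
  writeLines(mkrow("p1", "IPR000001", "x", 40), bad)
  expect_error(read_domain_annotations(bad), "non-numeric")
})

test_that("similarity tables parse the 12-column dialect", {
  row1 <- "q1\ts1\t85.5\t100\t14\t1\t1\t100\t5\t104\t1e-30\t180"
  path <- tempfile()
  writeLines(row1, path)
  tbl <- read_similarity_table(path)
  expect_equal(nrow(tbl), 1L)
  expect_equal(tbl$identity, 85.5)
  expect_true(is.na(tbl$query_cov))

  with_len <- read_similarity_table(path, query_lengths = c(q1 = 200),
                                    subject_lengths = c(s1 = 100))
  expect_equal(with_len$query_cov, 50)
  expect_equal(with_len$subject_cov, 100)

  selfhit <- tempfile()
  writeLines("q1\tq1\t100\t100\t0\t0\t1\t100\t1\t100\t0\t200", selfhit)
  expect_equal(nrow(read_similarity_table(selfhit)), 1L)  # kept, filtered downstream

  bad <- tempfile()
  writeLines("q1\ts1\t85.5", bad)
  expect_error(read_similarity_table(bad), "12 expected")
})
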