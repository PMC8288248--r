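# Small fixture builders shared across test files.

write_temp_fasta <- function(records, ext = ".fasta") {
  path <- tempfile(fileext = ext)
  writeLines(unlist(lapply(seq_along(records), function(i) {
    c(paste0(">", names(records)[i]), records[[i]])
  })), path)
  path
}

write_temp_gff3 <- function(rows, header = "##gff-version 3") {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(header, rows), path)
  path
}

toy_gff3_rows <- function() {
  c("chr1\ttest\tgene\t100\t400\t.\t+\t.\tID=gA",
    "chr1\ttest\tmRNA\t100\t400\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\ttest\tgene\t1000\t1300\t.\t-\t.\tID=gB",
    "chr2\ttest\tgene\t50\t200\t.\t+\t.\tID=gC")
}

# A tiny planted two-family dataset used by several similarity tests.
two_family_proteins <- function() {
  set.seed(99)
  base1 <- random_protein(120)
  base2 <- random_protein(120)
  mutate_seq <- function(s, n_sub) {
    v <- strsplit(s, "")[[1]]
    pos <- sample(seq_along(v), n_sub)
    for (p in pos) v[p] <- sample(setdiff(c("A","R","N","D","C","Q","E","G",
                                            "H","I","L","K","M","F","P","S",
                                            "T","W","Y","V"), v[p]), 1)
    paste(v, collapse = "")
  }
  tibble::tibble(
    id = c("f1a", "f1b", "f1c", "f2a", "f2b"),
    sequence = c(base1, mutate_seq(base1, 10), mutate_seq(base1, 12),
                 base2, mutate_seq(base2, 10)))
}

extdata <- function(name) {
  system.file("extdata", name, package = "polyflor", mustWork = TRUE)
}

# Small synthetic genome reused by several suites (cached per test run).
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_genome(simulation_config(
        seed = 11, n_chromosomes = 2, genes_per_chromosome = 40))
    }
    cache
  }
})
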