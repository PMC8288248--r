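simrec <- function(q, s, identity = 90, score = 200, evalue = 1e-30,
                   qc = 95, sc = 95) {
  tibble::tibble(query_id = q, subject_id = s, identity = identity,
                 align_length = 100L, mismatches = NA_integer_,
                 gap_opens = NA_integer_, qstart = NA_integer_,
                 qend = NA_integer_, sstart = NA_integer_,
                 send = NA_integer_, evalue = evalue, bitscore = score,
                 query_cov = qc, subject_cov = sc)
}

test_that("edges require reciprocity and exclude self-hits", {
  mutual <- dplyr::bind_rows(simrec("a", "b"), simrec("b", "a"))
  net <- build_network(mutual)
  expect_equal(nrow(net$edges), 1L)

  oneway <- simrec("a", "b")
  expect_equal(nrow(build_network(oneway)$edges), 0L)
  expect_equal(nrow(build_network(oneway, reciprocal = FALSE)$edges), 1L)

  selfy <- dplyr::bind_rows(simrec("a", "a"), simrec("a", "b"),
                            simrec("b", "a"))
  net2 <- build_network(selfy)
  expect_equal(nrow(net2$edges), 1L)
  expect_false(any(net2$edges$from == net2$edges$to))
})

test_that("components are deterministic groups keyed by smallest member", {
  clique <- dplyr::bind_rows(lapply(c("a", "b", "c", "d"), function(x) {
    dplyr::bind_rows(lapply(setdiff(c("a", "b", "c", "d"), x),
                            function(y) simrec(x, y)))
  }))
  groups <- network_components(build_network(clique))
  expect_equal(nrow(groups), 1L)
  expect_equal(groups$group_id, "a")
  expect_equal(groups$n_members, 4L)
  expect_true(groups$major)

  empty <- build_network(simrec("a", "b")[0, ])
  expect_equal(nrow(network_components(empty)), 0L)
})

test_that("planted families split into separate components", {
  p <- two_family_proteins()
  hits <- all_vs_all(p, min_score = 50)
  net <- build_network(hits, id_min = 60, cov_min = 60)
  groups <- network_components(net)
  expect_equal(nrow(groups), 2L)
  expect_setequal(groups$members[[match("f1a", groups$group_id)]],
                  c("f1a", "f1b", "f1c"))
  expect_setequal(groups$members[[match("f2a", groups$group_id)]],
                  c("f2a", "f2b"))
})

test_that("component counts never grow as thresholds tighten is inverted", {
  p <- two_family_proteins()
  hits <- all_vs_all(p, min_score = 30)
  thresholds <- c(90, 75, 60, 40, 0)
  n_comp <- vapply(thresholds, function(idm) {
    nrow(network_components(build_network(hits, id_min = idm, cov_min = 60,
                                          nodes = p$id)))
  }, numeric(1))
  # relaxing identity can only merge components
  expect_true(all(diff(n_comp) <= 0))
})

test_that("networks are invariant to record order", {
  p <- two_family_proteins()
  hits <- all_vs_all(p, min_score = 50)
  net1 <- build_network(hits)
  net2 <- build_network(hits[sample(nrow(hits)), ])
  expect_equal(net1$edges, net2$edges)
  expect_equal(net1$nodes, net2$nodes)
})

test_that("group statistics average lengths and tally duplication classes", {
  groups <- tibble::tibble(group_id = "a", members = list(c("a", "b")),
                           n_members = 2L, major = FALSE)
  prot <- tibble::tibble(id = c("a", "b"), length = c(100L, 200L))
  calls <- tibble::tibble(gene_id = "a", species = "sp",
                          class = "wgd_segmental")
  st <- group_stats(groups, prot, calls)
  expect_equal(st$mean_length, 150)
  dist <- st$duplication_distribution[[1]]
  expect_equal(unname(dist[["wgd_segmental"]]), 1L)
  expect_equal(unname(dist[["unassigned"]]), 1L)   # member without a call

  expect_error(group_stats(groups, prot[1, ], calls), "without a protein length")
})

test_that("network exports are readable text formats", {
  mutual <- dplyr::bind_rows(simrec("a", "b"), simrec("b", "a"))
  net <- build_network(mutual)
  edge_path <- tempfile(fileext = ".tsv")
  write_network_edgelist(net, edge_path)
  back <- readr::read_tsv(edge_path, show_col_types = FALSE)
  expect_equal(nrow(back), 1L)

  gml_path <- tempfile(fileext = ".graphml")
  write_network_graphml(net, gml_path)
  expect_true(any(grepl("graphml", readLines(gml_path, n = 3))))
})
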