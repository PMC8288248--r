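#' Load a reference flowering-time gene catalog
#'
#' The catalog is a TSV with columns `symbol`, `category`, `subcategory`
#' (may be empty) and `protein_id` (may be empty when no sequence resource is
#' attached), one row per (symbol, category) membership: curated catalogs in
#' the FLOR-ID tradition list some genes under several functional categories.
#' When `proteins` (and optionally `hits`) are supplied, each symbol's protein
#' sequence, length, and domain architecture are attached; a symbol whose
#' `protein_id` has no sequence is a load error, and symbols without any
#' domain hit get an empty architecture with a warning.
#'
#' @param path path to the catalog TSV (header required).
#' @param proteins optional protein tibble (from [read_protein_fasta()]).
#' @param hits optional domain-hit tibble (from [read_domain_annotations()]).
#' @return tibble with one row per membership, carrying `symbol`, `category`,
#'   `subcategory`, `protein_id` and - when sequences are attached -
#'   `sequence`, `length`, `architecture` (list of character vectors) and
#'   `architecture_key`.
#' @export
load_reference_catalog <- function(path, proteins = NULL, hits = NULL) {
  if (!file.exists(path)) stopf("catalog file not found: %s", path)
  cat_tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                             progress = FALSE)
  check_columns(cat_tbl, c("symbol", "category"), "catalog")
  if (!"subcategory" %in% names(cat_tbl)) cat_tbl$subcategory <- ""
  if (!"protein_id" %in% names(cat_tbl)) cat_tbl$protein_id <- cat_tbl$symbol
  cat_tbl$subcategory[is.na(cat_tbl$subcategory)] <- ""
  dup <- duplicated(cat_tbl[, c("symbol", "category", "subcategory")])
  if (any(dup)) {
    stopf("duplicate catalog membership for symbol '%s'", cat_tbl$symbol[dup][1])
  }
  out <- as_tibble(cat_tbl[, c("symbol", "category", "subcategory", "protein_id")])
  if (is.null(proteins)) return(out)

  check_columns(proteins, c("id", "sequence", "length"), "proteins")
  idx <- match(out$protein_id, proteins$id)
  if (anyNA(idx)) {
    stopf("catalog symbol '%s' has no protein sequence (protein_id '%s')",
          out$symbol[is.na(idx)][1], out$protein_id[is.na(idx)][1])
  }
  out$sequence <- proteins$sequence[idx]
  out$length <- proteins$length[idx]
  arch <- architectures_for(out$protein_id, out$length, hits)
  out$architecture <- arch
  out$architecture_key <- vapply(arch, architecture_key, character(1))
  no_dom <- unique(out$symbol[lengths(arch) == 0L])
  if (length(no_dom) > 0L) {
    rlang::warn(sprintf("%d reference gene(s) without domain hits (empty architecture): %s",
                        length(no_dom), paste(head(no_dom, 5), collapse = ", ")))
  }
  out
}

architectures_for <- function(protein_ids, lengths, hits) {
  if (is.null(hits)) return(rep(list(character(0)), length(protein_ids)))
  split_hits <- split(hits, hits$protein_id)
  lapply(seq_along(protein_ids), function(i) {
    h <- split_hits[[protein_ids[i]]]
    if (is.null(h)) return(character(0))
    architecture_of(h, protein_length = lengths[i])
  })
}

#' Partition reference genes into architecture subtypes
#'
#' Distinct symbols are grouped by exact equality of their ordered domain
#' architectures. The subtype id is the lexicographically smallest member
#' symbol. Symbols with an empty architecture are collected into one
#' `no-domain` subtype that is flagged non-matchable (and excluded from
#' candidate matching) with a warning.
#'
#' @param refgenes catalog tibble from [load_reference_catalog()] with
#'   architectures attached.
#' @return tibble with one row per subtype: `subtype_id`, `architecture`
#'   (character-vector list column), `architecture_key`, `members` (list of
#'   tibbles with `symbol`, `protein_id`, `length`), `n_members`, `matchable`.
#' @export
build_subtypes <- function(refgenes) {
  check_columns(refgenes, c("symbol", "architecture_key"), "refgenes")
  genes <- refgenes |>
    distinct(.data$symbol, .keep_all = TRUE) |>
    select("symbol", "protein_id", "length", "architecture", "architecture_key")
  if (any(genes$architecture_key == "")) {
    rlang::warn(sprintf("%d reference gene(s) have no domain architecture; grouped into a non-matchable 'no-domain' subtype",
                        sum(genes$architecture_key == "")))
  }
  grouped <- split(genes, genes$architecture_key)
  rows <- lapply(grouped, function(g) {
    g <- arrange(g, .data$symbol)
    tibble(subtype_id = if (g$architecture_key[1] == "") "no-domain" else g$symbol[1],
           architecture = list(g$architecture[[1]]),
           architecture_key = g$architecture_key[1],
           members = list(select(g, "symbol", "protein_id", "length")),
           n_members = nrow(g),
           matchable = g$architecture_key[1] != "")
  })
  arrange(bind_rows(rows), .data$subtype_id)
}

#' Per-category gene counts of a reference catalog
#'
#' One row per (category, subcategory) membership group; `count` is the
#' number of distinct symbols in the group and `symbols` lists them sorted.
#' Because catalogs may list a gene under several categories, the counts may
#' sum to more than the number of distinct symbols.
#'
#' @param refgenes catalog tibble from [load_reference_catalog()].
#' @return tibble with `category`, `subcategory`, `count`, `symbols`
#'   (list column of sorted character vectors).
#' @export
category_summary <- function(refgenes) {
  check_columns(refgenes, c("symbol", "category", "subcategory"), "refgenes")
  if (nrow(refgenes) == 0L) {
    return(tibble(category = character(), subcategory = character(),
                  count = integer(), symbols = list()))
  }
  refgenes |>
    group_by(.data$category, .data$subcategory) |>
    summarise(symbols = list(sort(unique(.data$symbol))), .groups = "drop") |>
    mutate(count = lengths(.data$symbols)) |>
    select("category", "subcategory", "count", "symbols") |>
    arrange(.data$category, .data$subcategory)
}
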