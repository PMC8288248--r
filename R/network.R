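#' Build a reciprocal sequence-similarity network
#'
#' Nodes are protein ids seen in the similarity records (plus any in
#' `nodes`); an edge joins two proteins when qualifying hits exist in both
#' directions (reciprocity; set `reciprocal = FALSE` to accept one
#' direction). A hit qualifies when identity is strictly above `id_min`,
#' both coverages are strictly above `cov_min` (missing coverages pass), and
#' the E-value is at most `evalue_max` when present, otherwise the score is
#' at least `min_score`. Self-hits are discarded. Edge attributes average
#' the two directions' identity and take the best score.
#'
#' @param records similarity tibble ([all_vs_all()] or
#'   [read_similarity_table()]).
#' @param id_min identity threshold in percent.
#' @param cov_min coverage threshold in percent.
#' @param evalue_max E-value threshold for hits with E-values.
#' @param min_score score threshold for hits without E-values.
#' @param reciprocal require hits in both directions.
#' @param nodes optional character vector of node ids to include even when
#'   isolated.
#' @return an object of class `similarity_network`: list with `nodes` and
#'   `edges` tibbles.
#' @export
build_network <- function(records, id_min = 60, cov_min = 60,
                          evalue_max = 1e-10, min_score = 50,
                          reciprocal = TRUE, nodes = NULL) {
  all_ids <- sort(unique(c(records$query_id, records$subject_id, nodes)))
  if (nrow(records) > 0L) {
    h <- records[records$query_id != records$subject_id, , drop = FALSE]
    ev <- h$evalue %||% rep(NA_real_, nrow(h))
    qual <- h$identity > id_min &
      (is.na(h$query_cov %||% NA_real_) | h$query_cov > cov_min) &
      (is.na(h$subject_cov %||% NA_real_) | h$subject_cov > cov_min) &
      ifelse(is.na(ev), h$bitscore >= min_score, ev <= evalue_max)
    h <- h[qual, , drop = FALSE]
  } else {
    h <- records
  }
  edges <- tibble(from = character(), to = character(), identity = double(),
                  score = double())
  if (nrow(h) > 0L) {
    a <- pmin(h$query_id, h$subject_id)
    b <- pmax(h$query_id, h$subject_id)
    dir_tbl <- tibble(a = a, b = b, forward = h$query_id == a,
                      identity = h$identity, score = h$bitscore)
    agg <- dir_tbl |>
      group_by(.data$a, .data$b) |>
      summarise(n_dir = dplyr::n_distinct(.data$forward),
                identity = mean(.data$identity), score = max(.data$score),
                .groups = "drop")
    if (reciprocal) agg <- agg[agg$n_dir == 2L, , drop = FALSE]
    edges <- tibble(from = agg$a, to = agg$b, identity = agg$identity,
                    score = agg$score)
  }
  structure(list(nodes = tibble(id = all_ids), edges = edges),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network: %d nodes, %d edges>\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' Connected components of a similarity network
#'
#' Groups are connected components; the deterministic group id is the
#' smallest member id. Components with at least `major_min` members are
#' flagged as major groups.
#'
#' @param network a `similarity_network`.
#' @param major_min minimum size of a major group.
#' @return tibble with `group_id`, `members` (list column), `n_members`,
#'   `major`.
#' @export
network_components <- function(network, major_min = 3) {
  if (nrow(network$nodes) == 0L) {
    return(tibble(group_id = character(), members = list(),
                  n_members = integer(), major = logical()))
  }
  g <- as_igraph(network)
  comp <- igraph::components(g)
  membership <- split(names(comp$membership), comp$membership)
  rows <- lapply(membership, function(m) {
    m <- sort(m)
    tibble(group_id = m[1], members = list(m), n_members = length(m))
  })
  out <- arrange(bind_rows(rows), .data$group_id)
  out$major <- out$n_members >= major_min
  out
}

#' Fill per-group statistics
#'
#' Adds the arithmetic mean protein length and the duplication-class
#' distribution of each group. Members without a duplication call are
#' counted as `unassigned`.
#'
#' @param groups tibble from [network_components()].
#' @param proteins protein tibble covering every member id.
#' @param dup_calls optional tibble from [classify_duplications()].
#' @return `groups` with `mean_length` and `duplication_distribution`
#'   (list of named integer vectors) added.
#' @export
group_stats <- function(groups, proteins, dup_calls = NULL) {
  check_columns(proteins, c("id", "length"), "proteins")
  call_map <- NULL
  if (!is.null(dup_calls)) {
    call_map <- setNames(as.character(dup_calls$class), dup_calls$gene_id)
  }
  groups$mean_length <- vapply(groups$members, function(m) {
    len <- proteins$length[match(m, proteins$id)]
    if (anyNA(len)) stopf("group member without a protein length: %s",
                          m[is.na(len)][1])
    mean(len)
  }, numeric(1))
  groups$duplication_distribution <- lapply(groups$members, function(m) {
    cls <- if (is.null(call_map)) rep("unassigned", length(m)) else {
      out <- call_map[m]
      out[is.na(out)] <- "unassigned"
      out
    }
    table(factor(cls, levels = duplication_classes()))
  })
  groups
}

#' Export a network as an edge-list TSV
#'
#' @param network a `similarity_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_edgelist <- function(network, path) {
  readr::write_tsv(network$edges, path, progress = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' @param network a `similarity_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}
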