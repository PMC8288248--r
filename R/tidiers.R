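#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a conservation profile
#'
#' @param x a `conservation_profile`.
#' @param ... unused.
#' @return tibble with one row per alignment column (`column`, `score`).
#' @export
tidy.conservation_profile <- function(x, ...) {
  tibble(column = seq_along(x$column_scores), score = x$column_scores)
}

#' One-row summary of a conservation profile
#'
#' @param x a `conservation_profile`.
#' @param ... unused.
#' @return one-row tibble with `family_score`, `n_members`, `n_columns`,
#'   `min_gene_score`, `max_gene_score`.
#' @export
glance.conservation_profile <- function(x, ...) {
  tibble(family_score = x$family_score, n_members = x$n_members,
         n_columns = length(x$column_scores),
         min_gene_score = min(x$per_gene_scores),
         max_gene_score = max(x$per_gene_scores))
}

#' Tidy a similarity network
#'
#' @param x a `similarity_network`.
#' @param ... unused.
#' @return the edge tibble.
#' @export
tidy.similarity_network <- function(x, ...) x$edges

#' One-row summary of a similarity network
#'
#' @param x a `similarity_network`.
#' @param ... unused.
#' @return one-row tibble with `n_nodes`, `n_edges`, `n_components`,
#'   `n_major`.
#' @export
glance.similarity_network <- function(x, ...) {
  comps <- network_components(x)
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_components = nrow(comps), n_major = sum(comps$major))
}

#' Tidy a multiple alignment
#'
#' @param x a `multiple_alignment`.
#' @param ... unused.
#' @return tibble with `id` and gapped `alignment` rows.
#' @export
tidy.multiple_alignment <- function(x, ...) {
  tibble(id = x$member_ids, alignment = x$rows)
}

#' One-row summary of a synthetic dataset
#'
#' @param x a `synthetic_dataset`.
#' @param ... unused.
#' @return one-row tibble of dataset dimensions.
#' @export
glance.synthetic_dataset <- function(x, ...) {
  tibble(n_genes = nrow(x$loci),
         n_chromosomes = length(unique(x$loci$chromosome)),
         n_families = length(unique(x$truth$family_id)),
         n_homeolog_pairs = nrow(x$homeolog_pairs),
         n_repeats = nrow(x$repeats))
}
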