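# Simulation-side codon tables: per-position synonymous fractions and
# synonymous / nonsynonymous single-base neighbor lists, cached per session.
sim_codon_tables <- function() {
  if (!is.null(the$sim_codon_tables)) return(the$sim_codon_tables)
  gc_map <- Biostrings::GENETIC_CODE
  codons <- names(gc_map)
  aa <- unname(gc_map)
  bases <- c("A", "C", "G", "T")
  n <- length(codons)
  idx <- setNames(seq_len(n), codons)
  syn_frac <- matrix(0, n, 3)
  syn_nb <- vector("list", n * 3)
  dim(syn_nb) <- c(n, 3)
  nonsyn_nb <- vector("list", n)
  for (i in seq_len(n)) {
    if (aa[i] == "*") next
    cd <- strsplit(codons[i], "")[[1]]
    ns <- integer(0)
    for (pos in 1:3) {
      sy <- integer(0)
      for (b in setdiff(bases, cd[pos])) {
        nb <- cd
        nb[pos] <- b
        j <- idx[paste(nb, collapse = "")]
        if (aa[j] == "*") next
        if (aa[j] == aa[i]) sy <- c(sy, j) else ns <- c(ns, j)
      }
      syn_frac[i, pos] <- length(sy) / 3
      syn_nb[[i, pos]] <- sy
    }
    nonsyn_nb[[i]] <- ns
  }
  the$sim_codon_tables <- list(codons = codons, aa = aa, idx = idx,
                               syn_frac = syn_frac, syn_nb = syn_nb,
                               nonsyn_nb = nonsyn_nb,
                               sense = which(aa != "*"))
  the$sim_codon_tables
}

#' Configuration for the polyploid-genome simulator
#'
#' The defaults describe the study conditions exercised throughout the
#' package's tests: a genome of 1,000 ancestral genes (5 chromosomes x 200
#' genes) of 300 codons each, one whole-genome duplication with planted
#' synonymous distance 0.2 between homeologs and 30% fractionation loss,
#' low rates of tandem/proximal/dispersed duplication, 5% per-site
#' amino-acid divergence per gene copy, and LTR-style repeat insertion in
#' one intergenic flank out of five.
#'
#' @param seed integer random seed; a fixed seed gives byte-identical
#'   emitted files.
#' @param n_chromosomes number of ancestral chromosomes.
#' @param genes_per_chromosome ancestral genes per chromosome.
#' @param n_families number of gene families; defaults to one family per
#'   ancestral gene. When smaller, families are reassigned to shuffled
#'   positions so shared ancestry does not fabricate collinearity.
#' @param protein_length founder protein length in codons.
#' @param wgd_rounds list of `c(ds = ..., loss = ...)` vectors, one per
#'   whole-genome duplication: `ds` is the planted synonymous distance
#'   between homeologs created by that round, `loss` the fractionation
#'   probability that the new homeolog is lost.
#' @param tandem_rate,proximal_rate,dispersed_rate per-gene probabilities of
#'   a recent local/dispersed duplication (at most one per gene).
#' @param substitution_rate per-site amino-acid replacement probability on
#'   the lineage from the family founder to each gene copy.
#' @param truncation_rate per-gene probability that a copy is truncated.
#' @param truncation_fraction retained length fraction of truncated copies.
#' @param repeat_insertion_rate per-intergenic-flank probability of one
#'   LTR-style repeat insertion.
#' @param intergenic_mean mean intergenic gap in bp.
#' @param proximal_window maximum gene-rank offset of proximal duplicates.
#' @param species species label of the simulated genome.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 5L,
                              genes_per_chromosome = 200L,
                              n_families = NULL,
                              protein_length = 300L,
                              wgd_rounds = list(c(ds = 0.2, loss = 0.3)),
                              tandem_rate = 0.03,
                              proximal_rate = 0.02,
                              dispersed_rate = 0.02,
                              substitution_rate = 0.05,
                              truncation_rate = 0,
                              truncation_fraction = 0.6,
                              repeat_insertion_rate = 0.2,
                              intergenic_mean = 2000,
                              proximal_window = 10L,
                              species = "synthetica") {
  n_genes <- n_chromosomes * genes_per_chromosome
  if (n_genes < 1L) stopf("the genome must contain at least one gene")
  if (protein_length < 10L) stopf("protein_length must be at least 10 codons")
  n_families <- n_families %||% n_genes
  if (n_families < 1L || n_families > n_genes) {
    stopf("n_families must be in [1, %d]", n_genes)
  }
  rates <- c(tandem_rate, proximal_rate, dispersed_rate, substitution_rate,
             truncation_rate, repeat_insertion_rate)
  if (any(rates < 0) || any(rates > 1)) stopf("all rates must lie in [0, 1]")
  if (sum(tandem_rate, proximal_rate, dispersed_rate, truncation_rate) > 1) {
    stopf("tandem + proximal + dispersed + truncation rates must not exceed 1")
  }
  for (r in wgd_rounds) {
    if (!all(c("ds", "loss") %in% names(r)) || r[["ds"]] < 0 ||
        r[["loss"]] < 0 || r[["loss"]] > 1) {
      stopf("each wgd round needs ds >= 0 and loss in [0, 1]")
    }
  }
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 genes_per_chromosome = genes_per_chromosome,
                 n_families = n_families, protein_length = protein_length,
                 wgd_rounds = wgd_rounds, tandem_rate = tandem_rate,
                 proximal_rate = proximal_rate,
                 dispersed_rate = dispersed_rate,
                 substitution_rate = substitution_rate,
                 truncation_rate = truncation_rate,
                 truncation_fraction = truncation_fraction,
                 repeat_insertion_rate = repeat_insertion_rate,
                 intergenic_mean = intergenic_mean,
                 proximal_window = proximal_window, species = species),
            class = "simulation_config")
}

# JC-inverted per-site change probability for a branch of synonymous length d
jc_change_prob <- function(d) 0.75 * (1 - exp(-4 * d / 3))

# Evolve a codon-index vector by branch synonymous distance d: each codon
# position changes to a random synonymous neighbor with probability
# (per-position synonymous fraction) * jc_change_prob(d).
evolve_syn <- function(cds_idx, d, tabs) {
  if (d <= 0) return(cds_idx)
  p <- jc_change_prob(d)
  for (pos in 1:3) {
    pr <- tabs$syn_frac[cds_idx, pos] * p
    hit <- which(stats::runif(length(cds_idx)) < pr)
    for (h in hit) {
      nb <- tabs$syn_nb[[cds_idx[h], pos]]
      if (length(nb) > 0L) cds_idx[h] <- nb[sample.int(length(nb), 1L)]
    }
  }
  cds_idx
}

# Replace amino acids at per-site rate using nonsynonymous single-base
# neighbors (keeps synonymous positions untouched).
apply_aa_substitutions <- function(cds_idx, rate, tabs) {
  if (rate <= 0) return(cds_idx)
  hit <- which(stats::runif(length(cds_idx)) < rate)
  for (h in hit) {
    nb <- tabs$nonsyn_nb[[cds_idx[h]]]
    if (length(nb) > 0L) cds_idx[h] <- nb[sample.int(length(nb), 1L)]
  }
  cds_idx
}

#' Simulate a polyploid genome with planted ground truth
#'
#' Places ancestral gene families on chromosomes, applies the configured
#' whole-genome duplications (duplicating every chromosome, then removing
#' new homeologs at the fractionation loss rate), adds recent tandem,
#' proximal and dispersed duplicates, diverges codon sequences so that the
#' planted synonymous distance is the expected NG86 estimate between
#' homeologs (synonymous-neighbor moves with Jukes-Cantor-inverted
#' per-site probabilities), applies star-shaped per-copy amino-acid
#' divergence, lays out coordinates with exponential intergenic gaps,
#' inserts LTR-style repeats into flanks, and records per-gene truth.
#'
#' @param config a [simulation_config()].
#' @return an object of class `synthetic_dataset`: list of tibbles
#'   `proteins`, `cds`, `loci`, `domain_hits`, `repeats`, `truth`,
#'   `homeolog_pairs`, `reference` plus the `config`.
#' @export
simulate_genome <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stopf("config must come from simulation_config()")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)
  tabs <- sim_codon_tables()
  L <- config$protein_length

  # planted family architectures: the first accession is family-unique so
  # architecture tuples identify families exactly
  n_fam <- config$n_families
  fam_ids <- sprintf("FAM%04d", seq_len(n_fam))
  shared_pool <- sprintf("IPR9%05d", 1:50)
  architectures <- vector("list", n_fam)
  for (f in seq_len(n_fam)) {
    n_dom <- sample(1:3, 1L)
    acc <- c(sprintf("IPR%06d", f),
             if (n_dom > 1L) sample(shared_pool, n_dom - 1L) else character(0))
    seg <- floor(L / n_dom)
    doms <- lapply(seq_len(n_dom), function(k) {
      lo <- (k - 1L) * seg + 1L
      hi <- k * seg
      w <- sample(20:min(60, seg - 5L), 1L)
      s <- sample(lo:(hi - w), 1L)
      c(start = s, end = s + w - 1L)
    })
    architectures[[f]] <- tibble(
      accession = acc,
      start = vapply(doms, `[[`, integer(1), "start"),
      end = vapply(doms, `[[`, integer(1), "end"))
  }

  # founder CDS per family (codon indices; ATG start, no internal stops)
  founder_cds <- lapply(seq_len(n_fam), function(f) {
    c(tabs$idx[["ATG"]], sample(tabs$sense, L - 1L, replace = TRUE))
  })

  # ancestral genome
  n_genes <- config$n_chromosomes * config$genes_per_chromosome
  fam_assign <- if (n_fam == n_genes) seq_len(n_genes) else
    sample(rep_len(seq_len(n_fam), n_genes))
  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("g%05d", counter)
  }
  gene_family <- integer(0)
  gene_cds <- list()
  chroms <- list()
  for (ch in seq_len(config$n_chromosomes)) {
    ids <- character(config$genes_per_chromosome)
    for (k in seq_len(config$genes_per_chromosome)) {
      g <- new_id()
      ids[k] <- g
      f <- fam_assign[(ch - 1L) * config$genes_per_chromosome + k]
      gene_family[g] <- f
      gene_cds[[g]] <- founder_cds[[f]]
    }
    chroms[[paste0("chr", ch)]] <- ids
  }

  # whole-genome duplications, oldest first
  rounds <- config$wgd_rounds
  ds_vals <- vapply(rounds, `[[`, numeric(1), "ds")
  rounds <- rounds[order(-ds_vals)]
  depths <- vapply(rounds, `[[`, numeric(1), "ds") / 2
  pairs <- list()
  prev_depth <- if (length(depths)) depths[1] else 0
  for (r in seq_along(rounds)) {
    branch <- prev_depth - depths[r]
    if (branch > 0) {
      for (g in names(gene_cds)) {
        gene_cds[[g]] <- evolve_syn(gene_cds[[g]], branch, tabs)
      }
    }
    loss <- rounds[[r]][["loss"]]
    for (ch in names(chroms)) {
      src_ids <- chroms[[ch]]
      kept <- character(0)
      for (g in src_ids) {
        if (stats::runif(1) < loss) next
        gn <- new_id()
        gene_family[gn] <- gene_family[[g]]
        gene_cds[[gn]] <- gene_cds[[g]]
        pairs[[length(pairs) + 1L]] <- tibble(
          id_a = g, id_b = gn, round = r,
          planted_ds = rounds[[r]][["ds"]])
        kept <- c(kept, gn)
      }
      if (length(kept) > 0L) chroms[[paste0(ch, "_", r)]] <- kept
    }
    prev_depth <- depths[r]
  }
  if (length(depths) > 0L && depths[length(depths)] > 0) {
    for (g in names(gene_cds)) {
      gene_cds[[g]] <- evolve_syn(gene_cds[[g]], depths[length(depths)], tabs)
    }
  }
  homeolog_pairs <- if (length(pairs)) bind_rows(pairs) else
    tibble(id_a = character(), id_b = character(), round = integer(),
           planted_ds = double())

  # recent local / dispersed duplications and truncations (one event max)
  p_t <- config$tandem_rate
  p_p <- config$proximal_rate
  p_d <- config$dispersed_rate
  p_x <- config$truncation_rate
  truncated <- character(0)
  snapshot <- names(gene_cds)
  chrom_names_snapshot <- names(chroms)
  for (g in snapshot) {
    u <- stats::runif(1)
    if (u < p_t + p_p + p_d) {
      gn <- new_id()
      gene_family[gn] <- gene_family[[g]]
      gene_cds[[gn]] <- gene_cds[[g]]
      src_ch <- chrom_names_snapshot[vapply(chrom_names_snapshot, function(ch)
        g %in% chroms[[ch]], logical(1))][1]
      pos <- match(g, chroms[[src_ch]])
      if (u < p_t) {
        chroms[[src_ch]] <- append(chroms[[src_ch]], gn, after = pos)
      } else if (u < p_t + p_p) {
        offset <- sample(2:config$proximal_window, 1L)
        at <- min(pos + offset - 1L, length(chroms[[src_ch]]))
        chroms[[src_ch]] <- append(chroms[[src_ch]], gn, after = at)
      } else {
        dest <- sample(names(chroms), 1L)
        at <- sample.int(length(chroms[[dest]]) + 1L, 1L) - 1L
        chroms[[dest]] <- append(chroms[[dest]], gn, after = at)
      }
    } else if (u < p_t + p_p + p_d + p_x) {
      keep <- max(10L, floor(L * config$truncation_fraction))
      gene_cds[[g]] <- gene_cds[[g]][seq_len(keep)]
      truncated <- c(truncated, g)
    }
  }

  # star-shaped amino-acid divergence per copy
  if (config$substitution_rate > 0) {
    for (g in names(gene_cds)) {
      gene_cds[[g]] <- apply_aa_substitutions(gene_cds[[g]],
                                              config$substitution_rate, tabs)
    }
  }

  # coordinate layout and repeat insertion
  loci_rows <- list()
  repeat_rows <- list()
  for (ch in sort(names(chroms))) {
    pos <- 0L
    for (g in chroms[[ch]]) {
      gap <- max(200L, as.integer(round(stats::rexp(1, 1 / config$intergenic_mean))))
      if (stats::runif(1) < config$repeat_insertion_rate && gap > 600L) {
        rep_len_bp <- min(gap - 100L, sample(500:3000, 1L))
        rep_start <- pos + sample.int(gap - rep_len_bp - 50L, 1L) + 25L
        repeat_rows[[length(repeat_rows) + 1L]] <- tibble(
          chromosome = ch, start = rep_start,
          end = rep_start + rep_len_bp - 1L, class = "LTR")
      }
      start <- pos + gap + 1L
      end <- start + 3L * length(gene_cds[[g]]) - 1L
      loci_rows[[length(loci_rows) + 1L]] <- tibble(
        gene_id = g, chromosome = ch, start = start, end = end,
        strand = "+", species = config$species)
      pos <- end
    }
  }
  loci <- arrange(bind_rows(loci_rows), .data$chromosome, .data$start)
  repeats <- if (length(repeat_rows)) bind_rows(repeat_rows) else
    tibble(chromosome = character(), start = integer(), end = integer(),
           class = character())

  # sequences, domain hits, truth
  all_ids <- loci$gene_id
  cds_str <- vapply(all_ids, function(g) {
    paste(tabs$codons[gene_cds[[g]]], collapse = "")
  }, character(1))
  prot_str <- vapply(all_ids, function(g) {
    paste(tabs$aa[gene_cds[[g]]], collapse = "")
  }, character(1))
  proteins <- tibble(id = all_ids, species = config$species,
                     sequence = unname(prot_str),
                     length = nchar(unname(prot_str)))
  cds_tbl <- tibble(id = all_ids, species = config$species,
                    sequence = unname(cds_str),
                    length = nchar(unname(cds_str)))

  hit_rows <- lapply(all_ids, function(g) {
    arch <- architectures[[gene_family[[g]]]]
    plen <- length(gene_cds[[g]])
    arch <- arch[arch$start <= plen, , drop = FALSE]
    if (nrow(arch) == 0L) return(NULL)
    tibble(protein_id = g, accession = arch$accession,
           start = arch$start, end = pmin(arch$end, plen), evalue = 1e-30)
  })
  domain_hits <- bind_rows(hit_rows)

  arch_keys <- vapply(architectures, function(a)
    architecture_key(a$accession), character(1))
  surv_pairs <- homeolog_pairs[homeolog_pairs$id_a %in% all_ids &
                                 homeolog_pairs$id_b %in% all_ids, ,
                               drop = FALSE]
  partner_map <- list()
  for (i in seq_len(nrow(surv_pairs))) {
    a <- surv_pairs$id_a[i]; b <- surv_pairs$id_b[i]
    r <- surv_pairs$round[i]; d <- surv_pairs$planted_ds[i]
    for (pair in list(c(a, b), c(b, a))) {
      cur <- partner_map[[pair[1]]]
      if (is.null(cur) || r > cur$round) {
        partner_map[[pair[1]]] <- list(partner = pair[2], round = r, ds = d)
      }
    }
  }
  ranks <- assign_gene_ranks(loci)
  rank_map <- setNames(ranks$rank, ranks$gene_id)
  chrom_map <- setNames(ranks$chromosome, ranks$gene_id)
  fam_of <- vapply(all_ids, function(g) gene_family[[g]], integer(1))
  fam_members <- split(all_ids, fam_of)
  truth_class <- vapply(all_ids, function(g) {
    if (!is.null(partner_map[[g]])) return("wgd_segmental")
    sibs <- setdiff(fam_members[[as.character(fam_of[[g]])]], g)
    if (length(sibs) == 0L) return("singleton")
    same <- sibs[chrom_map[sibs] == chrom_map[[g]]]
    dr <- abs(rank_map[same] - rank_map[[g]])
    if (length(same) > 0L && any(dr == 1L)) return("tandem")
    if (length(same) > 0L && any(dr <= config$proximal_window)) {
      return("proximal")
    }
    "dispersed"
  }, character(1))
  truth <- tibble(
    gene_id = all_ids, species = config$species,
    family_id = fam_ids[fam_of],
    architecture_key = arch_keys[fam_of],
    duplication_class = truth_class,
    homeolog_partner = vapply(all_ids, function(g) {
      p <- partner_map[[g]]
      if (is.null(p)) NA_character_ else p$partner
    }, character(1)),
    branch_ds = vapply(all_ids, function(g) {
      p <- partner_map[[g]]
      if (is.null(p)) NA_real_ else p$ds
    }, numeric(1)),
    truncated = all_ids %in% truncated)

  ref_prot <- vapply(founder_cds, function(v)
    paste(tabs$aa[v], collapse = ""), character(1))
  reference <- tibble(
    symbol = fam_ids, category = "synthetic", subcategory = "",
    protein_id = fam_ids, sequence = ref_prot, length = nchar(ref_prot),
    architecture = lapply(architectures, function(a) a$accession),
    architecture_key = arch_keys)
  ref_domain_hits <- bind_rows(lapply(seq_len(n_fam), function(f) {
    a <- architectures[[f]]
    tibble(protein_id = fam_ids[f], accession = a$accession,
           start = a$start, end = a$end, evalue = 1e-30)
  }))

  structure(list(proteins = proteins, cds = cds_tbl, loci = loci,
                 domain_hits = domain_hits, repeats = repeats, truth = truth,
                 homeolog_pairs = surv_pairs, reference = reference,
                 ref_domain_hits = ref_domain_hits, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset: %d genes on %d chromosomes, %d families, %d surviving homeolog pairs>\n",
              nrow(x$loci), length(unique(x$loci$chromosome)),
              length(unique(x$truth$family_id)), nrow(x$homeolog_pairs)))
  invisible(x)
}

#' Write a synthetic dataset to disk in standard formats
#'
#' Emits protein FASTA, CDS FASTA, gene GFF3, InterProScan-style domain TSV,
#' repeat GFF3, a truth TSV, and the reference catalog (TSV + FASTA +
#' domain TSV); every file is readable by the package's readers and
#' byte-identical across reruns of the same configuration.
#'
#' @param dataset a `synthetic_dataset`.
#' @param directory output directory (created if missing).
#' @return named character vector of file paths.
#' @export
emit <- function(dataset, directory) {
  if (!inherits(dataset, "synthetic_dataset")) {
    stopf("dataset must come from simulate_genome()")
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stopf("cannot create directory: %s", directory)
  paths <- c(
    proteins = file.path(directory, "proteins.fasta"),
    cds = file.path(directory, "cds.fasta"),
    genes = file.path(directory, "genes.gff3"),
    domains = file.path(directory, "domains.tsv"),
    repeats = file.path(directory, "repeats.gff3"),
    truth = file.path(directory, "truth.tsv"),
    catalog = file.path(directory, "reference_catalog.tsv"),
    ref_proteins = file.path(directory, "reference_proteins.fasta"),
    ref_domains = file.path(directory, "reference_domains.tsv"))
  write_fasta(dataset$proteins, paths[["proteins"]])
  write_fasta(dataset$cds, paths[["cds"]])
  write_gene_models(dataset$loci, paths[["genes"]])
  write_domain_annotations(dataset$domain_hits, paths[["domains"]])
  write_repeat_annotations(dataset$repeats, paths[["repeats"]])
  readr::write_tsv(dataset$truth, paths[["truth"]], progress = FALSE)
  readr::write_tsv(dataset$reference[, c("symbol", "category", "subcategory",
                                         "protein_id")],
                   paths[["catalog"]], progress = FALSE)
  write_fasta(tibble(id = dataset$reference$protein_id,
                     sequence = dataset$reference$sequence),
              paths[["ref_proteins"]])
  write_domain_annotations(dataset$ref_domain_hits, paths[["ref_domains"]])
  paths
}
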