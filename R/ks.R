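# Codon bookkeeping for Nei-Gojobori (1986) counting. Tables are computed
# once per session from the standard genetic code and cached.
codon_tables <- function() {
  if (!is.null(the$codon_tables)) return(the$codon_tables)
  gc_map <- Biostrings::GENETIC_CODE
  codons <- names(gc_map)
  aa <- unname(gc_map)
  bases <- c("A", "C", "G", "T")
  n <- length(codons)
  idx <- setNames(seq_len(n), codons)
  is_stop <- aa == "*"

  # synonymous site fraction per codon: per position, the share of the three
  # single-base neighbors that are synonymous; neighbors that are stop codons
  # count as nonsynonymous.
  syn_sites <- rep(NA_real_, n)
  names(syn_sites) <- codons
  for (i in seq_len(n)) {
    if (is_stop[i]) next
    s <- 0
    cd <- strsplit(codons[i], "")[[1]]
    for (pos in 1:3) {
      for (b in setdiff(bases, cd[pos])) {
        nb <- cd
        nb[pos] <- b
        nb_codon <- paste(nb, collapse = "")
        if (!is_stop[idx[nb_codon]] && aa[idx[nb_codon]] == aa[i]) {
          s <- s + 1 / 3
        }
      }
    }
    syn_sites[i] <- s
  }

  # pathway-averaged synonymous / nonsynonymous differences per codon pair;
  # minimal substitution pathways traversing a stop codon are excluded (all
  # pathways are used if every pathway is blocked).
  syn_diff <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  nonsyn_diff <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (i in seq_len(n)) {
    if (is_stop[i]) next
    ci <- strsplit(codons[i], "")[[1]]
    for (j in seq_len(n)) {
      if (is_stop[j]) next
      cj <- strsplit(codons[j], "")[[1]]
      diff_pos <- which(ci != cj)
      nd <- length(diff_pos)
      if (nd == 0L) {
        syn_diff[i, j] <- 0
        nonsyn_diff[i, j] <- 0
        next
      }
      paths <- lapply(perms[[nd]], function(p) diff_pos[p])
      evaluate <- function(path) {
        cur <- ci
        sd <- 0; nsd <- 0; blocked <- FALSE
        for (pos in path) {
          nxt <- cur
          nxt[pos] <- cj[pos]
          aa_cur <- aa[idx[paste(cur, collapse = "")]]
          aa_nxt <- aa[idx[paste(nxt, collapse = "")]]
          if (aa_nxt == "*") blocked <- TRUE
          if (aa_cur == aa_nxt) sd <- sd + 1 else nsd <- nsd + 1
          cur <- nxt
        }
        c(sd, nsd, blocked)
      }
      evals <- vapply(paths, evaluate, numeric(3))
      ok <- evals[3, ] == 0
      if (!any(ok)) ok <- rep(TRUE, ncol(evals))
      syn_diff[i, j] <- mean(evals[1, ok])
      nonsyn_diff[i, j] <- mean(evals[2, ok])
    }
  }
  the$codon_tables <- list(syn_sites = syn_sites, syn_diff = syn_diff,
                           nonsyn_diff = nonsyn_diff, is_stop = is_stop,
                           idx = idx)
  the$codon_tables
}

split_codons <- function(row) {
  if (nchar(row) %% 3 != 0) stopf("codon row length not divisible by 3")
  substring(row, seq(1L, nchar(row), by = 3L), seq(3L, nchar(row), by = 3L))
}

#' Nei-Gojobori site and difference counts for a codon pair
#'
#' Computes the NG86 quantities for two equal-length gapped codon rows.
#' Columns with a gap or a stop codon in either row are skipped pairwise.
#' Synonymous site fractions are averaged over both sequences; codons
#' differing at more than one position are resolved by averaging over all
#' minimal substitution pathways, excluding pathways that traverse a stop
#' codon.
#'
#' @param codon_row_a,codon_row_b gapped codon strings (gap codon `---`).
#' @return list with `syn_sites`, `nonsyn_sites`, `syn_diffs`,
#'   `nonsyn_diffs`, `n_codons` (codon columns used).
#' @export
ng86_sites_and_differences <- function(codon_row_a, codon_row_b) {
  if (nchar(codon_row_a) != nchar(codon_row_b)) {
    stopf("codon rows differ in length (%d vs %d)",
          nchar(codon_row_a), nchar(codon_row_b))
  }
  ca <- toupper(split_codons(codon_row_a))
  cb <- toupper(split_codons(codon_row_b))
  tabs <- codon_tables()
  ia <- tabs$idx[ca]
  ib <- tabs$idx[cb]
  usable <- !is.na(ia) & !is.na(ib) & !tabs$is_stop[ia] & !tabs$is_stop[ib] &
    !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
  ia <- ia[usable]; ib <- ib[usable]
  if (length(ia) == 0L) {
    return(list(syn_sites = 0, nonsyn_sites = 0, syn_diffs = 0,
                nonsyn_diffs = 0, n_codons = 0L))
  }
  syn_sites <- (sum(tabs$syn_sites[ia]) + sum(tabs$syn_sites[ib])) / 2
  list(syn_sites = syn_sites,
       nonsyn_sites = 3 * length(ia) - syn_sites,
       syn_diffs = sum(tabs$syn_diff[cbind(ia, ib)]),
       nonsyn_diffs = sum(tabs$nonsyn_diff[cbind(ia, ib)]),
       n_codons = length(ia))
}

#' Jukes-Cantor-corrected synonymous distance
#'
#' Converts NG86 counts into the proportion of synonymous differences per
#' synonymous site (`pS`) and the Jukes-Cantor-corrected synonymous distance
#' `ks = -(3/4) * ln(1 - (4/3) * pS)`. When `pS >= 3/4` (outside the
#' correction domain) or no synonymous sites are available, `ks` is `NA`
#' with the reason recorded, never an error.
#'
#' @param counts list from [ng86_sites_and_differences()].
#' @return one-row tibble with `syn_sites`, `nonsyn_sites`, `syn_diffs`,
#'   `nonsyn_diffs`, `pS`, `ks`, `note`.
#' @export
ks <- function(counts) {
  if (counts$syn_sites <= 0) {
    return(tibble(syn_sites = counts$syn_sites,
                  nonsyn_sites = counts$nonsyn_sites,
                  syn_diffs = counts$syn_diffs,
                  nonsyn_diffs = counts$nonsyn_diffs,
                  pS = NA_real_, ks = NA_real_,
                  note = "no synonymous sites"))
  }
  pS <- counts$syn_diffs / counts$syn_sites
  if (pS >= 0.75) {
    ks_val <- NA_real_
    note <- "pS >= 3/4 (saturation; outside Jukes-Cantor domain)"
  } else {
    ks_val <- -(3 / 4) * log(1 - (4 / 3) * pS)
    note <- NA_character_
  }
  tibble(syn_sites = counts$syn_sites, nonsyn_sites = counts$nonsyn_sites,
         syn_diffs = counts$syn_diffs, nonsyn_diffs = counts$nonsyn_diffs,
         pS = pS, ks = ks_val, note = note)
}

#' Synonymous distance between two gapped codon rows
#'
#' Convenience wrapper chaining [ng86_sites_and_differences()] and [ks()].
#'
#' @inheritParams ng86_sites_and_differences
#' @return one-row tibble as in [ks()].
#' @export
ks_pair <- function(codon_row_a, codon_row_b) {
  ks(ng86_sites_and_differences(codon_row_a, codon_row_b))
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each aligned protein row is converted to codons using its CDS: residues
#' map to consecutive codons and alignment gaps map to `---`. The CDS must
#' be divisible by three and translate (standard code, ignoring a terminal
#' stop) to the row's ungapped sequence; any mismatch is an error naming the
#' position.
#'
#' @param protein_msa a `multiple_alignment` of proteins.
#' @param cds_records CDS tibble (`id`, `sequence`) covering every member.
#' @return an object of class `codon_alignment`: list with `member_ids` and
#'   `rows` (gapped codon strings).
#' @export
back_translate <- function(protein_msa, cds_records) {
  check_columns(cds_records, c("id", "sequence"), "cds_records")
  rows <- character(length(protein_msa$member_ids))
  for (k in seq_along(protein_msa$member_ids)) {
    id <- protein_msa$member_ids[k]
    cds <- cds_records$sequence[match(id, cds_records$id)]
    if (is.na(cds)) stopf("no CDS for member '%s'", id)
    if (nchar(cds) %% 3 != 0) {
      stopf("CDS length of '%s' (%d) is not divisible by 3", id, nchar(cds))
    }
    gc_map <- Biostrings::GENETIC_CODE
    codon_vec <- split_codons(toupper(cds))
    aa_vec <- unname(gc_map[codon_vec])
    if (anyNA(aa_vec)) {
      stopf("CDS of '%s' contains a non-standard codon at codon %d",
            id, which(is.na(aa_vec))[1])
    }
    aa <- sub("\\*$", "", paste(aa_vec, collapse = ""))
    prot_row <- protein_msa$rows[k]
    prot <- sub("\\*$", "", gsub("-", "", prot_row, fixed = TRUE))
    if (nchar(aa) != nchar(prot)) {
      stopf("CDS of '%s' translates to %d residues but the protein row has %d",
            id, nchar(aa), nchar(prot))
    }
    cmp <- strsplit(aa, "")[[1]] != strsplit(prot, "")[[1]]
    if (any(cmp)) {
      stopf("translation mismatch for '%s' at residue %d", id, which(cmp)[1])
    }
    codons <- split_codons(substr(cds, 1L, 3L * nchar(prot)))
    out <- character(nchar(prot_row))
    res_chars <- strsplit(prot_row, "")[[1]]
    is_res <- res_chars != "-"
    out[is_res] <- codons
    out[!is_res] <- "---"
    rows[k] <- paste(out, collapse = "")
  }
  structure(list(member_ids = protein_msa$member_ids, rows = rows),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment: %d sequences x %d codon columns>\n",
              length(x$member_ids),
              if (length(x$rows)) nchar(x$rows[1]) / 3 else 0L))
  invisible(x)
}

#' Pairwise synonymous distances within families
#'
#' For each family with at least two members, aligns the member proteins
#' (pairwise global alignment for two members, progressive alignment
#' otherwise), back-translates to codons and reports the NG86
#' Jukes-Cantor-corrected synonymous distance of every within-family pair.
#'
#' @param families tibble with `gene_id` and `family_id`.
#' @param proteins protein tibble covering all members.
#' @param cds CDS tibble covering all members.
#' @param scheme a [scoring_scheme()].
#' @return tibble with `family_id`, `id_a`, `id_b`, `syn_sites`,
#'   `syn_diffs`, `pS`, `ks`.
#' @export
pairwise_ks_for_families <- function(families, proteins, cds,
                                     scheme = scoring_scheme()) {
  check_columns(families, c("gene_id", "family_id"), "families")
  out <- list()
  for (fam in split(families, families$family_id)) {
    ids <- sort(unique(fam$gene_id))
    if (length(ids) < 2L) next
    seqs <- proteins$sequence[match(ids, proteins$id)]
    if (anyNA(seqs)) stopf("missing protein sequence for family '%s'",
                           fam$family_id[1])
    seqs <- sub("\\*$", "", seqs)
    msa <- if (length(ids) == 2L) {
      aln <- global_align(seqs[1], seqs[2], scheme)
      multiple_alignment(ids, c(aln$aligned_a, aln$aligned_b))
    } else {
      progressive_msa(setNames(seqs, ids), scheme)
    }
    codon_aln <- back_translate(msa, cds)
    combs <- utils::combn(seq_along(codon_aln$member_ids), 2L)
    for (c_i in seq_len(ncol(combs))) {
      i <- combs[1, c_i]; j <- combs[2, c_i]
      est <- ks_pair(codon_aln$rows[i], codon_aln$rows[j])
      out[[length(out) + 1L]] <- mutate(
        est, family_id = fam$family_id[1],
        id_a = codon_aln$member_ids[i], id_b = codon_aln$member_ids[j],
        .before = 1L)
    }
  }
  if (length(out) == 0L) {
    return(tibble(family_id = character(), id_a = character(),
                  id_b = character(), syn_sites = double(),
                  nonsyn_sites = double(), syn_diffs = double(),
                  nonsyn_diffs = double(), pS = double(), ks = double(),
                  note = character()))
  }
  bind_rows(out)
}

#' Write pairwise Ks estimates as TSV
#'
#' @param ks_tbl tibble from [pairwise_ks_for_families()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ks_tsv <- function(ks_tbl, path) {
  readr::write_tsv(ks_tbl, path, progress = FALSE)
  invisible(path)
}
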