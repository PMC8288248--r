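#' Read a protein FASTA file
#'
#' Reads amino-acid sequences into a tibble, one row per record. The record id
#' is the header token before the first whitespace. A single terminal stop
#' (`*`) is allowed and excluded from the reported length.
#'
#' @param path path to a FASTA file.
#' @param species species label attached to every record (`NA` if unknown).
#' @return a tibble with columns `id`, `species`, `sequence`, `length`.
#' @export
read_protein_fasta <- function(path, species = NA_character_) {
  read_fasta_tbl(path, species, type = "AA")
}

#' Read a CDS FASTA file
#'
#' @inheritParams read_protein_fasta
#' @return a tibble with columns `id`, `species`, `sequence`, `length`
#'   (length in nucleotides).
#' @export
read_cds_fasta <- function(path, species = NA_character_) {
  read_fasta_tbl(path, species, type = "DNA")
}

read_fasta_tbl <- function(path, species, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) > 0L && !startsWith(trimws(lines[nonblank[1]]), ">")) {
    stopf("malformed FASTA in %s: line %d does not start a record ('>')",
          path, nonblank[1])
  }
  if (length(nonblank) == 0L) {
    return(tibble(id = character(), species = character(),
                  sequence = character(), length = integer()))
  }
  set <- if (type == "AA") Biostrings::readAAStringSet(path) else
    Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  len <- nchar(sub("\\*$", "", seqs))
  tibble(id = unname(ids), species = species,
         sequence = unname(seqs), length = unname(len))
}

#' Write sequences to FASTA
#'
#' @param records tibble with columns `id` and `sequence`.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  check_columns(records, c("id", "sequence"), "records")
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    seq <- records$sequence[i]
    chunks <- substring(seq, seq(1L, nchar(seq), by = width),
                        pmin(seq(1L, nchar(seq), by = width) + width - 1L, nchar(seq)))
    writeLines(c(paste0(">", records$id[i]), chunks), con, sep = "\n")
  }
  invisible(path)
}

#' Remove internally truncated and redundant proteins
#'
#' Mirrors standard proteome preparation: records with a stop (`*`) anywhere
#' but the final position are dropped, then redundant sequences are removed by
#' greedy incremental clustering on length-descending order (CD-HIT-like).
#' A record is removed when its global identity to an already-retained record
#' is at least `redundancy_identity`; identity here is matches divided by all
#' alignment columns (gap columns included), so the default of 1 removes exact
#' duplicates only. Retained records are returned in input order.
#'
#' @param records protein tibble from [read_protein_fasta()] (one species).
#' @param redundancy_identity identity fraction in (0, 1].
#' @param scheme scoring scheme for the identity alignments,
#'   see [scoring_scheme()].
#' @return the retained subset of `records`, in input order.
#' @export
clean_proteome <- function(records, redundancy_identity = 1.0,
                           scheme = scoring_scheme()) {
  check_columns(records, c("id", "sequence"), "records")
  if (!is.numeric(redundancy_identity) || length(redundancy_identity) != 1L ||
      is.na(redundancy_identity) ||
      redundancy_identity <= 0 || redundancy_identity > 1) {
    stopf("redundancy_identity must be a single number in (0, 1]")
  }
  core <- sub("\\*$", "", records$sequence)
  internal_stop <- grepl("\\*", core)
  records <- records[!internal_stop, , drop = FALSE]
  core <- core[!internal_stop]
  if (nrow(records) <= 1L) return(records)

  ord <- order(-nchar(core), seq_along(core))
  if (redundancy_identity == 1) {
    # identity 1 over all alignment columns forces exact sequence equality
    drop <- duplicated(core[ord])
    keep_idx <- sort(ord[!drop])
    return(records[keep_idx, , drop = FALSE])
  }

  retained <- integer(0)
  for (i in ord) {
    redundant <- FALSE
    for (j in retained) {
      # identity >= c requires len(short)/len(long) >= c; skip hopeless pairs
      ls <- nchar(core[i]); lj <- nchar(core[j])
      if (min(ls, lj) / max(ls, lj) < redundancy_identity) next
      aln <- global_align(core[i], core[j], scheme)
      ncol_aln <- nchar(aln$aligned_a)
      matches <- sum(strsplit(aln$aligned_a, "")[[1]] ==
                       strsplit(aln$aligned_b, "")[[1]] &
                       strsplit(aln$aligned_a, "")[[1]] != "-")
      if (matches / ncol_aln >= redundancy_identity) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) retained <- c(retained, i)
  }
  records[sort(retained), , drop = FALSE]
}

#' Read gene models from GFF3
#'
#' Keeps `gene` features only and returns 1-based inclusive loci sorted by
#' chromosome then start coordinate.
#'
#' @param path path to a GFF3 file whose gene features carry `ID` attributes.
#' @param species species label attached to every locus.
#' @return tibble with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`, `species`.
#' @export
read_gene_models <- function(path, species = NA_character_) {
  rows <- read_gff3_rows(path)
  rows <- rows[rows$type == "gene", , drop = FALSE]
  if (nrow(rows) == 0L) {
    return(tibble(gene_id = character(), chromosome = character(),
                  start = integer(), end = integer(), strand = character(),
                  species = character()))
  }
  ids <- gff3_attribute(rows$attributes, "ID")
  if (anyNA(ids)) {
    stopf("GFF3 parse error in %s: gene feature without an ID attribute (line %d)",
          path, rows$line[which(is.na(ids))[1]])
  }
  out <- tibble(gene_id = ids, chromosome = rows$seqid,
                start = rows$start, end = rows$end,
                strand = rows$strand, species = species)
  dplyr::arrange(out, .data$chromosome, .data$start, .data$end, .data$gene_id)
}

#' Read repeat annotations from GFF3
#'
#' All feature rows are kept; the feature type column is used as the repeat
#' class (e.g. `LTR`).
#'
#' @param path path to a repeat GFF3 file.
#' @return tibble with columns `chromosome`, `start`, `end`, `class`.
#' @export
read_repeat_annotations <- function(path) {
  rows <- read_gff3_rows(path)
  tibble(chromosome = rows$seqid, start = rows$start, end = rows$end,
         class = rows$type)
}

read_gff3_rows <- function(path) {
  if (!file.exists(path)) stopf("GFF3 file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  line_no <- seq_along(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]; line_no <- line_no[keep]
  if (length(lines) == 0L) {
    return(tibble(seqid = character(), type = character(), start = integer(),
                  end = integer(), strand = character(),
                  attributes = character(), line = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 9L)) {
    stopf("GFF3 parse error in %s: line %d has %d fields (9 expected)",
          path, line_no[which(nfield != 9L)[1]], nfield[which(nfield != 9L)[1]])
  }
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stopf("GFF3 parse error in %s: non-numeric coordinates on line %d",
          path, line_no[bad])
  }
  if (any(end < start)) {
    bad <- which(end < start)[1]
    stopf("GFF3 parse error in %s: end < start on line %d", path, line_no[bad])
  }
  tibble(seqid = m[, 1], type = m[, 3], start = start, end = end,
         strand = m[, 7], attributes = m[, 9], line = line_no)
}

gff3_attribute <- function(attributes, key) {
  pattern <- paste0("(?:^|;)\\s*", key, "=([^;]*)")
  m <- regmatches(attributes, regexec(pattern, attributes))
  vapply(m, function(x) if (length(x) == 2L && nzchar(x[2])) x[2] else NA_character_,
         character(1))
}

#' Write gene loci to GFF3
#'
#' @param loci tibble as returned by [read_gene_models()].
#' @param path output path.
#' @param source source field for column 2.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(loci, path, source = "polyflor") {
  check_columns(loci, c("gene_id", "chromosome", "start", "end", "strand"), "loci")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con, sep = "\n")
  if (nrow(loci) > 0L) {
    writeLines(sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       loci$chromosome, source, loci$start, loci$end,
                       loci$strand, loci$gene_id), con, sep = "\n")
  }
  invisible(path)
}

#' Write repeat features to GFF3
#'
#' @param repeats tibble with `chromosome`, `start`, `end`, `class`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeat_annotations <- function(repeats, path) {
  check_columns(repeats, c("chromosome", "start", "end", "class"), "repeats")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con, sep = "\n")
  if (nrow(repeats) > 0L) {
    writeLines(sprintf("%s\tpolyflor\t%s\t%d\t%d\t.\t.\t.\tID=rep%d",
                       repeats$chromosome, repeats$class, repeats$start,
                       repeats$end, seq_len(nrow(repeats))), con, sep = "\n")
  }
  invisible(path)
}

#' Read InterProScan-style domain annotations
#'
#' Consumes the tab-separated InterProScan dialect: column 1 protein id,
#' column 7 start, column 8 end, column 9 e-value, column 12 InterPro
#' accession. Rows whose column 12 is not an IPR-style accession are skipped;
#' exact duplicate hits are removed.
#'
#' @param path path to the TSV file (no header).
#' @return tibble with columns `protein_id`, `accession`, `start`, `end`,
#'   `evalue`.
#' @export
read_domain_annotations <- function(path) {
  if (!file.exists(path)) stopf("domain annotation file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(protein_id = character(), accession = character(),
                  start = integer(), end = integer(), evalue = double()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 12L)) {
    stopf("domain TSV parse error in %s: line %d has fewer than 12 columns",
          path, which(lengths(parts) < 12L)[1])
  }
  m <- do.call(rbind, lapply(parts, function(x) x[c(1, 12, 7, 8, 9)]))
  keep <- grepl("^IPR\\d+$", m[, 2])
  m <- m[keep, , drop = FALSE]
  start <- suppressWarnings(as.integer(m[, 3]))
  end <- suppressWarnings(as.integer(m[, 4]))
  if (anyNA(start) || anyNA(end)) {
    stopf("domain TSV parse error in %s: non-numeric coordinates", path)
  }
  evalue <- suppressWarnings(as.numeric(m[, 5]))
  out <- tibble(protein_id = m[, 1], accession = m[, 2],
                start = start, end = end, evalue = evalue)
  dplyr::distinct(out)
}

#' Write domain hits in InterProScan-style TSV
#'
#' @param hits tibble with `protein_id`, `accession`, `start`, `end`, `evalue`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domain_annotations <- function(hits, path) {
  check_columns(hits, c("protein_id", "accession", "start", "end", "evalue"), "hits")
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(hits) > 0L) {
    writeLines(sprintf("%s\tmd5\t0\tPfam\tPF\tdomain\t%d\t%d\t%s\tT\t2020-01-01\t%s\tdomain\tdomain\t-",
                       hits$protein_id, hits$start, hits$end,
                       formatC(hits$evalue, format = "g", digits = 6),
                       hits$accession), con, sep = "\n")
  }
  invisible(path)
}

#' Read an all-vs-all similarity table (BLAST outfmt-6 dialect)
#'
#' Twelve tab-separated columns: qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore. When per-sequence lengths are
#' supplied, query and subject coverage (% of the sequence spanned by the
#' aligned region) are computed; otherwise they are `NA`.
#'
#' @param path path to the tabular file.
#' @param query_lengths,subject_lengths optional named vectors (id -> length
#'   in residues) used to compute coverages.
#' @return tibble with one row per hit.
#' @export
read_similarity_table <- function(path, query_lengths = NULL,
                                  subject_lengths = NULL) {
  if (!file.exists(path)) stopf("similarity table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_similarity_tbl())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 12L)) {
    stopf("similarity table parse error in %s: line %d has %d columns (12 expected)",
          path, which(lengths(parts) != 12L)[1],
          lengths(parts)[which(lengths(parts) != 12L)[1]])
  }
  m <- do.call(rbind, parts)
  out <- tibble(
    query_id = m[, 1], subject_id = m[, 2],
    identity = as.numeric(m[, 3]), align_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12])
  )
  if (anyNA(out$identity) || anyNA(out$qstart)) {
    stopf("similarity table parse error in %s: non-numeric fields", path)
  }
  qlen <- if (is.null(query_lengths)) NA_real_ else
    unname(query_lengths[out$query_id])
  slen <- if (is.null(subject_lengths)) NA_real_ else
    unname(subject_lengths[out$subject_id])
  out$query_cov <- (abs(out$qend - out$qstart) + 1) / qlen * 100
  out$subject_cov <- (abs(out$send - out$sstart) + 1) / slen * 100
  out
}

empty_similarity_tbl <- function() {
  tibble(query_id = character(), subject_id = character(),
         identity = double(), align_length = integer(),
         mismatches = integer(), gap_opens = integer(),
         qstart = integer(), qend = integer(), sstart = integer(),
         send = integer(), evalue = double(), bitscore = double(),
         query_cov = double(), subject_cov = double())
}
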