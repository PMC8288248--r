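# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive implementations (state recursion over all gapped
# alignments, exhaustive chain enumeration, single-base neighbor counting)
# kept separate from the package's code paths.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Best global alignment score over all gapped alignments, affine gaps
# (gap of length L costs open + L * ext, end gaps included), by memoized
# recursion over (position in a, position in b, previous move).
oracle_global_score <- function(a, b, open = 10, ext = 0.05, mat = blosum62) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, last) {
    if (i > length(av) && j > length(bv)) return(0)
    key <- paste(i, j, last)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, mat[av[i], bv[j]] + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(av)) {
      cost <- if (last == "ga") ext else open + ext
      best <- max(best, rec(i + 1, j, "ga") - cost)
    }
    if (j <= length(bv)) {
      cost <- if (last == "gb") ext else open + ext
      best <- max(best, rec(i, j + 1, "gb") - cost)
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, "m")
}

# Best local alignment score: maximum over all substring pairs of the
# end-gap-free global score, floored at 0.
oracle_local_score <- function(a, b, open = 10, ext = 0.05, mat = blosum62) {
  na <- nchar(a)
  nb <- nchar(b)
  best <- 0
  for (i1 in seq_len(na)) for (i2 in i1:na) {
    sub_a <- substr(a, i1, i2)
    for (j1 in seq_len(nb)) for (j2 in j1:nb) {
      s <- oracle_global_score(sub_a, substr(b, j1, j2), open, ext, mat)
      if (s > best) best <- s
    }
  }
  best
}

# All maximal monotone chains by depth-first enumeration; returns the
# lexicographically smallest index chain of maximal length for the given
# orientation (rows must be sorted the same way the package sorts them).
oracle_best_chain <- function(rank_a, rank_b, max_gap, inverted = FALSE) {
  rb <- if (inverted) -rank_b else rank_b
  n <- length(rank_a)
  best <- integer(0)
  extend <- function(chain) {
    last <- chain[length(chain)]
    grew <- FALSE
    for (j in seq_len(n)) {
      if (j <= last) next
      da <- rank_a[j] - rank_a[last]
      db <- rb[j] - rb[last]
      if (da > 0 && da <= max_gap && db > 0 && db <= max_gap) {
        grew <- TRUE
        extend(c(chain, j))
      }
    }
    if (!grew) {
      if (length(chain) > length(best) ||
          (length(chain) == length(best) &&
           paste(chain, collapse = ",") < paste(best, collapse = ","))) {
        best <<- chain
      }
    }
  }
  for (s in seq_len(n)) extend(s)
  best
}

# Repeated extraction mirroring the block-detection contract, via the
# enumeration oracle.
oracle_blocks <- function(anchors, min_anchors, max_gap) {
  sizes <- integer(0)
  piece <- anchors[order(anchors$rank_a, anchors$rank_b), , drop = FALSE]
  repeat {
    if (nrow(piece) < min_anchors) break
    same <- oracle_best_chain(piece$rank_a, piece$rank_b, max_gap, FALSE)
    inv <- oracle_best_chain(piece$rank_a, piece$rank_b, max_gap, TRUE)
    chain <- if (length(same) >= length(inv)) same else inv
    if (length(chain) < min_anchors) break
    sizes <- c(sizes, length(chain))
    piece <- piece[-chain, , drop = FALSE]
  }
  sizes
}

# Per-codon synonymous site fraction by explicit enumeration of the nine
# single-base neighbors against the standard genetic code (stop neighbors
# count as nonsynonymous).
oracle_syn_sites <- function(codon) {
  gc_map <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  cd <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(bases, cd[pos])) {
      nb <- cd
      nb[pos] <- b
      nbc <- paste(nb, collapse = "")
      if (gc_map[[nbc]] != "*" && gc_map[[nbc]] == gc_map[[codon]]) {
        s <- s + 1 / 3
      }
    }
  }
  s
}

# Pathway-averaged synonymous/nonsynonymous differences between two sense
# codons, enumerating position permutations; stop-traversing paths excluded
# (all paths used when every path is blocked).
oracle_codon_diffs <- function(c1, c2) {
  gc_map <- Biostrings::GENETIC_CODE
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  dpos <- which(a != b)
  if (length(dpos) == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (length(dpos) == 1L) list(dpos) else {
    do.call(c, lapply(combinat_perms(length(dpos)), function(p) list(dpos[p])))
  }
  res <- t(vapply(perms, function(path) {
    cur <- a
    sd <- 0; nsd <- 0; blocked <- FALSE
    for (pos in path) {
      nxt <- cur
      nxt[pos] <- b[pos]
      aa1 <- gc_map[[paste(cur, collapse = "")]]
      aa2 <- gc_map[[paste(nxt, collapse = "")]]
      if (aa2 == "*") blocked <- TRUE
      if (aa1 == aa2) sd <- sd + 1 else nsd <- nsd + 1
      cur <- nxt
    }
    c(sd, nsd, as.numeric(blocked))
  }, numeric(3)))
  ok <- res[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(res))
  c(syn = mean(res[ok, 1]), nonsyn = mean(res[ok, 2]))
}

combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in combinat_perms(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

random_protein <- function(len) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V"), len, replace = TRUE),
        collapse = "")
}

sense_codons <- function() {
  gc_map <- Biostrings::GENETIC_CODE
  names(gc_map)[gc_map != "*"]
}
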