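## Seeded local similarity search (the pipeline's stand-in for blastn) and
## all-vs-all grouping of sequences into families by shared high-scoring
## segments.
##
## Search is seed-and-extend: exact k-mer seeds (Biostrings::matchPDict)
## are chained along diagonals, and each chain is extended by a local DP
## restricted to a window around the chain; the `x_drop` parameter sizes
## the window margin. E-values are not computed: hits are retained by
## (identity, length) thresholds, which keeps behaviour deterministic and
## independent of database size.

hit_columns <- function() {
  tibble::tibble(query_id = character(), subject_id = character(),
                 q_start = integer(), q_end = integer(),
                 s_start = integer(), s_end = integer(),
                 strand = character(), length = integer(),
                 identity = double(), score = double())
}

#' Seeded local similarity search
#'
#' Finds local alignments of `query` in `subject` on both strands. Subject
#' coordinates are always reported on the forward strand, 0-based
#' half-open; `strand == "-"` means the query matched the reverse
#' complement of the reported span.
#'
#' @param query,subject Sequences (`DNAString`/length-1 `DNAStringSet`/character).
#' @param seed_k Seed k-mer size (>= 8).
#' @param min_identity Minimum alignment identity to report a hit.
#' @param min_length Minimum subject-span length (bp) to report a hit.
#' @param x_drop Extension window margin (bp) beyond the seed chain.
#' @param scoring A [trim_scoring()] scheme.
#' @param both_strands Search the minus strand too (default TRUE).
#' @param query_id,subject_id Ids used in the output table.
#' @return A tibble of hits: `query_id`, `subject_id`, `q_start`, `q_end`,
#'   `s_start`, `s_end`, `strand`, `length` (subject-span bp), `identity`,
#'   `score`, sorted by `s_start`.
#' @export
seeded_search <- function(query, subject, seed_k = 11L, min_identity = 0.75,
                          min_length = 100L, x_drop = 20L,
                          scoring = trim_scoring(), both_strands = TRUE,
                          query_id = "query", subject_id = "subject") {
  stopifnot(seed_k >= 8L)
  q <- as_dna(query); s <- as_dna(subject)
  qlen <- length(q); slen <- length(s)
  if (qlen < seed_k) {
    warning("query shorter than seed_k (", qlen, " < ", seed_k,
            "); no hits reported")
    return(hit_columns())
  }
  strands <- if (both_strands) c("+", "-") else "+"
  out <- list()
  for (strand in strands) {
    s_use <- if (strand == "+") s else Biostrings::reverseComplement(s)
    seeds <- find_seeds(q, s_use, seed_k)
    if (nrow(seeds) == 0L) next
    clusters <- chain_seeds(seeds, seed_k,
                            band = max(16L, x_drop),
                            gap_max = max(120L, seed_k * 10L))
    hits <- extend_clusters(q, s_use, clusters, seed_k, x_drop, scoring)
    if (nrow(hits) == 0L) next
    if (strand == "-") {
      s_start <- slen - hits$s_end
      hits$s_end <- slen - hits$s_start
      hits$s_start <- s_start
    }
    hits$strand <- strand
    out[[strand]] <- hits
  }
  hits <- if (length(out)) do.call(rbind, out) else hit_columns()
  if (nrow(hits)) {
    hits$length <- hits$s_end - hits$s_start
    hits <- hits[hits$identity >= min_identity & hits$length >= min_length, ,
                 drop = FALSE]
  }
  if (nrow(hits)) {
    hits <- dedup_hits(hits)
    hits$query_id <- query_id
    hits$subject_id <- subject_id
    hits <- hits[order(hits$s_start, hits$s_end), , drop = FALSE]
  }
  tibble::as_tibble(hits)[, names(hit_columns())]
}

## preprocessed query k-mer indexes are expensive to build (notably the
## PDict used against large subjects), so they are cached per (k, query)
## within the session
.pdict_cache <- new.env(parent = emptyenv())

query_index <- function(qstr, k, want_pdict) {
  key <- paste0(k, ":", substr(qstr, 1, 40), ":", nchar(qstr), ":",
                qstr)
  val <- get0(key, envir = .pdict_cache)
  if (is.null(val)) {
    n <- nchar(qstr) - k + 1L
    starts <- seq_len(n)
    kmers <- substring(qstr, starts, starts + k - 1L)
    keep <- !grepl("N", kmers, fixed = TRUE)
    val <- if (!any(keep)) list(empty = TRUE) else
      list(empty = FALSE, kmers = kmers[keep], starts = starts[keep],
           pos_by_kmer = split(starts[keep] - 1L, kmers[keep]))
    if (length(ls(.pdict_cache)) > 64L) {
      rm(list = ls(.pdict_cache), envir = .pdict_cache)
    }
    assign(key, val, envir = .pdict_cache)
  }
  if (want_pdict && !val$empty && is.null(val$pd)) {
    val$pd <- Biostrings::PDict(Biostrings::DNAStringSet(val$kmers))
    assign(key, val, envir = .pdict_cache)
  }
  val
}

## exact k-mer matches of query k-mers in subj; 0-based positions.
## Small subjects are matched by hashing their k-mers against the query
## k-mer table; large subjects go through Biostrings::matchPDict.
find_seeds <- function(q, subj, k) {
  no_seeds <- data.frame(qpos = integer(), spos = integer())
  slen <- length(subj)
  use_pdict <- slen >= 50000L
  idx <- query_index(as.character(q), k, want_pdict = use_pdict)
  if (idx$empty) return(no_seeds)
  if (use_pdict) {
    m <- Biostrings::matchPDict(idx$pd, subj)
    counts <- S4Vectors::elementNROWS(m)
    if (sum(counts) == 0L) return(no_seeds)
    qpos <- rep.int(idx$starts - 1L, counts)
    spos <- unlist(IRanges::start(m), use.names = FALSE) - 1L
    return(data.frame(qpos = qpos, spos = spos))
  }
  sstr <- as.character(subj)
  if (nchar(sstr) < k) return(no_seeds)
  sk <- substring(sstr, seq_len(nchar(sstr) - k + 1L),
                  seq_len(nchar(sstr) - k + 1L) + k - 1L)
  hit <- match(sk, names(idx$pos_by_kmer))
  found <- which(!is.na(hit))
  if (!length(found)) return(no_seeds)
  qlist <- idx$pos_by_kmer[hit[found]]
  counts <- lengths(qlist)
  data.frame(qpos = unlist(qlist, use.names = FALSE),
             spos = rep.int(found - 1L, counts))
}

## single-link chaining of seeds: a seed joins an open chain when it is
## within gap_max downstream and within band of the chain's last diagonal
chain_seeds <- function(seeds, k, band, gap_max) {
  seeds <- seeds[order(seeds$spos, seeds$qpos), , drop = FALSE]
  diag <- seeds$spos - seeds$qpos
  n <- nrow(seeds)
  active <- list()   # each: qmin,qmax,smin,smax,last_spos,last_diag
  done <- list()
  for (i in seq_len(n)) {
    sp <- seeds$spos[i]; qp <- seeds$qpos[i]; dg <- diag[i]
    ## retire chains too far upstream
    if (length(active)) {
      keep <- vapply(active, function(cl) sp - cl$last_spos <= gap_max,
                     logical(1))
      done <- c(done, active[!keep])
      active <- active[keep]
    }
    placed <- FALSE
    if (length(active)) {
      dd <- vapply(active, function(cl) abs(dg - cl$last_diag), numeric(1))
      j <- which.min(dd)
      if (dd[j] <= band) {
        cl <- active[[j]]
        cl$qmin <- min(cl$qmin, qp); cl$qmax <- max(cl$qmax, qp)
        cl$smin <- min(cl$smin, sp); cl$smax <- max(cl$smax, sp)
        cl$last_spos <- sp; cl$last_diag <- dg
        active[[j]] <- cl
        placed <- TRUE
      }
    }
    if (!placed) {
      active[[length(active) + 1L]] <-
        list(qmin = qp, qmax = qp, smin = sp, smax = sp,
             last_spos = sp, last_diag = dg)
    }
  }
  c(done, active)
}

extend_clusters <- function(q, subj, clusters, k, x_drop, scoring) {
  qlen <- length(q); slen <- length(subj)
  rows <- lapply(clusters, function(cl) {
    qw <- cl$qmax + k - cl$qmin
    pad <- x_drop + k + ceiling(0.1 * qw)
    q_lo <- max(0L, cl$qmin - pad); q_hi <- min(qlen, cl$qmax + k + pad)
    s_lo <- max(0L, cl$smin - pad); s_hi <- min(slen, cl$smax + k + pad)
    aln <- align_local(Biostrings::subseq(q, q_lo + 1L, q_hi),
                       Biostrings::subseq(subj, s_lo + 1L, s_hi), scoring)
    if (aln$score <= 0) return(NULL)
    data.frame(query_id = "", subject_id = "",
               q_start = as.integer(q_lo + aln$a_span[1]),
               q_end = as.integer(q_lo + aln$a_span[2]),
               s_start = as.integer(s_lo + aln$b_span[1]),
               s_end = as.integer(s_lo + aln$b_span[2]),
               strand = "+",
               length = as.integer(aln$b_span[2] - aln$b_span[1]),
               identity = aln$identity, score = aln$score)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(hit_columns())
  do.call(rbind, rows)
}

## drop a hit when another, higher-scoring hit on the same strand overlaps
## it reciprocally by more than 90%
dedup_hits <- function(hits) {
  if (nrow(hits) < 2L) return(hits)
  ord <- order(-hits$score, hits$s_start)
  hits <- hits[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1]) {
    for (j in which(keep[seq_len(i - 1L)])) {
      if (hits$strand[j] != hits$strand[i]) next
      ov <- min(hits$s_end[i], hits$s_end[j]) -
        max(hits$s_start[i], hits$s_start[j])
      if (ov <= 0) next
      wi <- hits$s_end[i] - hits$s_start[i]
      wj <- hits$s_end[j] - hits$s_start[j]
      if (ov > 0.9 * wi && ov > 0.9 * wj) { keep[i] <- FALSE; break }
    }
  }
  hits[keep, , drop = FALSE]
}

#' Filter hits by minimum subject-span length
#'
#' @param hits A hit tibble from [seeded_search()].
#' @param min_length Minimum length (bp); the genome-scan convention keeps
#'   hits of at least 100 bp.
#' @return The retained hits, input order preserved.
#' @export
filter_hits <- function(hits, min_length = 100L) {
  stopifnot(min_length >= 1L)
  hits[hits$length >= min_length, , drop = FALSE]
}

#' Group sequences into families by shared high-scoring segments
#'
#' Runs an all-vs-all seeded search and builds an undirected graph with an
#' edge for every pair of distinct sequences connected by a retained hit.
#' Families are the connected components with at least two members;
#' sequences participating in no hit are reported as singletons.
#'
#' @param seqs A named `DNAStringSet` (>= 2 sequences).
#' @param seed_k,min_identity,min_length,x_drop,scoring Passed to
#'   [seeded_search()].
#' @return A list with `groups` (list of `list(member_ids, evidence)`) and
#'   `singletons` (character vector of ids).
#' @export
all_vs_all_group <- function(seqs, seed_k = 11L, min_identity = 0.75,
                             min_length = 100L, x_drop = 20L,
                             scoring = trim_scoring()) {
  seqs <- as_dna_set(seqs)
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)),
            !anyDuplicated(names(seqs)))
  ids <- names(seqs)
  n <- length(seqs)
  ## k-mer prefilter: only pairs sharing >= 2 exact k-mers (either strand)
  ## are aligned
  kmer_sets <- lapply(seq_len(n), function(i) {
    x <- as.character(seqs[[i]])
    if (nchar(x) < seed_k) return(character())
    st <- seq_len(nchar(x) - seed_k + 1L)
    unique(substring(x, st, st + seed_k - 1L))
  })
  rc_sets <- lapply(kmer_sets, function(km)
    unique(c(km, reverse_complement(km))))
  pairs <- utils::combn(n, 2L)
  edges <- list(); evidence <- list()
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    if (sum(kmer_sets[[i]] %in% rc_sets[[j]]) < 2L) next
    h <- seeded_search(seqs[[i]], seqs[[j]], seed_k = seed_k,
                       min_identity = min_identity, min_length = min_length,
                       x_drop = x_drop, scoring = scoring,
                       query_id = ids[i], subject_id = ids[j])
    if (nrow(h)) {
      edges[[length(edges) + 1L]] <- c(ids[i], ids[j])
      evidence[[length(evidence) + 1L]] <- h
    }
  }
  if (length(edges)) {
    edf <- as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edf, directed = FALSE,
                                       vertices = data.frame(name = ids))
  } else {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = ids)
  }
  comp <- igraph::components(g)
  membership <- comp$membership
  groups <- list()
  for (cid in seq_len(comp$no)) {
    members <- ids[membership == cid]
    if (length(members) < 2L) next
    ev <- evidence[vapply(evidence, function(h)
      h$query_id[1] %in% members, logical(1))]
    groups[[length(groups) + 1L]] <-
      list(member_ids = sort(members),
           evidence = if (length(ev)) do.call(rbind, ev) else hit_columns())
  }
  singletons <- ids[membership %in% which(tabulate(membership) == 1L)]
  list(groups = groups, singletons = singletons)
}

#' Write hits as a TSV table
#'
#' BLAST outfmt-6-like layout, but coordinates are 0-based half-open (a
#' header comment documents the convention).
#'
#' @param hits A hit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# trimscape hits; coordinates 0-based, half-open",
    "# s_start/s_end are forward-strand subject coordinates; strand '-' means the query matched the reverse complement of the span"),
    con)
  utils::write.table(as.data.frame(hits), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
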