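#' Search options
#'
#' Options controlling the accept/reject search loop.
#'
#' @param id identity threshold in \[0, 1\].
#' @param iddef identity definition (see [compute_identity]).
#' @param maxaccepts stop after this many accepted targets (default 1;
#'   0 = unlimited).
#' @param maxrejects stop after this many rejected candidates (default 32;
#'   0 = unlimited).
#' @param strand `"plus"` or `"both"` (query also searched as its reverse
#'   complement; the best orientation is reported, ties resolved in favour
#'   of plus).
#' @param self exclude a target whose label equals the query's.
#' @param minqsize skip queries with abundance below this.
#' @param maxgaps reject alignments with more internal gap columns
#'   (`Inf` = unlimited).
#' @param maxsubs reject alignments with more mismatches (`Inf` =
#'   unlimited).
#' @param top_hits_only keep only hits sharing the best identity.
#' @param maxhits cap on reported hits per query (`Inf` = unlimited).
#' @param wordlength word length for the candidate filter.
#' @param minwordmatches minimum shared words for a candidate (automatically
#'   lowered for queries with fewer unique words).
#' @param qmask masking applied to query sequences before word extraction.
#' @param params an [align_params] scoring set.
#' @return list of class `amp_search_opts`.
#' @export
search_options <- function(id = 0, iddef = 2, maxaccepts = 1, maxrejects = 32,
                           strand = c("plus", "both"), self = FALSE,
                           minqsize = 1, maxgaps = Inf, maxsubs = Inf,
                           top_hits_only = FALSE, maxhits = Inf,
                           wordlength = 8, minwordmatches = 10,
                           qmask = c("dust", "none", "soft"),
                           params = align_params()) {
  if (id < 0 || id > 1) stop("id must be in [0, 1]")
  opts <- list(id = id, iddef = iddef, maxaccepts = maxaccepts,
               maxrejects = maxrejects, strand = match.arg(strand),
               self = self, minqsize = minqsize, maxgaps = maxgaps,
               maxsubs = maxsubs, top_hits_only = top_hits_only,
               maxhits = maxhits, wordlength = wordlength,
               minwordmatches = minwordmatches, qmask = match.arg(qmask),
               params = params)
  class(opts) <- "amp_search_opts"
  opts
}

empty_hits <- function() {
  data.frame(query = character(0), target = character(0),
             query_ord = integer(0), target_ord = integer(0),
             id = numeric(0), strand = character(0), score = numeric(0),
             alnlen = numeric(0), mism = numeric(0), gaps = numeric(0),
             qlo = numeric(0), qhi = numeric(0), tlo = numeric(0),
             thi = numeric(0), cigar = character(0),
             stringsAsFactors = FALSE)
}

hit_row <- function(qrec, db, t, aln, id, strand) {
  data.frame(query = qrec$label, target = db$label[t],
             query_ord = qrec$ordinal, target_ord = t - 1L,
             id = id, strand = strand, score = aln$score,
             alnlen = aln$columns, mism = aln$mismatches,
             gaps = aln$internal_gap_columns,
             qlo = aln$qlo, qhi = aln$qhi, tlo = aln$tlo, thi = aln$thi,
             cigar = aln$cigar, stringsAsFactors = FALSE)
}

# the accept/reject loop for one query orientation against one database;
# candidates are visited in rank_candidates order, pre-filtered, aligned,
# post-filtered, and accepted iff identity >= id.  The loop stops after
# maxaccepts acceptances or maxrejects rejections (0 = unlimited).
search_one <- function(qseq, qrec, db, index, opts, strand = "+",
                       exclude = integer(0)) {
  qmasked <- mask_sequences(qseq, opts$qmask)
  words <- unique_words(qmasked, index$k, honor_case = opts$qmask != "none")
  minw <- effective_min_word_matches(words, opts$minwordmatches)
  counts <- count_shared_words(words, index)
  cand <- rank_candidates(counts, index$target_lengths, minw)
  hits <- list()
  accepts <- 0L
  rejects <- 0L
  for (t in cand) {
    if (t %in% exclude) next
    if (opts$self && identical(db$label[t], qrec$label)) next
    aln <- global_align(qseq, db$sequence[t], opts$params)
    id <- compute_identity(aln, opts$iddef)
    rejected <- aln$internal_gap_columns > opts$maxgaps ||
      aln$mismatches > opts$maxsubs || id < opts$id
    if (rejected) {
      rejects <- rejects + 1L
      if (opts$maxrejects > 0 && rejects >= opts$maxrejects) break
    } else {
      accepts <- accepts + 1L
      hits[[length(hits) + 1L]] <- hit_row(qrec, db, t, aln, id, strand)
      if (opts$maxaccepts > 0 && accepts >= opts$maxaccepts) break
    }
  }
  if (length(hits)) do.call(rbind, hits) else empty_hits()
}

sort_hits <- function(h) {
  if (!nrow(h)) return(h)
  h <- h[order(-h$id, h$target_ord, h$strand != "+"), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Heuristic global-alignment search of queries against a database
#'
#' For each query, candidate targets are ranked by shared-word counts and
#' visited in order; each candidate is globally aligned and accepted iff
#' its identity meets the threshold. The loop stops after `maxaccepts`
#' acceptances or `maxrejects` rejections. Hits per query are sorted by
#' identity descending (ties: target ordinal ascending).
#'
#' @param queries query [amp_records].
#' @param db database [amp_records].
#' @param opts a [search_options] object.
#' @param index optional prebuilt `amp_word_index` over `db` (built on the
#'   fly otherwise).
#' @return data frame of hits (one row per query-target acceptance) with
#'   identity, alignment statistics and coordinates.
#' @export
usearch_global <- function(queries, db, opts = search_options(),
                           index = NULL) {
  if (is.null(index))
    index <- build_word_index(db, k = opts$wordlength, mask = opts$qmask)
  out <- lapply(seq_len(nrow(queries)), function(qi) {
    qrec <- queries[qi, ]
    if (qrec$abundance < opts$minqsize) return(empty_hits())
    hits <- search_one(qrec$sequence, qrec, db, index, opts, "+")
    if (opts$strand == "both") {
      rc <- reverse_complement(qrec$sequence)
      hm <- search_one(rc, qrec, db, index, opts, "-")
      hits <- rbind(hits, hm)
      if (nrow(hits)) {
        # best orientation per target; ties favour plus
        hits <- hits[order(hits$target_ord, -hits$id, hits$strand != "+"), ,
                     drop = FALSE]
        hits <- hits[!duplicated(hits$target_ord), , drop = FALSE]
      }
    }
    hits <- sort_hits(hits)
    if (opts$top_hits_only && nrow(hits))
      hits <- hits[hits$id == max(hits$id), , drop = FALSE]
    if (nrow(hits) > opts$maxhits) hits <- hits[seq_len(opts$maxhits), ,
                                                drop = FALSE]
    hits
  })
  res <- do.call(rbind, c(list(empty_hits()), out))
  rownames(res) <- NULL
  res
}

#' Exact full-length search
#'
#' Hits are the database records whose normalised full-length sequence
#' (U to T, case-insensitive) equals the query's; identity is 1 by
#' construction. Uses a hash lookup, no alignment.
#'
#' @inheritParams usearch_global
#' @return hit data frame as for [usearch_global].
#' @export
search_exact <- function(queries, db) {
  tab <- new.env(parent = emptyenv(), hash = TRUE)
  keys <- norm_seq(db$sequence)
  for (t in seq_len(nrow(db))) tab[[keys[t]]] <- c(tab[[keys[t]]], t)
  out <- lapply(seq_len(nrow(queries)), function(qi) {
    qrec <- queries[qi, ]
    targets <- tab[[norm_seq(qrec$sequence)]]
    if (is.null(targets)) return(empty_hits())
    rows <- lapply(targets, function(t) {
      aln <- global_align(qrec$sequence, db$sequence[t])
      hit_row(qrec, db, t, aln, 1, "+")
    })
    sort_hits(do.call(rbind, rows))
  })
  res <- do.call(rbind, c(list(empty_hits()), out))
  rownames(res) <- NULL
  res
}

#' All-vs-all global alignment
#'
#' Every unordered pair of records is aligned optimally (no word-count
#' heuristic and no reject limit); pairs with identity at or above the
#' threshold are reported.
#'
#' @param records an [amp_records] object (at least 2 rows).
#' @param opts a [search_options] object; only `id`, `iddef` and `params`
#'   are used.
#' @return hit data frame; `query` is the earlier record of each pair.
#' @export
allpairs_global <- function(records, opts = search_options()) {
  n <- nrow(records)
  if (n < 2) stop("allpairs_global needs at least 2 records")
  hits <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- global_align(records$sequence[i], records$sequence[j],
                          opts$params)
      id <- compute_identity(aln, opts$iddef)
      if (id >= opts$id)
        hits[[length(hits) + 1L]] <- hit_row(records[i, ], records, j, aln,
                                             id, "+")
    }
  }
  res <- do.call(rbind, c(list(empty_hits()), hits))
  rownames(res) <- NULL
  res
}
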