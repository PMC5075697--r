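#' Chimera detection options
#'
#' UCHIME-style scoring and candidate-search settings. Parent candidates
#' are found by searching four query segments with `parent_maxaccepts` 4,
#' `parent_maxrejects` 16 and identity threshold 0.55. A candidate parent
#' pair is scored over a three-way alignment: per column the query votes
#' yes when it matches the chimeric model (the best parent on that side of
#' the crossover) and differs from the other parent, no when it differs
#' from the model where the parents differ, abstains otherwise. The score
#' is `h = Y / (xn * (N + dn))`, maximised over crossover positions.
#' Divergence is the percent improvement of the chimeric model over the
#' best single parent. Classification: chimeric when `h >= minh` and
#' `divergence >= mindiv`; borderline when `h >= minh` but divergence is
#' too small; non-chimeric otherwise.
#'
#' @param minh score threshold (default 0.28).
#' @param mindiv minimum divergence percent (default 0.8).
#' @param xn no-vote weight beta (default 8).
#' @param dn no-vote pseudo-count (default 1.4).
#' @param abskew de novo parents must be at least this many times more
#'   abundant than the query (default 2).
#' @param segments number of query segments searched for parents.
#' @param parent_maxaccepts,parent_maxrejects,parent_id segment-search
#'   settings.
#' @param params alignment scoring parameters.
#' @return list of class `amp_chimera_opts`.
#' @export
chimera_options <- function(minh = 0.28, mindiv = 0.8, xn = 8, dn = 1.4,
                            abskew = 2, segments = 4, parent_maxaccepts = 4,
                            parent_maxrejects = 16, parent_id = 0.55,
                            params = align_params()) {
  stopifnot(minh > 0, mindiv > 0, xn > 0, dn > 0, abskew > 0)
  opts <- list(minh = minh, mindiv = mindiv, xn = xn, dn = dn,
               abskew = abskew, segments = segments,
               parent_maxaccepts = parent_maxaccepts,
               parent_maxrejects = parent_maxrejects, parent_id = parent_id,
               params = params)
  class(opts) <- "amp_chimera_opts"
  opts
}

#' Find candidate chimera parents for a query
#'
#' Splits the query into near-equal contiguous segments and searches each
#' against the database; the union of hit targets (minus the query itself
#' and, for de novo, targets not abundant enough under `abskew`) is the
#' candidate parent set. Queries too short to split yield an empty set.
#'
#' @param query a single-row [amp_records].
#' @param db parent database [amp_records].
#' @param opts a [chimera_options] object.
#' @param index optional prebuilt word index over `db`.
#' @param denovo apply the abskew abundance filter.
#' @return integer vector of candidate target rows in `db`.
#' @export
find_parent_candidates <- function(query, db, opts = chimera_options(),
                                   index = NULL, denovo = FALSE) {
  if (!nrow(db)) return(integer(0))
  sopts <- search_options(id = opts$parent_id,
                          maxaccepts = opts$parent_maxaccepts,
                          maxrejects = opts$parent_maxrejects,
                          params = opts$params)
  if (is.null(index))
    index <- build_word_index(db, k = sopts$wordlength, mask = sopts$qmask)
  L <- nchar(query$sequence)
  k <- opts$segments
  if (L < k * index$k) return(integer(0))  # too short to segment usefully
  bounds <- round(seq(0, L, length.out = k + 1))
  cand <- integer(0)
  excl <- which(db$label == query$label & norm_seq(db$sequence) ==
                  norm_seq(query$sequence))
  if (denovo) excl <- union(excl, which(db$abundance <
                                          opts$abskew * query$abundance))
  for (s in seq_len(k)) {
    seg <- substr(query$sequence, bounds[s] + 1, bounds[s + 1])
    segrec <- query
    segrec$sequence <- seg
    segrec$quality <- list(NULL)
    hits <- search_one(seg, segrec, db, index, sopts, "+", exclude = excl)
    cand <- union(cand, hits$target_ord + 1L)
  }
  sort(cand)
}

# merge query<->A and query<->B pairwise alignments on query coordinates
# ("once a gap, always a gap" on the query); rows over the common columns
# decompose the query<->target alignment onto query coordinates: the
# target char at each query position plus insertion slots between them
qp_decompose <- function(qseq, tseq, params) {
  aln <- global_align(qseq, tseq, params)
  Lq <- nchar(qseq)
  ops <- expand_cigar(aln$cigar)
  cols <- rep("-", Lq)
  slots <- vector("list", Lq + 1)
  qi <- 0; ti <- 0
  tchars <- strsplit(tseq, "")[[1]]
  for (k in seq_along(ops$op)) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op == "M") {
      cols[(qi + 1):(qi + len)] <- tchars[(ti + 1):(ti + len)]
      qi <- qi + len; ti <- ti + len
    } else if (op == "D") {  # target chars against query gaps
      slots[[qi + 1]] <- tchars[(ti + 1):(ti + len)]
      ti <- ti + len
    } else qi <- qi + len    # I: query char against target gap
  }
  list(cols = cols, slots = slots)
}

three_way_alignment <- function(qseq, aseq, bseq, params,
                                deca = NULL, decb = NULL) {
  Lq <- nchar(qseq)
  da <- if (is.null(deca)) qp_decompose(qseq, aseq, params) else deca
  db_ <- if (is.null(decb)) qp_decompose(qseq, bseq, params) else decb
  ins <- pmax(lengths(da$slots), lengths(db_$slots))
  qchars <- strsplit(qseq, "")[[1]]
  pad <- function(v, w) c(v, rep("-", w - length(v)))
  qrow <- arow <- brow <- character(0)
  for (p in 0:Lq) {
    if (ins[p + 1]) {
      qrow <- c(qrow, rep("-", ins[p + 1]))
      arow <- c(arow, pad(da$slots[[p + 1]], ins[p + 1]))
      brow <- c(brow, pad(db_$slots[[p + 1]], ins[p + 1]))
    }
    if (p < Lq) {
      qrow <- c(qrow, qchars[p + 1])
      arow <- c(arow, da$cols[p + 1])
      brow <- c(brow, db_$cols[p + 1])
    }
  }
  list(q = chartr("U", "T", toupper(qrow)),
       a = chartr("U", "T", toupper(arow)),
       b = chartr("U", "T", toupper(brow)))
}

three_way_identity <- function(x, y) {
  keep <- !(x == "-" & y == "-")
  if (!any(keep)) return(0)
  sum(x[keep] == y[keep] & x[keep] != "-") / sum(keep)
}

#' Score a candidate parent pair for one query
#'
#' Builds the three-way alignment of the query with two candidate parents
#' and evaluates the chimeric model at every crossover position, in both
#' parent orders. See [chimera_options] for the vote and score
#' definitions.
#'
#' @param qseq,aseq,bseq query and parent sequences (strings).
#' @param opts a [chimera_options] object.
#' @return list of class `amp_chimera_eval`: best `h`, `divergence`
#'   (percent), vote counts at the best crossover, crossover column, parent
#'   order, identities, and the `classification`.
#' @export
score_chimera <- function(qseq, aseq, bseq, opts = chimera_options(),
                          deca = NULL, decb = NULL) {
  tw <- three_way_alignment(qseq, aseq, bseq, opts$params, deca, decb)
  q <- tw$q; a <- tw$a; b <- tw$b
  nc <- length(q)
  # votes with parent A (resp. B) as the model
  yesA <- q == a & q != b
  noA <- q != a & a != b
  yesB <- q == b & q != a
  noB <- q != b & a != b
  cyA <- cumsum(yesA); cnA <- cumsum(noA)
  cyB <- cumsum(yesB); cnB <- cumsum(noB)
  best <- list(h = 0, crossover = 0L, first = "A", Y = 0, N = 0, A = nc)
  for (first in c("A", "B")) {
    # model = `first` parent up to the crossover column, the other after
    Yl <- if (first == "A") cyA else cyB
    Yr <- if (first == "A") cyB[nc] - cyB else cyA[nc] - cyA
    Y <- Yl + Yr
    N <- if (first == "A") cnA + (cnB[nc] - cnB) else cnB + (cnA[nc] - cnA)
    h <- Y / (opts$xn * (N + opts$dn))
    # a crossover is only evidence of chimerism when the query follows
    # each parent on its own side: no yes-votes on either side means the
    # "model" is just one parent, not a chimera
    h[Yl == 0 | Yr == 0] <- 0
    i <- which.max(h)
    if (h[i] > best$h)
      best <- list(h = h[i], crossover = i, first = first,
                   Y = Y[i], N = N[i], A = nc - Y[i] - N[i])
  }
  cross <- best$crossover
  id_qa <- three_way_identity(q, a)
  id_qb <- three_way_identity(q, b)
  if (cross > 0) {
    model <- if (best$first == "A") c(a[seq_len(cross)], b[-seq_len(cross)])
             else c(b[seq_len(cross)], a[-seq_len(cross)])
    id_qm <- three_way_identity(q, model)
    divergence <- 100 * (id_qm - max(id_qa, id_qb))
  } else {  # no crossover with support on both sides: no chimeric model
    id_qm <- max(id_qa, id_qb)
    divergence <- 0
  }
  classification <- if (best$h >= opts$minh && divergence >= opts$mindiv)
    "chimeric"
  else if (best$h >= opts$minh) "borderline"
  else "non-chimeric"
  out <- list(h = best$h, divergence = divergence, crossover = cross,
              parent_order = best$first, yes = best$Y, no = best$N,
              abstain = best$A, id_query_model = id_qm,
              id_query_parent_a = id_qa, id_query_parent_b = id_qb,
              classification = classification, columns = nc)
  class(out) <- "amp_chimera_eval"
  out
}

#' @export
print.amp_chimera_eval <- function(x, ...) {
  cat("amp_chimera_eval:", x$classification, " h =", round(x$h, 4),
      " divergence =", round(x$divergence, 3), "%\n")
  invisible(x)
}

non_chimera_eval <- function() {
  list(h = 0, divergence = 0, crossover = 0, parent_order = NA_character_,
       yes = 0, no = 0, abstain = 0, id_query_model = NA_real_,
       id_query_parent_a = NA_real_, id_query_parent_b = NA_real_,
       classification = "non-chimeric", columns = 0)
}

# evaluate one query against a database of potential parents; returns the
# best-scoring evaluation plus the chosen parent labels
evaluate_query <- function(query, db, opts, index, denovo) {
  cand <- find_parent_candidates(query, db, opts, index, denovo)
  if (length(cand) < 2) {
    ev <- non_chimera_eval()
    ev$parent_a <- ev$parent_b <- NA_character_
    return(ev)
  }
  decs <- lapply(cand, function(t)
    qp_decompose(query$sequence, db$sequence[t], opts$params))
  best <- NULL
  for (i in seq_len(length(cand) - 1)) {
    for (j in (i + 1):length(cand)) {
      ev <- score_chimera(query$sequence, db$sequence[cand[i]],
                          db$sequence[cand[j]], opts,
                          deca = decs[[i]], decb = decs[[j]])
      if (is.null(best) || ev$h > best$h) {
        best <- ev
        best$parent_a <- db$label[cand[i]]
        best$parent_b <- db$label[cand[j]]
      }
    }
  }
  best
}

chimera_report <- function(queries, evals) {
  data.frame(
    score = vapply(evals, function(e) e$h, numeric(1)),
    query = queries$label,
    parent_a = vapply(evals, function(e) e$parent_a, character(1)),
    parent_b = vapply(evals, function(e) e$parent_b, character(1)),
    divergence = vapply(evals, function(e) e$divergence, numeric(1)),
    yes = vapply(evals, function(e) as.numeric(e$yes), numeric(1)),
    no = vapply(evals, function(e) as.numeric(e$no), numeric(1)),
    abstain = vapply(evals, function(e) as.numeric(e$abstain), numeric(1)),
    verdict = vapply(evals, function(e)
      switch(e$classification, chimeric = "Y", borderline = "B", "N"),
      character(1)),
    stringsAsFactors = FALSE)
}

#' De novo chimera detection
#'
#' Processes records in abundance-descending order, testing each against
#' the previously seen (more abundant) records as potential parents;
#' parents must be at least `abskew` times more abundant than the query.
#'
#' @param records input [amp_records] with abundances.
#' @param opts a [chimera_options] object.
#' @return list of class `amp_chimera_result`: `chimeras`, `nonchimeras`,
#'   `borderline` record sets (a partition of the input) and a tabular
#'   `report` (score, query, parents, divergence, vote counts, verdict).
#' @export
uchime_denovo <- function(records, opts = chimera_options()) {
  ord <- order(-records$abundance, records$ordinal)
  proc <- records[ord, , drop = FALSE]
  index <- build_word_index(amp_records(character(0)))
  evals <- vector("list", nrow(proc))
  for (i in seq_len(nrow(proc))) {
    seen <- proc[seq_len(i - 1), , drop = FALSE]
    evals[[i]] <- evaluate_query(proc[i, ], seen, opts, index, denovo = TRUE)
    index_add_sequence(index, proc$sequence[i])
  }
  chimera_result(proc, evals)
}

#' Reference-based chimera detection
#'
#' Tests each record against a reference database (a reference identical
#' to the query is excluded as its own parent).
#'
#' @param records query [amp_records].
#' @param db reference [amp_records].
#' @inheritParams uchime_denovo
#' @return as [uchime_denovo].
#' @export
uchime_ref <- function(records, db, opts = chimera_options()) {
  index <- build_word_index(db)
  evals <- lapply(seq_len(nrow(records)), function(i)
    evaluate_query(records[i, ], db, opts, index, denovo = FALSE))
  chimera_result(records, evals)
}

chimera_result <- function(records, evals) {
  cls <- vapply(evals, function(e) e$classification, character(1))
  out <- list(chimeras = records[cls == "chimeric", , drop = FALSE],
              nonchimeras = records[cls == "non-chimeric", , drop = FALSE],
              borderline = records[cls == "borderline", , drop = FALSE],
              classification = cls,
              report = chimera_report(records, evals),
              evals = evals)
  class(out) <- "amp_chimera_result"
  out
}

#' @export
print.amp_chimera_result <- function(x, ...) {
  cat("amp_chimera_result:", nrow(x$chimeras), "chimeric,",
      nrow(x$borderline), "borderline,", nrow(x$nonchimeras),
      "non-chimeric\n")
  invisible(x)
}
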