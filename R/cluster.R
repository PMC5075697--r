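#' Greedy centroid-based clustering
#'
#' De novo clustering with an identity threshold. Sequences are processed
#' in the chosen order (`smallmem`: input order; `fast`: length
#' descending; `size`: abundance descending) and each is searched against
#' the database of existing centroids. If at least one centroid is
#' accepted at the threshold the query joins the accepted centroid with
#' the highest identity (distance-based greedy clustering, DGC) or, with
#' `sizeorder = TRUE`, the most abundant accepted centroid
#' (abundance-based greedy clustering, AGC); otherwise the query becomes a
#' new centroid. Clusters are numbered by centroid creation order.
#'
#' @param records input [amp_records].
#' @param id identity threshold in \[0, 1\] (e.g. 0.97).
#' @param mode input ordering: `"smallmem"`, `"fast"` or `"size"`.
#' @param sizeorder join the most abundant accepted centroid (AGC) instead
#'   of the most similar (DGC). Meaningful when `maxaccepts > 1`.
#' @param opts a [search_options] object for the centroid search
#'   (its `id` is overridden by `id`).
#' @param threads accepted for interface compatibility; clustering is
#'   sequential and its result is independent of the value.
#' @return object of class `amp_clusters`: list with `clusters` (each
#'   holding centroid row, member rows, per-member hits and total
#'   abundance), the processed `records`, and the assignment table.
#' @export
cluster_records <- function(records, id, mode = c("smallmem", "fast", "size"),
                            sizeorder = FALSE, opts = search_options(),
                            threads = 1) {
  mode <- match.arg(mode)
  opts$id <- id
  ord <- switch(mode,
    smallmem = seq_len(nrow(records)),
    fast = order(-nchar(records$sequence), -records$abundance,
                 records$ordinal),
    size = order(-records$abundance, -nchar(records$sequence),
                 records$ordinal))
  proc <- records[ord, , drop = FALSE]

  index <- build_word_index(amp_records(character(0)), k = opts$wordlength,
                            mask = opts$qmask)
  centroid_rows <- integer(0)      # row in `proc` of each centroid
  assign_to <- integer(nrow(proc)) # cluster number per processed row
  member_hits <- vector("list", nrow(proc))

  for (i in seq_len(nrow(proc))) {
    qrec <- proc[i, ]
    hits <- if (length(centroid_rows))
      search_one(qrec$sequence, qrec, proc[centroid_rows, , drop = FALSE],
                 index, opts, "+")
    else empty_hits()
    if (nrow(hits)) {
      hits <- sort_hits(hits)
      pick <- if (sizeorder) {
        ab <- proc$abundance[centroid_rows[hits$target_ord + 1L]]
        which(ab == max(ab))[1]  # hits are id-sorted: ties keep best id
      } else 1L
      cl <- hits$target_ord[pick] + 1L
      assign_to[i] <- cl
      member_hits[[i]] <- hits[pick, , drop = FALSE]
    } else {
      centroid_rows <- c(centroid_rows, i)
      cl <- length(centroid_rows)
      assign_to[i] <- cl
      index_add_sequence(index, qrec$sequence)
    }
  }

  clusters <- lapply(seq_along(centroid_rows), function(cl) {
    rows <- setdiff(which(assign_to == cl), centroid_rows[cl])
    list(centroid = centroid_rows[cl], members = rows,
         hits = do.call(rbind, c(list(empty_hits()), member_hits[rows])),
         total_abundance = sum(proc$abundance[c(centroid_rows[cl], rows)]))
  })
  out <- list(clusters = clusters, records = proc, mode = mode, id = id,
              sizeorder = sizeorder,
              assignment = data.frame(label = proc$label,
                                      ordinal = proc$ordinal,
                                      cluster = assign_to,
                                      stringsAsFactors = FALSE))
  class(out) <- "amp_clusters"
  out
}

#' @export
print.amp_clusters <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) 1L + length(cl$members),
                  integer(1))
  cat("amp_clusters:", length(x$clusters), "clusters from", nrow(x$records),
      "records (id >=", x$id, ", mode", x$mode,
      if (x$sizeorder) ", AGC" else ", DGC", ")\n")
  cat("  cluster sizes:", paste(utils::head(sort(sizes, decreasing = TRUE),
                                            10), collapse = " "),
      if (length(sizes) > 10) "..." else "", "\n")
  invisible(x)
}

#' Centroid records of a clustering
#'
#' @param x an `amp_clusters` object.
#' @param sizeout replace abundances with accumulated cluster abundances.
#' @return [amp_records] of centroids in cluster order.
#' @export
cluster_centroids <- function(x, sizeout = TRUE) {
  rows <- vapply(x$clusters, function(cl) cl$centroid, integer(1))
  out <- x$records[rows, , drop = FALSE]
  if (sizeout)
    out$abundance <- vapply(x$clusters, function(cl)
      as.integer(cl$total_abundance), integer(1))
  rownames(out) <- NULL
  reindex(out)
}

#' Center-star multiple alignment and consensus of one cluster
#'
#' Merges the member-to-centroid pairwise alignments on the centroid
#' coordinate ("once a gap, always a gap"), producing equal-length rows,
#' an abundance-weighted majority consensus (ties resolved by the fixed
#' symbol order A < C < G < T < gap) and a per-column symbol count
#' profile.
#'
#' @param x an `amp_clusters` object.
#' @param cluster 1-based cluster number.
#' @param params alignment scoring parameters.
#' @return list with `msa` (named character vector of aligned rows,
#'   centroid first), `consensus` (gap-free consensus string),
#'   `consensus_aligned` (with gap columns kept) and `profile` (symbol x
#'   column count matrix, abundance-weighted).
#' @export
center_star_msa <- function(x, cluster, params = align_params()) {
  cl <- x$clusters[[cluster]]
  cen <- x$records$sequence[cl$centroid]
  members <- cl$members
  L <- nchar(cen)
  alns <- lapply(members, function(r)
    global_align(x$records$sequence[r], cen, params))

  # decompose one member alignment into per-centroid-position columns and
  # insertion slots: slot p holds member chars aligned against centroid
  # gaps immediately after centroid position p (p = 0..L)
  decompose <- function(qchars, ops) {
    cols <- rep("-", L)
    slots <- vector("list", L + 1)
    pos <- 0; qi <- 0
    for (k in seq_along(ops$op)) {
      op <- ops$op[k]; len <- ops$len[k]
      if (op == "I") {
        slots[[pos + 1]] <- qchars[(qi + 1):(qi + len)]
        qi <- qi + len
      } else if (op == "M") {
        cols[(pos + 1):(pos + len)] <- qchars[(qi + 1):(qi + len)]
        pos <- pos + len; qi <- qi + len
      } else {  # D: centroid char against member gap
        pos <- pos + len
      }
    }
    list(cols = cols, slots = slots)
  }
  dec <- lapply(seq_along(members), function(mi)
    decompose(strsplit(x$records$sequence[members[mi]], "")[[1]],
              expand_cigar(alns[[mi]]$cigar)))
  ins <- integer(L + 1)  # widest insertion per slot ("once a gap, always a gap")
  for (d in dec)
    for (p in seq_len(L + 1)) ins[p] <- max(ins[p], length(d$slots[[p]]))

  assemble <- function(cols, slots) {
    parts <- character(0)
    for (p in 0:L) {
      sl <- slots[[p + 1]]
      parts <- c(parts, c(sl, rep("-", ins[p + 1] - length(sl))),
                 if (p < L) cols[p + 1])
    }
    paste(parts, collapse = "")
  }
  cen_chars <- strsplit(cen, "")[[1]]
  msa <- c(assemble(cen_chars, vector("list", L + 1)),
           vapply(dec, function(d) assemble(d$cols, d$slots), character(1)))
  names(msa) <- x$records$label[c(cl$centroid, members)]

  # abundance-weighted per-column counts and majority consensus;
  # ties resolved by the fixed symbol order A < C < G < T < others < gap
  ab <- x$records$abundance[c(cl$centroid, members)]
  mat <- do.call(rbind, strsplit(chartr("U", "T", toupper(msa)), ""))
  symbols <- sort(unique(as.vector(mat)))
  sym_order <- c(intersect(c("A", "C", "G", "T"), symbols),
                 setdiff(symbols, c("A", "C", "G", "T", "-")),
                 intersect("-", symbols))
  profile <- vapply(seq_len(ncol(mat)), function(j)
    vapply(sym_order, function(s) sum(ab[mat[, j] == s]), numeric(1)),
    numeric(length(sym_order)))
  if (is.null(dim(profile))) profile <- matrix(profile, nrow = 1)
  rownames(profile) <- sym_order
  cons_aln <- paste(sym_order[apply(profile, 2, which.max)], collapse = "")
  list(msa = msa, consensus = gsub("-", "", cons_aln),
       consensus_aligned = cons_aln, profile = profile)
}

expand_cigar <- function(cigar) {
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MDI]", cigar))[[1]]
  list(op = op, len = len)
}
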