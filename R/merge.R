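#' Paired-end merging options
#'
#' @param minovlen minimum overlap length (default 10).
#' @param maxdiffs maximum observed mismatches in the overlap (default 5).
#' @param minmergelen,maxmergelen bounds on the merged length.
#' @param allow_stagger allow staggered pairs (reverse 3' overhang left of
#'   the forward 5' start); overhangs are trimmed before scoring.
#' @param alpha match score for perfect-quality residues (default +4).
#' @param beta mismatch score for perfect-quality residues (default -5).
#' @param qmax_out cap on posterior quality scores (default 41).
#' @return list of class `amp_merge_opts`.
#' @export
merge_options <- function(minovlen = 10, maxdiffs = 5, minmergelen = 1,
                          maxmergelen = Inf, allow_stagger = FALSE,
                          alpha = 4, beta = -5, qmax_out = 41) {
  stopifnot(minovlen >= 1, alpha > 0, beta < 0)
  opts <- list(minovlen = minovlen, maxdiffs = maxdiffs,
               minmergelen = minmergelen, maxmergelen = maxmergelen,
               allow_stagger = allow_stagger, alpha = alpha, beta = beta,
               qmax_out = qmax_out)
  class(opts) <- "amp_merge_opts"
  opts
}

QTAB_MAX <- 93L

# probability that two observed-equal residues are truly the same base,
# assuming uniform 0.25 background frequencies
p_same_true <- function(p1, p2) (1 - p1) * (1 - p2) + p1 * p2 / 3

# probability that two observed-different residues are truly different:
# the complement of the probability the true bases coincide, which needs
# one read in error toward the other's base (p/3 per target base) or both
# in error onto the same third base (2 * p1/3 * p2/3 ways ... = 2 p1 p2/9)
p_diff_true <- function(p1, p2)
  1 - ((1 - p1) * p2 / 3 + (1 - p2) * p1 / 3 + 2 * p1 * p2 / 9)

# per-(q1, q2) score lookup tables, rows/cols indexed from quality 0
merge_score_tables <- function(opts) {
  p <- 10^(-(0:QTAB_MAX) / 10)
  P1 <- outer(p, p, p_same_true)
  Pd <- outer(p, p, p_diff_true)
  list(eq = opts$alpha * P1 + opts$beta * (1 - P1),
       diff = opts$beta * Pd + opts$alpha * (1 - Pd))
}

#' Quality-weighted score of one overlap placement
#'
#' Direct evaluation of the overlap scoring model: per overlapped column
#' with error probabilities p1, p2, an observed-equal column contributes
#' `alpha * P + beta * (1 - P)` with `P = (1-p1)(1-p2) + p1 p2 / 3` (the
#' probability the bases truly match), and an observed-different column
#' contributes `beta * P' + alpha * (1 - P')` with `P'` the probability
#' the true bases differ. Perfect-quality columns therefore contribute
#' exactly alpha (+4) or beta (-5).
#'
#' @param forward forward read: list/row with `sequence` and `quality`.
#' @param reverse_rc reverse-complemented reverse read (qualities already
#'   reversed).
#' @param shift start of `reverse_rc` relative to the forward read's first
#'   base (0-based; negative = staggered).
#' @param opts a [merge_options] object.
#' @return total score of the overlapped columns.
#' @export
overlap_score <- function(forward, reverse_rc, shift, opts = merge_options()) {
  f <- strsplit(norm_seq(forward$sequence[[1]]), "")[[1]]
  r <- strsplit(norm_seq(reverse_rc$sequence[[1]]), "")[[1]]
  fq <- read_quality(forward)
  rq <- read_quality(reverse_rc)
  lo <- max(0, shift)
  hi <- min(length(f), shift + length(r))
  if (hi - lo < 1) stop("overlap at this shift is empty")
  i <- (lo + 1):hi
  p1 <- 10^(-fq[i] / 10)
  p2 <- 10^(-rq[i - shift] / 10)
  eq <- f[i] == r[i - shift]
  P1 <- p_same_true(p1, p2)
  Pd <- p_diff_true(p1, p2)
  sum(ifelse(eq, opts$alpha * P1 + opts$beta * (1 - P1),
             opts$beta * Pd + opts$alpha * (1 - Pd)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Phred vector of a single read given either an amp_records row (list
# column) or a plain list with a numeric `quality`
read_quality <- function(x) {
  q <- x$quality
  if (is.list(q)) q <- q[[1]]
  if (is.null(q)) return(NULL)
  as.integer(q)
}

#' Posterior quality after merging two observations of one base
#'
#' For agreeing observations the posterior error probability is
#' `p1 p2/3 / (1 - p1 - p2 + 4 p1 p2 / 3)`; for disagreeing observations
#' the base with the smaller error probability (p1 <= p2) is kept with
#' posterior `p1 (1 - p2/3) / (p1 + p2 - 4 p1 p2 / 3)`. The returned
#' quality is `round(-10 log10 p)`, capped at `qmax_out`. Agreement never
#' lowers confidence below `max(q1, q2)`; disagreement never raises it.
#'
#' @param q1,q2 the two Phred scores (vectors allowed).
#' @param agree whether the observed bases agree.
#' @param qmax_out output cap.
#' @return integer posterior quality.
#' @export
posterior_quality <- function(q1, q2, agree, qmax_out = 41) {
  pa <- 10^(-q1 / 10)
  pb <- 10^(-q2 / 10)
  lo <- pmin(pa, pb)  # the more reliable observation's error probability
  hi <- pmax(pa, pb)
  p <- ifelse(rep_len(agree, length(lo)),
              (lo * hi / 3) / (1 - lo - hi + 4 * lo * hi / 3),
              lo * (1 - hi / 3) / (lo + hi - 4 * lo * hi / 3))
  q <- round(-10 * log10(p))
  as.integer(pmin(q, qmax_out))
}

#' Merge one read pair
#'
#' Finds the best-scoring ungapped overlap of the forward read and the
#' reverse-complemented reverse read (all placements with overlap at least
#' `minovlen`; score ties go to the smaller overlap), rejects the pair
#' when the overlap has too many observed mismatches, the merged length is
#' out of bounds, or the placement is staggered without `allow_stagger`,
#' and otherwise returns the merged record: non-overlap tails copied
#' verbatim, consensus base per overlapped column (the higher-quality base
#' on disagreement, the forward base on quality ties) with posterior
#' qualities.
#'
#' @param forward,reverse single-row [amp_records] (or lists with
#'   `sequence`/`quality`); both must carry qualities.
#' @param opts a [merge_options] object.
#' @param tables precomputed score tables (internal, for batch use).
#' @return list: `merged` (single-row [amp_records] or `NULL`), `status`
#'   (`"merged"` or a rejection reason), `shift`, `overlap`, `diffs`.
#' @export
merge_pair <- function(forward, reverse, opts = merge_options(),
                       tables = NULL) {
  fq <- read_quality(forward)
  rq0 <- read_quality(reverse)
  if (is.null(fq) || is.null(rq0))
    stop("merging requires FASTQ input with qualities")
  if (is.null(tables)) tables <- merge_score_tables(opts)
  r_rc <- reverse_complement(reverse$sequence[[1]])
  rq <- rev(rq0)
  scan <- .merge_scan_cpp(forward$sequence[[1]], pmin(fq, QTAB_MAX),
                          r_rc, pmin(rq, QTAB_MAX),
                          tables$eq, tables$diff,
                          as.integer(opts$minovlen))
  rejection <- function(status) list(merged = NULL, status = status,
                                     shift = scan$shift %||% NA_integer_,
                                     overlap = scan$overlap %||% 0L,
                                     diffs = scan$diffs %||% NA_integer_)
  if (!scan$found) return(rejection("no overlap of sufficient length"))
  if (scan$staggered && !opts$allow_stagger)
    return(rejection("staggered pair"))
  if (scan$diffs > opts$maxdiffs) return(rejection("too many differences"))

  f <- strsplit(forward$sequence[[1]], "")[[1]]
  r <- strsplit(r_rc, "")[[1]]
  s <- scan$shift
  lo <- max(0, s); hi <- min(length(f), s + length(r))
  i <- (lo + 1):hi
  eq <- norm_seq(f[i]) == norm_seq(r[i - s])  # elementwise via chartr
  q1 <- fq[i]; q2 <- rq[i - s]
  keep_f <- eq | q1 >= q2  # forward base on quality ties
  cons <- ifelse(keep_f, f[i], r[i - s])
  consq <- posterior_quality(q1, q2, eq, opts$qmax_out)
  # tails: left of the overlap from the forward read (non-staggered) and
  # right of it from whichever read extends further
  left_seq <- if (lo > 0) f[seq_len(lo)] else character(0)
  left_q <- if (lo > 0) fq[seq_len(lo)] else integer(0)
  if (s + length(r) > length(f)) {
    right_seq <- r[(hi - s + 1):length(r)]
    right_q <- rq[(hi - s + 1):length(r)]
  } else if (hi < length(f)) {
    right_seq <- f[(hi + 1):length(f)]
    right_q <- fq[(hi + 1):length(f)]
  } else {
    right_seq <- character(0); right_q <- integer(0)
  }
  mseq <- paste(c(left_seq, cons, right_seq), collapse = "")
  mq <- c(left_q, consq, right_q)
  if (nchar(mseq) < opts$minmergelen || nchar(mseq) > opts$maxmergelen)
    return(rejection("merged length out of range"))
  lab <- if (is.data.frame(forward)) forward$label else "merged"
  merged <- amp_records(mseq, label = lab, quality = list(mq))
  list(merged = merged, status = "merged", shift = s,
       overlap = scan$overlap, diffs = scan$diffs)
}

#' Merge a file's worth of read pairs
#'
#' @param forward,reverse [amp_records] of equal length (read i of each is
#'   a pair).
#' @param opts a [merge_options] object.
#' @return list: `merged` records, `notmerged_fwd`/`notmerged_rev`
#'   records, and a per-pair `status` character vector.
#' @export
merge_pairs <- function(forward, reverse, opts = merge_options()) {
  if (nrow(forward) != nrow(reverse))
    stop("forward and reverse files differ in record count")
  tables <- merge_score_tables(opts)
  status <- character(nrow(forward))
  merged <- vector("list", nrow(forward))
  for (i in seq_len(nrow(forward))) {
    res <- merge_pair(forward[i, ], reverse[i, ], opts, tables)
    status[i] <- res$status
    merged[[i]] <- res$merged
  }
  ok <- status == "merged"
  mrec <- if (any(ok)) do.call(rbind, merged[ok]) else amp_records(character(0))
  class(mrec) <- c("amp_records", "data.frame")
  list(merged = reindex(mrec),
       notmerged_fwd = reindex(forward[!ok, , drop = FALSE]),
       notmerged_rev = reindex(reverse[!ok, , drop = FALSE]),
       status = status)
}
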