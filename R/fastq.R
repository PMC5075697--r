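#' Inspect FASTQ quality characters
#'
#' Reports the observed quality character range and guesses the encoding
#' offset: 33 when any character code is below 59; 64 when all codes are
#' at least 64; otherwise the range is ambiguous and 33 is reported (with
#' the ambiguity flagged). Also tabulates the length of the trailing run
#' of the lowest-quality character of each read (low-quality tails).
#'
#' @param records FASTQ [amp_records].
#' @return list of class `amp_fastq_chars`: `min_char`, `max_char`,
#'   `min_code`, `max_code`, `guessed_offset`, `ambiguous`,
#'   `interpretations` (quality ranges under +33 and +64 when ambiguous)
#'   and `tail_lengths` summary.
#' @export
fastq_chars <- function(records) {
  if (!nrow(records) || any(vapply(records$quality, is.null, logical(1))))
    stop("fastq_chars requires FASTQ input")
  # recover raw codes under the +33 convention used at parse time
  codes <- lapply(records$quality, function(q) q + 33L)
  all_codes <- unlist(codes)
  lo <- min(all_codes); hi <- max(all_codes)
  # any code below 59 can only be Phred+33; all codes >= 64 suggests
  # Phred+64; codes from 59 upward are compatible with both encodings
  offset <- if (lo < 59) 33L else if (lo >= 64) 64L else 33L
  tails <- vapply(codes, function(cd) {
    r <- rle(rev(cd))
    if (r$values[1] == lo) r$lengths[1] else 0L
  }, integer(1))
  out <- list(min_char = intToUtf8(lo), max_char = intToUtf8(hi),
              min_code = lo, max_code = hi,
              guessed_offset = offset,
              ambiguous = lo >= 59,
              interpretations = list(
                phred33 = c(lo - 33L, hi - 33L),
                phred64 = if (lo >= 64) c(lo - 64L, hi - 64L) else NULL),
              tail_lengths = summary(tails))
  class(out) <- "amp_fastq_chars"
  out
}

#' @export
print.amp_fastq_chars <- function(x, ...) {
  cat("quality characters '", x$min_char, "' (", x$min_code, ") to '",
      x$max_char, "' (", x$max_code, ")\n", sep = "")
  cat("guessed offset: +", x$guessed_offset,
      if (x$ambiguous) " (range compatible with more than one encoding)",
      "\n", sep = "")
  invisible(x)
}

#' Expected errors of a read
#'
#' `EE = sum_i 10^(-q_i / 10)`: the expected number of erroneous bases
#' given the Phred scores. Additive over concatenation; strictly decreases
#' when any quality increases.
#'
#' @param qualities integer vector of Phred scores (or a list of them).
#' @return numeric EE (vector when a list is given); an empty read has
#'   EE 0.
#' @export
expected_errors <- function(qualities) {
  if (is.list(qualities))
    return(vapply(qualities, function(q) sum(10^(-q / 10)), numeric(1)))
  sum(10^(-qualities / 10))
}

#' Per-position quality statistics
#'
#' For each position: number of reads covering it, quartiles of the
#' quality scores and the mean expected error rate. Also tabulates, for
#' each possible truncation length, the fraction of reads (truncated to
#' that length) with EE at or below 1, 0.5 and 0.25 - the information the
#' eestats reports summarise.
#'
#' @param records FASTQ [amp_records].
#' @return list of class `amp_fastq_stats` with `position` and
#'   `ee_by_length` data frames.
#' @export
fastq_stats <- function(records) {
  quals <- records$quality
  if (any(vapply(quals, is.null, logical(1))))
    stop("fastq_stats requires FASTQ input")
  maxlen <- max(lengths(quals))
  qmat <- matrix(NA_real_, nrow = length(quals), ncol = maxlen)
  for (i in seq_along(quals)) qmat[i, seq_along(quals[[i]])] <- quals[[i]]
  pos <- data.frame(
    position = seq_len(maxlen),
    reads = colSums(!is.na(qmat)),
    q25 = apply(qmat, 2, quantile, 0.25, na.rm = TRUE),
    median = apply(qmat, 2, median, na.rm = TRUE),
    q75 = apply(qmat, 2, quantile, 0.75, na.rm = TRUE),
    mean_error = colMeans(10^(-qmat / 10), na.rm = TRUE))
  pmat <- 10^(-qmat / 10)
  pmat[is.na(pmat)] <- 0
  cum_ee <- t(apply(pmat, 1, cumsum))
  if (nrow(pmat) == 1) cum_ee <- matrix(cum_ee, nrow = 1)
  covered <- outer(lengths(quals), seq_len(maxlen), ">=")
  ee <- data.frame(
    length = seq_len(maxlen),
    reads = colSums(covered),
    frac_ee_le_1 = colSums(covered & cum_ee <= 1) / pmax(1, colSums(covered)),
    frac_ee_le_0.5 = colSums(covered & cum_ee <= 0.5) /
      pmax(1, colSums(covered)),
    frac_ee_le_0.25 = colSums(covered & cum_ee <= 0.25) /
      pmax(1, colSums(covered)),
    median_ee = apply(ifelse(covered, cum_ee, NA), 2, median, na.rm = TRUE))
  out <- list(position = pos, ee_by_length = ee, n_reads = length(quals))
  class(out) <- "amp_fastq_stats"
  out
}

#' @export
print.amp_fastq_stats <- function(x, ...) {
  cat("amp_fastq_stats:", x$n_reads, "reads, positions 1..",
      nrow(x$position), "\n")
  print(utils::head(x$position))
  invisible(x)
}

#' Truncate and filter FASTQ reads
#'
#' Criteria are applied per read in a fixed order: strip bases from the
#' ends, truncate at the first position with quality below `truncqual`,
#' truncate to `trunclen` (reads shorter than `trunclen` are discarded),
#' length bounds, maximum N count, then maximum expected errors (absolute
#' and per base) computed on the final truncated read.
#'
#' @param records FASTQ [amp_records].
#' @param trunclen truncate to this length and discard shorter reads.
#' @param truncqual truncate at the first position with quality below this.
#' @param minlen,maxlen length bounds after truncation.
#' @param maxee maximum expected errors.
#' @param maxee_rate maximum expected errors per base.
#' @param maxns maximum number of N symbols.
#' @param stripleft,stripright bases removed from the 5'/3' ends first.
#' @return list with `kept` and `discarded` [amp_records]; together they
#'   partition the input.
#' @export
fastq_filter <- function(records, trunclen = NULL, truncqual = NULL,
                         minlen = 1, maxlen = Inf, maxee = Inf,
                         maxee_rate = Inf, maxns = Inf,
                         stripleft = 0, stripright = 0) {
  n <- nrow(records)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    s <- records$sequence[i]
    q <- records$quality[[i]]
    L <- nchar(s)
    from <- stripleft + 1
    to <- L - stripright
    if (from > to) { keep[i] <- FALSE; next }
    s <- substr(s, from, to)
    if (!is.null(q)) q <- q[from:to]
    if (!is.null(truncqual) && !is.null(q)) {
      cut <- which(q < truncqual)
      if (length(cut)) {
        s <- substr(s, 1, cut[1] - 1)
        q <- q[seq_len(cut[1] - 1)]
      }
    }
    if (!is.null(trunclen)) {
      if (nchar(s) < trunclen) { keep[i] <- FALSE; next }
      s <- substr(s, 1, trunclen)
      q <- q[seq_len(trunclen)]
    }
    L <- nchar(s)
    if (L < minlen || L > maxlen) { keep[i] <- FALSE; next }
    if (lengths(regmatches(s, gregexpr("[Nn]", s))) > maxns) {
      keep[i] <- FALSE; next
    }
    if (!is.null(q)) {
      ee <- expected_errors(q)
      if (ee > maxee || (L > 0 && ee / L > maxee_rate)) {
        keep[i] <- FALSE; next
      }
    }
    records$sequence[i] <- s
    records$quality[[i]] <- q
  }
  list(kept = reindex(records[keep, , drop = FALSE]),
       discarded = reindex(records[!keep, , drop = FALSE]))
}

#' Convert between FASTQ quality encodings
#'
#' Quality values are preserved, re-encoded with the output offset and
#' clamped to `[qmin_out, qmax_out]`. Applied at write time via the
#' `fastq_ascii` argument of [write_fastq]; this function performs the
#' clamping on parsed records.
#'
#' @param records FASTQ [amp_records].
#' @param qmin_out,qmax_out clamp bounds for output qualities.
#' @return records with clamped qualities.
#' @export
fastq_convert <- function(records, qmin_out = 0, qmax_out = 41) {
  records$quality <- lapply(records$quality, function(q)
    if (is.null(q)) NULL else as.integer(pmin(pmax(q, qmin_out), qmax_out)))
  records
}
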