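#' Alignment scoring parameters
#'
#' Affine gap-penalty parameters for global alignment. Gap runs touching
#' either end of the alignment (terminal runs) are priced separately from
#' interior runs; a run of length L costs `open + L * extend`. Defaults
#' (+2 match, -4 mismatch, interior open 20 / extend 2, terminal open 2 /
#' extend 1) follow the conventions of the amplicon search tool family the
#' package interoperates with; all are overridable.
#'
#' @param match match reward (positive).
#' @param mismatch mismatch penalty (negative).
#' @param gap_open_interior_query,gap_open_terminal_query cost of opening a
#'   gap in the query (non-negative).
#' @param gap_open_interior_target,gap_open_terminal_target cost of opening
#'   a gap in the target.
#' @param gap_extend_interior,gap_extend_terminal per-base extension costs.
#' @return a list of class `amp_scoring`.
#' @export
align_params <- function(match = 2, mismatch = -4,
                         gap_open_interior_query = 20,
                         gap_open_terminal_query = 2,
                         gap_open_interior_target = 20,
                         gap_open_terminal_target = 2,
                         gap_extend_interior = 2,
                         gap_extend_terminal = 1) {
  if (match <= mismatch) stop("match reward must exceed mismatch penalty")
  p <- list(match = match, mismatch = mismatch,
            gap_open_interior_query = gap_open_interior_query,
            gap_open_terminal_query = gap_open_terminal_query,
            gap_open_interior_target = gap_open_interior_target,
            gap_open_terminal_target = gap_open_terminal_target,
            gap_extend_interior = gap_extend_interior,
            gap_extend_terminal = gap_extend_terminal)
  if (any(unlist(p[-(1:2)]) < 0)) stop("gap penalties must be >= 0")
  class(p) <- "amp_scoring"
  p
}

# product of lengths above which the linear-memory path is mandatory
LINEAR_SWITCH_PRODUCT <- 25e6

#' Optimal global pairwise alignment
#'
#' Computes the optimal global alignment of two nucleotide sequences under
#' affine gap penalties with separate terminal-gap pricing. Uses a
#' full-matrix dynamic program with traceback; when the product of the
#' sequence lengths exceeds 25,000,000 (two 5,000 bp sequences) a
#' linear-memory divide-and-conquer variant with identical scores is used
#' automatically.
#'
#' Ambiguity handling: N against anything scores 0 and never counts as an
#' identity match; other IUPAC codes whose base sets intersect score as a
#' match but count toward identity only when textually equal after
#' normalisation. Traceback ties prefer diagonal over gap-in-query over
#' gap-in-target, yielding one canonical optimal alignment.
#'
#' @param a query sequence (string).
#' @param b target sequence (string).
#' @param params an [align_params] object.
#' @param method `"auto"` (switch on the length product), `"full"`, or
#'   `"linear"`.
#' @return an object of class `amp_alignment`: score, CIGAR (query-centric
#'   M/D/I), column counts (matches, mismatches, internal/terminal gap
#'   columns, internal gap runs), aligned region bounds (`qlo`..`qhi`,
#'   `tlo`..`thi`) and the two aligned row strings.
#' @examples
#' aln <- global_align("ACGT", "AGGT")
#' aln$matches    # 3
#' aln$mismatches # 1
#' @export
global_align <- function(a, b, params = align_params(),
                         method = c("auto", "full", "linear")) {
  method <- match.arg(method)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  linear <- switch(method,
                   auto = as.double(nchar(a)) * nchar(b) > LINEAR_SWITCH_PRODUCT,
                   full = FALSE,
                   linear = TRUE)
  res <- .align_cpp(a, b, unclass(params), linear)
  res$len_query <- nchar(a)
  res$len_target <- nchar(b)
  res$params <- params
  res$method <- if (linear) "linear" else "full"
  class(res) <- "amp_alignment"
  res
}

#' Linear-memory global alignment
#'
#' Divide-and-conquer global alignment using memory linear in the sequence
#' lengths; identical scores (and an optimal, possibly different,
#' traceback) to [global_align].
#'
#' @inheritParams global_align
#' @return an `amp_alignment` object.
#' @export
global_align_linear <- function(a, b, params = align_params()) {
  global_align(a, b, params, method = "linear")
}

#' @export
print.amp_alignment <- function(x, ...) {
  cat("amp_alignment (", x$method, " DP): score ", x$score, ", ",
      x$columns, " columns, ", x$matches, " matches, ", x$mismatches,
      " mismatches, cigar ", x$cigar, "\n", sep = "")
  cat("  identity (iddef 2): ", round(compute_identity(x), 4), "\n", sep = "")
  invisible(x)
}

#' Percent identity of an alignment under a chosen definition
#'
#' \describe{
#'   \item{iddef 0}{matches / length of the shorter sequence}
#'   \item{iddef 1}{matches / alignment columns}
#'   \item{iddef 2 (default)}{matches / (columns - terminal gap columns)}
#'   \item{iddef 3}{matches / (matches + mismatches + internal gap runs)}
#'   \item{iddef 4}{matches / columns (BLAST style, all gap columns
#'     counted)}
#' }
#' A zero denominator yields identity 0.
#'
#' @param result an `amp_alignment` object.
#' @param iddef identity definition, 0..4.
#' @param len_a,len_b sequence lengths (taken from `result` when omitted).
#' @return fraction in \[0, 1\].
#' @export
compute_identity <- function(result, iddef = 2, len_a = result$len_query,
                             len_b = result$len_target) {
  den <- switch(as.character(iddef),
    "0" = min(len_a, len_b),
    "1" = result$columns,
    "2" = result$columns - result$terminal_gap_columns,
    "3" = result$matches + result$mismatches + result$internal_gap_runs,
    "4" = result$columns,
    stop("iddef must be in 0..4"))
  if (den <= 0) return(0)
  result$matches / den
}

#' Render a pairwise alignment as text
#'
#' @param aln an `amp_alignment` object.
#' @param qname,tname sequence names for the margin.
#' @param width characters of alignment per block.
#' @return character vector of lines.
#' @export
render_alignment <- function(aln, qname = "Query", tname = "Target",
                             width = 60) {
  q <- aln$qrow; t <- aln$trow
  n <- nchar(q)
  mid <- paste(ifelse(strsplit(q, "")[[1]] == strsplit(t, "")[[1]] &
                        strsplit(q, "")[[1]] != "-", "|", " "), collapse = "")
  out <- character(0)
  for (s in seq(1, max(n, 1), by = width)) {
    e <- min(s + width - 1, n)
    out <- c(out,
             sprintf("%6s  %s", qname, substr(q, s, e)),
             sprintf("%6s  %s", "", substr(mid, s, e)),
             sprintf("%6s  %s", tname, substr(t, s, e)), "")
  }
  out
}
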