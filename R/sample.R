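# run an expression under a locally seeded, platform-stable RNG
# (Mersenne-Twister with rejection sampling); seed 0 draws a seed from the
# clock, any other seed gives an identical stream on every platform
with_rng <- function(seed, expr) {
  if (!is.null(seed) && seed == 0) seed <- as.integer(Sys.time()) %% .Machine$integer.max
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  if (!is.null(seed)) set.seed(seed, kind = "Mersenne-Twister",
                               sample.kind = "Rejection")
  expr
}

#' Sort records by length or abundance
#'
#' Stable sort, descending key; ties keep input order. Idempotent.
#'
#' @param records an [amp_records] object.
#' @param by `"length"` or `"size"` (abundance).
#' @param topn keep at most this many records.
#' @param minsize,maxsize abundance bounds applied before sorting (size
#'   sort only).
#' @return sorted [amp_records].
#' @export
sort_records <- function(records, by = c("length", "size"), topn = Inf,
                         minsize = 1, maxsize = Inf) {
  by <- match.arg(by)
  if (by == "size")
    records <- records[records$abundance >= minsize &
                         records$abundance <= maxsize, , drop = FALSE]
  key <- if (by == "length") nchar(records$sequence) else records$abundance
  out <- records[order(-key, records$ordinal), , drop = FALSE]
  if (nrow(out) > topn) out <- out[seq_len(topn), , drop = FALSE]
  rownames(out) <- NULL
  reindex(out)
}

#' Shuffle records into random order
#'
#' Fisher-Yates permutation; the same seed yields the same permutation on
#' every platform.
#'
#' @param records an [amp_records] object.
#' @param seed RNG seed (0 = time-derived).
#' @param topn keep at most this many records after shuffling.
#' @return permuted [amp_records].
#' @export
shuffle_records <- function(records, seed = 0, topn = Inf) {
  out <- with_rng(seed, records[sample.int(nrow(records)), , drop = FALSE])
  if (nrow(out) > topn) out <- out[seq_len(topn), , drop = FALSE]
  rownames(out) <- NULL
  reindex(out)
}

#' Abundance-aware random subsampling
#'
#' Samples reads uniformly without replacement, as if the records were
#' rereplicated, subsampled and dereplicated again - without ever
#' materialising the expanded read multiset. With `sizein`, the sampling
#' units are reads (record abundances) and each record's output abundance
#' follows the multivariate hypergeometric marginal, realised by a
#' constant-space sequential hypergeometric draw per record; records drawn
#' to abundance zero are omitted. Without `sizein`, the units are records,
#' kept or dropped uniformly. Either a unit count (`size`) or a percentage
#' (`pct`, converted to a count by rounding half up) may be given.
#'
#' @param records an [amp_records] object.
#' @param size number of units to keep.
#' @param pct percentage of units to keep (0..100).
#' @param sizein sample reads (weighted by abundance) rather than records.
#' @param sizeout keep accumulated abundances on output (otherwise output
#'   abundances are reset to 1).
#' @param seed RNG seed (0 = time-derived).
#' @return subsampled [amp_records] in input order.
#' @export
subsample_records <- function(records, size = NULL, pct = NULL,
                              sizein = FALSE, sizeout = TRUE, seed = 0) {
  total <- if (sizein) sum(records$abundance) else nrow(records)
  if (is.null(size)) {
    if (is.null(pct)) stop("give size or pct")
    size <- floor(total * pct / 100 + 0.5)  # round half up
  }
  if (size > total) stop("sample size (", size, ") exceeds the ", total,
                         " available units")
  if (!sizein) {
    keep <- with_rng(seed, sort(sample.int(nrow(records), size)))
    out <- records[keep, , drop = FALSE]
  } else {
    ab <- records$abundance
    out_ab <- integer(length(ab))
    with_rng(seed, {
      remaining <- total
      need <- size
      for (i in seq_along(ab)) {
        # draws for record i given what the earlier records consumed
        k <- if (need == 0) 0L else rhyper(1, ab[i], remaining - ab[i], need)
        out_ab[i] <- k
        need <- need - k
        remaining <- remaining - ab[i]
      }
    })
    out <- records[out_ab > 0, , drop = FALSE]
    out$abundance <- out_ab[out_ab > 0]
  }
  if (!sizeout) out$abundance <- rep(1L, nrow(out))
  rownames(out) <- NULL
  reindex(out)
}
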