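#' Unique k-mer word codes of a sequence
#'
#' All overlapping words of length `k` composed solely of A, C, G, T (after
#' U to T normalisation), encoded base 4 (A=0, C=1, G=2, T=3), duplicates
#' collapsed. Windows containing any other symbol are skipped; when
#' `honor_case = TRUE` lowercase (soft-masked) positions are also excluded.
#' A sequence of length n yields at most n - k + 1 unique words.
#'
#' @param sequence a single sequence string.
#' @param k word length, 3..15 (default 8).
#' @param honor_case exclude lowercase (soft-masked) positions.
#' @return numeric vector of distinct word codes in 0..4^k - 1.
#' @export
unique_words <- function(sequence, k = 8, honor_case = FALSE) {
  check_wordlength(k)
  n <- nchar(sequence)
  if (n < k) return(numeric(0))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  code <- word_base_codes(chars, honor_case)
  nw <- n - k + 1
  w <- numeric(nw)
  valid <- rep(TRUE, nw)
  for (t in 0:(k - 1)) {
    ct <- code[(1 + t):(nw + t)]
    valid <- valid & ct >= 0
    w <- w * 4 + pmax(ct, 0)
  }
  unique(w[valid])
}

# per-base codes: A=0 C=1 G=2 T/U=3, -1 for anything else (or lowercase when
# soft masking is honoured)
word_base_codes <- function(chars, honor_case) {
  lower <- chars %in% c("a", "c", "g", "t", "u")
  up <- chartr("U", "T", toupper(chars))
  code <- match(up, c("A", "C", "G", "T")) - 1
  code[is.na(code)] <- -1
  if (honor_case) code[lower] <- -1
  code
}

check_wordlength <- function(k) {
  if (k < 3 || k > 15) stop("wordlength must be in 3..15")
  invisible(k)
}

#' Build a word index over a database
#'
#' Inverted index from word code to the ordinals (1-based row numbers) of
#' the database records containing that word; each target appears at most
#' once per word. Used to count shared words between a query and every
#' database sequence without aligning.
#'
#' @param records database [amp_records].
#' @param k word length (default 8).
#' @param mask masking applied before indexing: `"none"`, `"dust"`
#'   (low-complexity regions excluded), or `"soft"` (existing lowercase
#'   excluded).
#' @return an object of class `amp_word_index`.
#' @export
build_word_index <- function(records, k = 8, mask = c("dust", "none", "soft")) {
  check_wordlength(k)
  mask <- match.arg(mask)
  idx <- new.env(parent = emptyenv())
  idx$k <- k
  idx$mask <- mask
  idx$postings <- new.env(parent = emptyenv(), hash = TRUE)
  idx$n_targets <- 0L
  idx$target_lengths <- integer(0)
  idx$target_words <- integer(0)
  class(idx) <- "amp_word_index"
  for (i in seq_len(nrow(records)))
    index_add_sequence(idx, records$sequence[i])
  idx
}

# append one target to a word index (reference semantics: the index is an
# environment, so greedy clustering and de novo chimera scans can grow the
# centroid/parent database incrementally)
index_add_sequence <- function(index, sequence) {
  masked <- mask_sequences(sequence, index$mask)
  w <- unique_words(masked, index$k, honor_case = index$mask != "none")
  ord <- index$n_targets + 1L
  p <- index$postings
  for (key in as.character(w)) p[[key]] <- c(p[[key]], ord)
  index$n_targets <- ord
  index$target_lengths <- c(index$target_lengths, nchar(sequence))
  index$target_words <- c(index$target_words, length(w))
  invisible(index)
}

#' @export
print.amp_word_index <- function(x, ...) {
  cat("amp_word_index: k =", x$k, ",", x$n_targets, "targets,",
      length(ls(x$postings)), "distinct words\n")
  invisible(x)
}

#' Count words shared with every database sequence
#'
#' @param query_words word codes from [unique_words] (same k as the index).
#' @param index an `amp_word_index`.
#' @return integer vector of per-target shared-word counts.
#' @export
count_shared_words <- function(query_words, index) {
  if (!length(query_words)) return(integer(index$n_targets))
  hit <- mget(as.character(query_words), envir = index$postings,
              ifnotfound = list(NULL))
  vals <- unlist(hit, use.names = FALSE)
  if (is.null(vals)) return(integer(index$n_targets))
  tabulate(vals, nbins = index$n_targets)
}

#' Rank candidate targets by shared-word count
#'
#' Targets with at least `min_shared` shared words, ordered by count
#' descending, then length ascending, then ordinal ascending (a total
#' order independent of index construction order).
#'
#' @param counts per-target shared-word counts.
#' @param target_lengths per-target sequence lengths.
#' @param min_shared minimum shared words to qualify (>= 1).
#' @return integer vector of target ordinals (1-based), best first.
#' @export
rank_candidates <- function(counts, target_lengths, min_shared = 1) {
  if (min_shared < 1) stop("min_shared must be >= 1")
  keep <- which(counts >= min_shared)
  keep[order(-counts[keep], target_lengths[keep], keep)]
}

#' Effective minimum shared-word threshold
#'
#' The configured `minwordmatches` (default 10), automatically lowered for
#' short or simple queries that contain fewer unique words, with a floor of
#' one.
#'
#' @param query_words word codes of the query.
#' @param configured configured minimum (>= 1).
#' @return integer threshold actually applied.
#' @export
effective_min_word_matches <- function(query_words, configured = 10) {
  if (configured < 1) stop("minwordmatches must be >= 1")
  max(1L, min(configured, length(query_words)))
}
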