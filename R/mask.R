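#' DUST low-complexity masking intervals
#'
#' Tatusov-Lipman DUST: sliding windows of length `window` (step
#' `window/2`); within each window every subinterval ending at each cursor
#' position is scored as `sum_t c_t (c_t - 1) / 2` over its triplet counts
#' `c_t`, divided by (number of triplets - 1). The maximal-scoring
#' subinterval of a window is masked when `10 * score > level`.
#' Overlapping and adjacent intervals are merged. Triplets containing
#' non-ACGT symbols are skipped. Masking is deterministic and
#' position-shift-covariant for sequences embedded in unmasked flanks.
#'
#' @param sequence a single sequence string.
#' @param window window length (classic default 64).
#' @param level masking threshold (classic default 20).
#' @param step window step (default `window / 2`).
#' @return data frame of masked intervals with 0-based half-open `start`,
#'   `end` columns, sorted and non-overlapping.
#' @examples
#' dust_mask(strrep("A", 64))   # fully masked
#' dust_mask("ACGTACCTGGATCCAATGCA")  # typically nothing
#' @export
dust_mask <- function(sequence, window = 64, level = 20, step = window / 2) {
  if (level <= 0) stop("level must be > 0")
  n <- nchar(sequence)
  if (n < 3) return(data.frame(start = integer(0), end = integer(0)))
  code <- word_base_codes(strsplit(sequence, "", fixed = TRUE)[[1]],
                          honor_case = FALSE)
  # triplet code at position i covers bases i..i+2; -1 when invalid
  nt <- n - 2
  tri <- code[1:nt] * 16 + code[2:(nt + 1)] * 4 + code[3:(nt + 2)]
  tri[code[1:nt] < 0 | code[2:(nt + 1)] < 0 | code[3:(nt + 2)] < 0] <- -1
  starts <- seq(1, n, by = step)
  starts <- starts[starts <= max(1, n - 2)]
  iv_s <- integer(0); iv_e <- integer(0)
  for (ws in starts) {
    we <- min(ws + window - 1, n)
    if (we - ws + 1 < 3) next
    best <- 0; bs <- 0L; be <- 0L
    # all subintervals [s, e] of the window, counts updated incrementally
    for (s in ws:(we - 2)) {
      counts <- integer(64)
      raw <- 0
      ntri <- 0L
      for (e in (s + 2):we) {
        tc <- tri[e - 2]
        if (tc >= 0) {
          raw <- raw + counts[tc + 1]
          counts[tc + 1] <- counts[tc + 1] + 1L
          ntri <- ntri + 1L
        }
        if (ntri > 1) {
          sc <- raw / (ntri - 1)
          if (sc > best) { best <- sc; bs <- s; be <- e }
        }
      }
    }
    if (10 * best > level) { iv_s <- c(iv_s, bs); iv_e <- c(iv_e, be) }
  }
  merge_intervals(iv_s - 1L, iv_e)  # to 0-based half-open
}

merge_intervals <- function(s, e) {
  if (!length(s)) return(data.frame(start = integer(0), end = integer(0)))
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) me <- max(me, e[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
  }
  data.frame(start = as.integer(c(out_s, ms)), end = as.integer(c(out_e, me)))
}

#' Apply mask intervals to a sequence
#'
#' @param sequence a single sequence string.
#' @param intervals data frame with 0-based half-open `start`/`end` columns.
#' @param mode `"soft"` (lowercase) or `"hard"` (replace with N).
#' @return masked sequence string (length unchanged).
#' @export
apply_mask <- function(sequence, intervals, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  if (!nrow(intervals)) return(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(intervals))) {
    idx <- (intervals$start[i] + 1):intervals$end[i]
    chars[idx] <- if (mode == "soft") tolower(chars[idx]) else "N"
  }
  paste(chars, collapse = "")
}

# apply the configured masking mode to a vector of sequences; "soft" keeps
# existing lowercase, "none" leaves everything significant
mask_sequences <- function(seqs, mask = c("dust", "none", "soft"),
                           hardmask = FALSE) {
  mask <- match.arg(mask)
  if (mask != "dust") return(seqs)
  vapply(seqs, function(s)
    apply_mask(s, dust_mask(s), mode = if (hardmask) "hard" else "soft"),
    character(1), USE.NAMES = FALSE)
}

#' Mask low-complexity regions in a record set
#'
#' @param records an [amp_records] object.
#' @param mask masking algorithm: `"dust"`, `"soft"` (respect existing
#'   lowercase, i.e. leave sequences unchanged) or `"none"`.
#' @param hardmask replace masked symbols with N instead of lowercasing.
#' @return records with masked sequences.
#' @export
fastx_mask <- function(records, mask = c("dust", "soft", "none"),
                       hardmask = FALSE) {
  mask <- match.arg(mask)
  records$sequence <- mask_sequences(records$sequence, mask, hardmask)
  records
}
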