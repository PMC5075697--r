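#' Sequence record sets
#'
#' The basic container used throughout the package is an `amp_records`
#' object: a data frame with one row per sequence and columns
#' \describe{
#'   \item{label}{first whitespace-delimited token of the header}
#'   \item{desc}{remainder of the header (may be `""`)}
#'   \item{sequence}{nucleotide sequence, case preserved}
#'   \item{quality}{list column of integer Phred scores (`NULL` entries for
#'     FASTA records)}
#'   \item{abundance}{positive integer, the number of reads the record
#'     represents (default 1)}
#'   \item{ordinal}{0-based position in the input stream}
#' }
#'
#' @param sequence character vector of nucleotide sequences.
#' @param label character vector of labels (defaults to `seq1`, `seq2`, ...).
#' @param desc character vector of descriptions.
#' @param quality optional list of integer Phred score vectors, one per
#'   sequence, each the same length as its sequence.
#' @param abundance integer vector of abundances (default 1).
#' @return An `amp_records` data frame.
#' @examples
#' recs <- amp_records(c("ACGT", "GGGA"), label = c("a", "b"))
#' recs
#' @export
amp_records <- function(sequence, label = NULL, desc = NULL,
                        quality = NULL, abundance = NULL) {
  n <- length(sequence)
  if (is.null(label)) label <- if (n) paste0("seq", seq_len(n)) else character(0)
  if (is.null(desc)) desc <- rep("", n)
  if (is.null(abundance)) abundance <- rep(1L, n)
  abundance <- as.integer(abundance)
  if (any(is.na(abundance)) || any(abundance < 1L))
    stop("abundance must be a positive integer")
  if (is.null(quality)) {
    quality <- vector("list", n)
  } else {
    if (length(quality) != n) stop("quality must have one entry per sequence")
    for (i in seq_len(n)) {
      q <- quality[[i]]
      if (!is.null(q)) {
        if (length(q) != nchar(sequence[i]))
          stop("record '", label[i], "': quality length (", length(q),
               ") does not match sequence length (", nchar(sequence[i]), ")")
        if (any(q < 0)) stop("record '", label[i], "': negative quality score")
        quality[[i]] <- as.integer(q)
      }
    }
  }
  out <- data.frame(label = as.character(label), desc = as.character(desc),
                    sequence = as.character(sequence),
                    abundance = abundance,
                    ordinal = if (n) 0:(n - 1L) else integer(0),
                    stringsAsFactors = FALSE)
  out$quality <- quality
  class(out) <- c("amp_records", "data.frame")
  out
}

#' @export
print.amp_records <- function(x, ...) {
  n <- nrow(x)
  has_q <- any(!vapply(x$quality, is.null, logical(1)))
  cat("amp_records: ", n, " sequence", if (n != 1) "s", " (",
      if (has_q) "FASTQ" else "FASTA", "-like), total abundance ",
      sum(x$abundance), "\n", sep = "")
  if (n) {
    show <- utils::head(x, 6)
    for (i in seq_len(nrow(show))) {
      s <- show$sequence[i]
      if (nchar(s) > 40) s <- paste0(substr(s, 1, 40), "...")
      cat(sprintf("  %s (len %d, size %d): %s\n", show$label[i],
                  nchar(show$sequence[i]), show$abundance[i], s))
    }
    if (n > 6) cat("  ...", n - 6, "more\n")
  }
  invisible(x)
}

#' @export
`[.amp_records` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- c("amp_records", "data.frame")
  out
}

# reindex ordinals after subsetting/combining a record set
reindex <- function(records) {
  if (nrow(records)) records$ordinal <- 0:(nrow(records) - 1L)
  records
}

#' Normalise sequences for comparison
#'
#' Uppercases and converts U to T. All sequence comparison in the package
#' (dereplication, exact search, word counting, digests) operates on
#' normalised sequences; stored record text is never altered.
#'
#' @param x character vector.
#' @return normalised character vector.
#' @export
norm_seq <- function(x) chartr("U", "T", toupper(x))

IUPAC_CHARS <- "ACGTURYSWKMBDHVN"
IUPAC_COMP <- "TGCAAYRSWMKVHDBN"

#' Reverse-complement sequence records
#'
#' IUPAC-aware reverse complement; qualities are reversed in step.
#'
#' @param x an `amp_records` object or a character vector of sequences.
#' @return object of the same type with sequences reverse-complemented.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(x) {
  if (inherits(x, "amp_records")) {
    x$sequence <- reverse_complement(x$sequence)
    x$quality <- lapply(x$quality, function(q) if (is.null(q)) NULL else rev(q))
    return(x)
  }
  bad <- grepl(paste0("[^", IUPAC_CHARS, tolower(IUPAC_CHARS), "]"), x)
  if (any(bad))
    stop("non-IUPAC symbol in sequence: ", x[which(bad)[1]])
  from <- paste0(IUPAC_CHARS, tolower(IUPAC_CHARS))
  to <- paste0(IUPAC_COMP, tolower(IUPAC_COMP))
  rev_str(chartr(from, to, x))
}

rev_str <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Parse and strip abundance annotations
#'
#' Parses the USEARCH-style `;size=N` annotation (case-sensitive key,
#' optional trailing semicolon) anywhere in a label.
#'
#' @param header character vector of labels/headers.
#' @param sizein if `FALSE`, annotations are left in place and abundance 1 is
#'   returned for every record.
#' @return list with `label` (annotation stripped when `sizein`) and
#'   `abundance` (integer).
#' @examples
#' parse_abundance("amp1;size=5;", sizein = TRUE)
#' @export
parse_abundance <- function(header, sizein = TRUE) {
  if (!sizein)
    return(list(label = header, abundance = rep(1L, length(header))))
  ab <- rep(1L, length(header))
  has <- grepl(";size=", header, fixed = TRUE)
  if (any(has)) {
    ann <- regmatches(header[has], regexpr(";size=[^;]*;?", header[has]))
    val <- sub("^;size=([^;]*);?$", "\\1", ann)
    num <- suppressWarnings(as.integer(val))
    bad <- !grepl("^[0-9]+$", val) | is.na(num) | num < 1L
    if (any(bad))
      stop("invalid abundance annotation in '", header[has][bad][1], "'")
    ab[has] <- num
  }
  list(label = sub(";size=[^;]*;?", "", header), abundance = ab)
}

# append a ;size= annotation (replacing any existing one)
annotate_size <- function(label, abundance) {
  paste0(sub(";size=[^;]*;?", "", label), ";size=", abundance)
}

#' Relabel with a message digest of the sequence
#'
#' Returns the lowercase hex SHA-1 or MD5 digest of the normalised sequence
#' (U converted to T, all uppercase).
#'
#' @param x an `amp_records` object or character vector of sequences.
#' @param algorithm `"sha1"` or `"md5"`.
#' @return character vector of hex digests (40 chars for sha1, 32 for md5).
#' @export
relabel_digest <- function(x, algorithm = c("sha1", "md5")) {
  algorithm <- match.arg(algorithm)
  s <- if (inherits(x, "amp_records")) x$sequence else x
  if (any(!nzchar(s))) stop("cannot digest an empty sequence")
  vapply(norm_seq(s), function(z)
    digest::digest(z, algo = algorithm, serialize = FALSE),
    character(1), USE.NAMES = FALSE)
}

#' Relabel records
#'
#' Replaces labels with either `<prefix><n>` (sequential) or a message
#' digest of the sequence. Descriptions are preserved.
#'
#' @param records an `amp_records` object.
#' @param prefix label prefix for sequential relabelling.
#' @param digest `NULL`, `"sha1"` or `"md5"`.
#' @return relabelled `amp_records`.
#' @export
relabel <- function(records, prefix = NULL, digest = NULL) {
  if (!is.null(digest)) records$label <- relabel_digest(records, digest)
  else if (!is.null(prefix)) records$label <- paste0(prefix, seq_len(nrow(records)))
  records
}
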