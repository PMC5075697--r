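#' Read FASTA or FASTQ sequences
#'
#' Reads a FASTA or FASTQ file (plain or gzip-compressed; format and
#' compression are auto-detected) into an [amp_records] data frame. Parsing
#' is delegated to \pkg{Biostrings}; quality characters are converted to
#' Phred scores using `fastq_ascii` (33 for modern files, 64 for old
#' Illumina encodings).
#'
#' @param path file path.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @param fastq_ascii quality encoding offset, 33 or 64.
#' @param sizein parse `;size=N` abundance annotations from labels.
#' @return an [amp_records] object, records in file order.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           fastq_ascii = 33, sizein = FALSE) {
  format <- match.arg(format)
  if (!fastq_ascii %in% c(33, 64)) stop("fastq_ascii must be 33 or 64")
  if (format == "auto") format <- detect_format(path)
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                    error = function(e) stop("FASTA parse error in '", path,
                                             "': ", conditionMessage(e)))
    quals <- NULL
  } else {
    validate_fastq(path)
    parsed <- tryCatch({
      set <- Biostrings::readBStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
      list(set = set,
           quals = as.character(S4Vectors::mcols(set)$qualities))
    }, error = function(e) stop("FASTQ parse error in '", path, "': ",
                                conditionMessage(e)))
    set <- parsed$set
    quals <- parsed$quals
  }
  headers <- names(set)
  seqs <- as.character(set)
  if (!length(seqs)) stop("no sequences found in '", path, "'")
  label <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  pa <- parse_abundance(label, sizein)
  quality <- NULL
  if (!is.null(quals)) {
    quality <- lapply(seq_along(quals), function(i) {
      q <- utf8ToInt(quals[i]) - fastq_ascii
      if (length(q) != nchar(seqs[i]))
        stop("FASTQ record '", label[i], "': quality length (", length(q),
             ") does not match sequence length (", nchar(seqs[i]), ")")
      if (any(q < 0))
        stop("FASTQ record '", label[i], "': quality character below the +",
             fastq_ascii, " offset; wrong fastq_ascii?")
      as.integer(q)
    })
  }
  amp_records(seqs, label = pa$label, desc = desc, quality = quality,
              abundance = pa$abundance)
}

# structural well-formedness check for 4-line FASTQ records; malformed
# records are reported by name before any parsing takes place
validate_fastq <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (!length(lines)) stop("empty input: '", path, "'")
  if (length(lines) %% 4 != 0)
    stop("FASTQ parse error in '", path, "': truncated record at end of file")
  idx <- seq(1, length(lines), by = 4)
  bad_at <- !startsWith(lines[idx], "@")
  bad_plus <- !startsWith(lines[idx + 2], "+")
  bad_len <- nchar(lines[idx + 1]) != nchar(lines[idx + 3])
  bad <- which(bad_at | bad_plus | bad_len)
  if (length(bad)) {
    i <- bad[1]
    lab <- sub("^@", "", sub("\\s.*$", "", lines[idx[i]]))
    what <- if (bad_at[i]) "missing '@' header"
            else if (bad_plus[i]) "missing '+' separator"
            else paste0("quality length (", nchar(lines[idx[i] + 3]),
                        ") does not match sequence length (",
                        nchar(lines[idx[i] + 1]), ")")
    stop("FASTQ parse error in record '", lab, "' (record ", i, " of '",
         path, "'): ", what)
  }
  invisible(TRUE)
}

# peek at the first byte (through gzip if needed) to pick the format
detect_format <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  repeat {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (!length(ch) || !nzchar(ch)) stop("empty input: '", path, "'")
    if (!ch %in% c("\n", "\r", " ", "\t")) break
  }
  if (ch == ">") return("fasta")
  if (ch == "@") return("fastq")
  stop("cannot detect format of '", path, "': leading character '", ch, "'")
}

record_headers <- function(records, sizeout = FALSE) {
  label <- records$label
  if (sizeout) label <- annotate_size(label, records$abundance)
  ifelse(nzchar(records$desc), paste(label, records$desc), label)
}

#' Write records as FASTA
#'
#' @param records an [amp_records] object.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param width sequence line width; 0 turns line wrapping off.
#' @param sizeout append `;size=N` abundance annotations to labels.
#' @export
write_fasta <- function(records, path, width = 80, sizeout = FALSE) {
  if (width < 0) stop("width must be >= 0")
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- record_headers(records, sizeout)
  w <- if (width == 0) max(1L, max(nchar(records$sequence))) else width
  Biostrings::writeXStringSet(set, path, format = "fasta", width = w,
                              compress = grepl("\\.gz$", path))
  invisible(records)
}

#' Write records as FASTQ
#'
#' @inheritParams write_fasta
#' @param fastq_ascii quality encoding offset for output, 33 or 64.
#' @export
write_fastq <- function(records, path, sizeout = FALSE, fastq_ascii = 33) {
  if (any(vapply(records$quality, is.null, logical(1))))
    stop("cannot write FASTQ: records lack qualities")
  qstr <- vapply(records$quality, function(q) intToUtf8(q + fastq_ascii),
                 character(1))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- record_headers(records, sizeout)
  qual <- Biostrings::BStringSet(qstr)
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(records)
}

#' Write records in the format they were read in
#'
#' FASTQ when every record carries qualities, FASTA otherwise.
#' @inheritParams write_fasta
#' @param ... passed to [write_fasta] or [write_fastq].
#' @export
write_sequences <- function(records, path, ...) {
  if (nrow(records) && all(!vapply(records$quality, is.null, logical(1))))
    write_fastq(records, path, ...)
  else
    write_fasta(records, path, ...)
}
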