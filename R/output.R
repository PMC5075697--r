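# Tabular result writers: uc (cluster/search), blast6 and userfields.

uc_line <- function(...) paste(c(...), collapse = "\t")

#' Write search hits in uc format
#'
#' Standard 10-column uc records: one H line per hit and one N line per
#' query without hits.
#'
#' @param hits hit data frame from [usearch_global] or [search_exact].
#' @param queries the query [amp_records] the hits came from.
#' @param path output file.
#' @export
write_uc_hits <- function(hits, queries, path) {
  lines <- character(0)
  for (qi in seq_len(nrow(queries))) {
    h <- hits[hits$query_ord == queries$ordinal[qi], , drop = FALSE]
    if (!nrow(h)) {
      lines <- c(lines, uc_line("N", "*", "*", "*", "*", "*", "*", "*",
                                queries$label[qi], "*"))
    } else {
      for (r in seq_len(nrow(h)))
        lines <- c(lines, uc_line("H", h$target_ord[r],
                                  nchar(queries$sequence[qi]),
                                  sprintf("%.1f", 100 * h$id[r]),
                                  h$strand[r], 0, 0, h$cigar[r],
                                  h$query[r], h$target[r]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a clustering in uc format
#'
#' S records for centroids, H records for members, C summary records.
#'
#' @param x an `amp_clusters` object.
#' @param path output file.
#' @export
write_uc_clusters <- function(x, path) {
  lines <- character(0)
  for (cl in seq_along(x$clusters)) {
    c0 <- x$clusters[[cl]]
    cen <- x$records[c0$centroid, ]
    lines <- c(lines, uc_line("S", cl - 1, nchar(cen$sequence), "*", "*",
                              "*", "*", "*", cen$label, "*"))
    h <- c0$hits
    for (r in seq_along(c0$members)) {
      m <- x$records[c0$members[r], ]
      hr <- h[r, ]
      lines <- c(lines, uc_line("H", cl - 1, nchar(m$sequence),
                                sprintf("%.1f", 100 * hr$id), "+", 0, 0,
                                hr$cigar, m$label, cen$label))
    }
  }
  for (cl in seq_along(x$clusters)) {
    c0 <- x$clusters[[cl]]
    cen <- x$records[c0$centroid, ]
    lines <- c(lines, uc_line("C", cl - 1, 1 + length(c0$members), "*",
                              "*", "*", "*", "*", cen$label, "*"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a dereplication in uc format
#'
#' S records for representatives, H records for the records merged into
#' them, C summary records. Uses the `"members"` attribute attached by
#' [derep_fulllength] and [derep_prefix].
#'
#' @param derep dereplicated records carrying a `"members"` attribute.
#' @param records the input records the dereplication was computed from.
#' @param path output file.
#' @export
write_uc_derep <- function(derep, records, path) {
  members <- attr(derep, "members")
  rep_rows <- attr(derep, "rep_rows")
  if (is.null(members)) stop("no members attribute: not a derep result")
  lines <- character(0)
  for (r in seq_len(nrow(derep))) {
    lines <- c(lines, uc_line("S", r - 1, nchar(derep$sequence[r]), "*",
                              "*", "*", "*", "*", derep$label[r], "*"))
    for (m in setdiff(members[[r]], rep_rows[r]))
      lines <- c(lines, uc_line("H", r - 1, nchar(records$sequence[m]),
                                "100.0", "+", 0, 0, "*",
                                records$label[m], derep$label[r]))
  }
  for (r in seq_len(nrow(derep)))
    lines <- c(lines, uc_line("C", r - 1, length(members[[r]]), "*", "*",
                              "*", "*", "*", derep$label[r], "*"))
  writeLines(lines, path)
  invisible(path)
}

#' Write hits in blast6 tabular format
#'
#' 12 columns; identity as a percentage with one decimal; the e-value and
#' bit-score columns are -1 and 0 (global alignments have no e-value).
#'
#' @inheritParams write_uc_hits
#' @export
write_blast6 <- function(hits, path) {
  lines <- vapply(seq_len(nrow(hits)), function(r)
    uc_line(hits$query[r], hits$target[r], sprintf("%.1f", 100 * hits$id[r]),
            hits$alnlen[r], hits$mism[r], hits$gaps[r], hits$qlo[r],
            hits$qhi[r], hits$tlo[r], hits$thi[r], -1, 0), character(1))
  writeLines(lines, path)
  invisible(path)
}

USERFIELDS <- c("query", "target", "id", "alnlen", "mism", "gaps",
                "qlo", "qhi", "tlo", "thi")

#' Write hits with user-selected fields
#'
#' @inheritParams write_uc_hits
#' @param fields subset of `query, target, id, alnlen, mism, gaps, qlo,
#'   qhi, tlo, thi`.
#' @export
write_userout <- function(hits, path, fields = USERFIELDS) {
  bad <- setdiff(fields, USERFIELDS)
  if (length(bad)) stop("unknown userfields: ", paste(bad, collapse = ", "))
  cols <- lapply(fields, function(f)
    if (f == "id") sprintf("%.1f", 100 * hits$id) else hits[[f]])
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write the chimera score table
#'
#' Tab-separated: score, query, parents, divergence, vote counts, verdict
#' (Y chimeric / N non-chimeric / B borderline).
#'
#' @param result an `amp_chimera_result`.
#' @param path output file.
#' @export
write_uchimeout <- function(result, path) {
  rep <- result$report
  lines <- vapply(seq_len(nrow(rep)), function(r)
    uc_line(sprintf("%.4f", rep$score[r]), rep$query[r],
            ifelse(is.na(rep$parent_a[r]), "*", rep$parent_a[r]),
            ifelse(is.na(rep$parent_b[r]), "*", rep$parent_b[r]),
            sprintf("%.2f", rep$divergence[r]), rep$yes[r], rep$no[r],
            rep$abstain[r], rep$verdict[r]), character(1))
  writeLines(lines, path)
  invisible(path)
}
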