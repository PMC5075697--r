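#' 64-bit FNV-1a hash of a sequence
#'
#' Fowler-Noll-Vo 1a, the rolling hash used for prefix dereplication: the
#' hash of every prefix of a length-n sequence is computed in O(n) total by
#' folding in one symbol at a time. States are 16-character lowercase hex
#' strings. Sequences are normalised (U to T, uppercase) before hashing.
#'
#' @param sequence a single sequence string; `fnv1a64("")` returns the FNV
#'   offset basis.
#' @return hex hash of the full normalised sequence.
#' @export
fnv1a64 <- function(sequence) {
  s <- norm_seq(sequence)
  if (!nzchar(s)) return(.fnv1a64_basis_hex())
  h <- .fnv1a64_prefixes_hex(s)
  h[length(h)]
}

#' @rdname fnv1a64
#' @param state a hash state (16-char hex string).
#' @param symbols symbols to fold into the state (normalised first).
#' @return `fnv1a64_extend`: the extended state.
#' @export
fnv1a64_extend <- function(state, symbols) {
  .fnv1a64_extend_hex(state, norm_seq(symbols))
}

#' @rdname fnv1a64
#' @return `fnv1a64_prefixes`: hex hashes of every prefix (lengths 1..n).
#' @export
fnv1a64_prefixes <- function(sequence) {
  .fnv1a64_prefixes_hex(norm_seq(sequence))
}

#' Full-length dereplication
#'
#' Collapses records with identical normalised sequences (U to T,
#' case-insensitive) into one record with summed abundance. The
#' representative keeps the first-seen label, description, case and
#' qualities. Output is sorted by abundance descending (ties:
#' first-occurrence order).
#'
#' @param records an [amp_records] object.
#' @param minuniquesize drop output records with accumulated abundance
#'   below this (applied after accumulation).
#' @param topn keep at most this many output records.
#' @return dereplicated [amp_records]; attribute `"cluster"` maps each
#'   input row to the output row it was merged into.
#' @export
derep_fulllength <- function(records, minuniquesize = 1, topn = Inf) {
  keys <- norm_seq(records$sequence)
  first <- !duplicated(keys)
  rep_of <- match(keys, keys[first])  # input row -> representative index
  out <- records[first, , drop = FALSE]
  out$abundance <- as.integer(
    tapply(records$abundance, factor(rep_of, levels = seq_len(sum(first))),
           sum))
  o <- order(-out$abundance, out$ordinal)
  out <- reindex(out[o, , drop = FALSE])
  cluster <- match(rep_of, o)  # input row -> output row (before filtering)
  members <- split(seq_along(cluster), cluster)
  rep_rows <- which(first)[o]
  keep <- which(out$abundance >= minuniquesize)
  if (length(keep) > topn) keep <- keep[seq_len(topn)]
  out2 <- reindex(out[keep, , drop = FALSE])
  attr(out2, "cluster") <- cluster
  attr(out2, "members") <- members[keep]
  attr(out2, "rep_rows") <- rep_rows[keep]
  rownames(out2) <- NULL
  out2
}

#' Prefix dereplication
#'
#' Clusters sequences identical to other sequences or to their prefixes.
#' Records are processed shortest first; for each, the full sequence and
#' then successively shorter prefixes (down to the length of the shortest
#' input sequence) are looked up in a hash table of earlier survivors. On a
#' match, the matched entry is deleted and the longer sequence inserted
#' with accumulated abundance. A sequence that is a prefix of several
#' candidates is clustered with the shortest; among equally long
#' candidates, priority goes to the most abundant, then the
#' lexicographically smaller label, then the earliest input position
#' (realised by the processing order). Lookups use the incremental 64-bit
#' FNV-1a prefix hashes; hash collisions are resolved by full sequence
#' comparison, never merged blindly.
#'
#' @inheritParams derep_fulllength
#' @return dereplicated [amp_records], abundance-sorted; no output
#'   sequence is a strict prefix of another.
#' @export
derep_prefix <- function(records, minuniquesize = 1, topn = Inf) {
  n <- nrow(records)
  if (!n) return(records)
  lens <- nchar(records$sequence)
  s_min <- min(lens)
  ord <- order(lens, -records$abundance, records$label, records$ordinal)
  tab <- new.env(parent = emptyenv(), hash = TRUE)  # hash hex -> entry list
  norm <- norm_seq(records$sequence)

  tab_find <- function(hash, seqstr) {
    bucket <- tab[[hash]]
    if (is.null(bucket)) return(NULL)
    for (entry in bucket) if (entry$seq == seqstr) return(entry)
    NULL
  }
  tab_delete <- function(hash, seqstr) {
    bucket <- tab[[hash]]
    keep <- Filter(function(e) e$seq != seqstr, bucket)
    if (length(keep)) tab[[hash]] <- keep else rm(list = hash, envir = tab)
  }
  tab_insert <- function(hash, entry) {
    tab[[hash]] <- c(tab[[hash]], list(entry))
  }

  for (i in ord) {
    sq <- norm[i]
    L <- lens[i]
    hashes <- .fnv1a64_prefixes_hex(sq)
    merged <- FALSE
    for (p in L:s_min) {  # full sequence first, then shorter prefixes
      pref <- substr(sq, 1, p)
      entry <- tab_find(hashes[p], pref)
      if (!is.null(entry)) {
        if (p == L) {  # exact duplicate: representative stays
          entry$abundance <- entry$abundance + records$abundance[i]
          entry$rows <- c(entry$rows, i)
          tab_delete(hashes[p], pref)
          tab_insert(hashes[p], entry)
        } else {       # prefix match: the longer sequence takes over
          tab_delete(hashes[p], pref)
          tab_insert(hashes[L],
                     list(seq = sq, row = i,
                          abundance = entry$abundance + records$abundance[i],
                          rows = c(entry$rows, i)))
        }
        merged <- TRUE
        break
      }
    }
    if (!merged)
      tab_insert(hashes[L], list(seq = sq, row = i,
                                 abundance = records$abundance[i],
                                 rows = i))
  }

  entries <- unlist(lapply(ls(tab), function(h) tab[[h]]), recursive = FALSE)
  rows <- vapply(entries, function(e) e$row, integer(1))
  abund <- vapply(entries, function(e) e$abundance, numeric(1))
  members <- lapply(entries, function(e) e$rows)
  out <- records[rows, , drop = FALSE]
  out$abundance <- as.integer(abund)
  o <- order(-out$abundance, out$ordinal)
  out <- out[o, , drop = FALSE]
  keep <- which(out$abundance >= minuniquesize)
  if (length(keep) > topn) keep <- keep[seq_len(topn)]
  out2 <- reindex(out[keep, , drop = FALSE])
  attr(out2, "members") <- members[o][keep]
  attr(out2, "rep_rows") <- rows[o][keep]
  rownames(out2) <- NULL
  out2
}

#' Rereplication
#'
#' Expands each record of abundance n into n copies of abundance 1,
#' recreating a dataset as it was before full-length dereplication
#' (original labels cannot be recreated; each copy keeps the
#' representative's label).
#'
#' @param records an [amp_records] object with abundances parsed.
#' @return expanded [amp_records], every abundance 1.
#' @export
rereplicate <- function(records) {
  idx <- rep.int(seq_len(nrow(records)), records$abundance)
  out <- records[idx, , drop = FALSE]
  out$abundance <- rep(1L, length(idx))
  rownames(out) <- NULL
  reindex(out)
}
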