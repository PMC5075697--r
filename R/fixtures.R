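# Deterministic synthetic-data generators. Every module is testable with
# no external downloads: these emulate the inputs the methods operate on
# (clustered amplicon families, known chimeras, overlapping read pairs)
# with ground truth attached.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# substitute round(n * rate) positions, each to a different base: the
# realised divergence equals the requested rate, so fixture guarantees
# (member within X% of its template) hold exactly rather than on average
mutate_seq <- function(sequence, rate) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  k <- round(n * rate)
  if (k == 0) return(sequence)
  idx <- sample.int(n, k)
  for (i in idx)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

#' Synthetic amplicon families with known membership
#'
#' Generates independent random templates (mutually unrelated, so family
#' separation is guaranteed far below any clustering threshold) and
#' mutates each at `member_divergence` to produce family members. The
#' truth table makes the fixture usable for recall/precision or adjusted
#' Rand scoring of clustering output.
#'
#' @param n_families number of templates.
#' @param members_per_family members per family (recycled).
#' @param template_length template length (a single value or range).
#' @param member_divergence per-base substitution rate within a family.
#' @param abundance_max member abundances drawn uniformly from
#'   1..abundance_max; each template itself gets abundance
#'   `abundance_max + 1` so that abundance-ordered clustering seeds every
#'   cluster on the template, making the member-to-centroid identity bound
#'   (`1 - member_divergence`) hold by construction.
#' @param seed RNG seed.
#' @return list: `records` ([amp_records], shuffled) and `truth` (data
#'   frame label/family).
#' @export
make_families <- function(n_families = 5, members_per_family = 6,
                          template_length = 300, member_divergence = 0.02,
                          abundance_max = 10, seed = 1) {
  with_rng(seed, {
    members_per_family <- rep_len(members_per_family, n_families)
    lens <- rep_len(template_length, n_families)
    seqs <- character(0); fam <- integer(0); labs <- character(0)
    for (f in seq_len(n_families)) {
      template <- random_seq(lens[f])
      for (m in seq_len(members_per_family[f])) {
        seqs <- c(seqs, if (m == 1) template
                  else mutate_seq(template, member_divergence))
        fam <- c(fam, f)
        labs <- c(labs, sprintf("fam%d_m%d", f, m))
      }
    }
    ab <- sample.int(abundance_max, length(seqs), replace = TRUE)
    ab[!duplicated(fam)] <- abundance_max + 1L  # template leads its family
    perm <- sample.int(length(seqs))
    records <- amp_records(seqs[perm], label = labs[perm],
                           abundance = ab[perm])
    list(records = records,
         truth = data.frame(label = labs[perm], family = fam[perm],
                            stringsAsFactors = FALSE))
  })
}

#' Synthetic two-parent chimeras with labelled ground truth
#'
#' Parent pairs are generated at a controlled mutual identity (the second
#' parent is the first mutated at `1 - parent_identity`); each chimera
#' takes the left part of parent A and the right part of parent B at a
#' breakpoint near the middle. Parents are always at least `abskew` times
#' more abundant than their chimeras.
#'
#' @param n_chimeras number of chimeras (one parent pair each).
#' @param length sequence length.
#' @param parent_identity mutual identity of each parent pair (scalar or
#'   vector to sample from).
#' @param parent_abundance abundance given to each parent.
#' @param chimera_abundance abundance given to each chimera.
#' @param breakpoint breakpoint position as a fraction of the length.
#' @param seed RNG seed.
#' @return list: `records` (parents then chimeras) and `truth` data frame
#'   (label, type, parent_a, parent_b, breakpoint).
#' @export
make_chimeras <- function(n_chimeras = 10, length = 300,
                          parent_identity = c(0.85, 0.97),
                          parent_abundance = 50, chimera_abundance = 1,
                          breakpoint = 0.5, seed = 1) {
  with_rng(seed, {
    seqs <- character(0); labs <- character(0); ab <- integer(0)
    truth <- NULL
    for (i in seq_len(n_chimeras)) {
      idy <- if (length(parent_identity) > 1)
        runif(1, min(parent_identity), max(parent_identity))
      else parent_identity
      pa <- random_seq(length)
      pb <- mutate_seq(pa, 1 - idy)
      bp <- round(length * breakpoint)
      ch <- paste0(substr(pa, 1, bp), substr(pb, bp + 1, length))
      la <- sprintf("parentA%d", i); lb <- sprintf("parentB%d", i)
      lc <- sprintf("chimera%d", i)
      seqs <- c(seqs, pa, pb, ch)
      labs <- c(labs, la, lb, lc)
      ab <- c(ab, parent_abundance, parent_abundance, chimera_abundance)
      truth <- rbind(truth, data.frame(
        label = c(la, lb, lc), type = c("parent", "parent", "chimera"),
        parent_a = c(NA, NA, la), parent_b = c(NA, NA, lb),
        breakpoint = c(NA, NA, bp), stringsAsFactors = FALSE))
    }
    list(records = amp_records(seqs, label = labs, abundance = ab),
         truth = truth)
  })
}

#' Synthetic overlapping read pairs with known truth
#'
#' Each pair is drawn from a random template of length
#' `read_length * 2 - overlap`: the forward read is the template prefix,
#' the reverse read the reverse complement of the template suffix.
#' Qualities are constant `q` with an optional linear 3' decay; planted
#' substitution errors (at known overlap columns) can be added to the
#' forward read.
#'
#' @param n_pairs number of pairs.
#' @param read_length read length (default 108, mirroring short amplicon
#'   sequencing).
#' @param overlap true overlap length (default 18).
#' @param q constant Phred quality.
#' @param decay total linear quality drop toward the 3' end.
#' @param errors_per_pair substitutions planted in the forward read's
#'   overlap region.
#' @param seed RNG seed.
#' @return list: `forward`, `reverse` ([amp_records]) and `truth`
#'   (templates plus planted error positions).
#' @export
make_read_pairs <- function(n_pairs = 100, read_length = 108, overlap = 18,
                            q = 35, decay = 0, errors_per_pair = 0,
                            seed = 1) {
  with_rng(seed, {
    tlen <- 2 * read_length - overlap
    fwd_s <- character(n_pairs); rev_s <- character(n_pairs)
    templates <- character(n_pairs)
    err_pos <- vector("list", n_pairs)
    qual <- round(q - decay * (seq_len(read_length) - 1) /
                    max(1, read_length - 1))
    for (i in seq_len(n_pairs)) {
      tpl <- random_seq(tlen)
      templates[i] <- tpl
      f <- substr(tpl, 1, read_length)
      if (errors_per_pair > 0) {
        ovl_cols <- (read_length - overlap + 1):read_length
        pos <- sample(ovl_cols, errors_per_pair)
        fc <- strsplit(f, "")[[1]]
        for (p in pos)
          fc[p] <- sample(setdiff(c("A", "C", "G", "T"), fc[p]), 1)
        f <- paste(fc, collapse = "")
        err_pos[[i]] <- sort(pos)
      }
      fwd_s[i] <- f
      rev_s[i] <- reverse_complement(substr(tpl, tlen - read_length + 1,
                                            tlen))
    }
    quals <- replicate(n_pairs, qual, simplify = FALSE)
    list(forward = amp_records(fwd_s, label = paste0("pair", seq_len(n_pairs)),
                               quality = quals),
         reverse = amp_records(rev_s, label = paste0("pair", seq_len(n_pairs)),
                               quality = quals),
         truth = list(templates = templates, error_positions = err_pos,
                      overlap = overlap))
  })
}
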