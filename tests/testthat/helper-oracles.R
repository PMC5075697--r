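# Independent brute-force oracles used across the test files.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# brute-force k-mer set: enumerate windows, drop those with non-ACGT
oracle_unique_words <- function(sequence, k) {
  s <- chartr("U", "T", toupper(sequence))
  n <- nchar(s)
  if (n < k) return(numeric(0))
  out <- numeric(0)
  for (i in 1:(n - k + 1)) {
    w <- substr(s, i, i + k - 1)
    ch <- strsplit(w, "")[[1]]
    code <- match(ch, c("A", "C", "G", "T")) - 1
    if (any(is.na(code))) next
    out <- c(out, sum(code * 4^((k - 1):0)))
  }
  unique(out)
}

# exhaustive enumeration of every global alignment of two tiny sequences,
# priced directly from the scoring model definition (terminal runs are the
# gap runs lying at a query/target end)
enum_align_score <- function(a, b, p = align_params()) {
  m <- nchar(a); n <- nchar(b)
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  bits <- c(A = 1, C = 2, G = 4, T = 8, R = 5, Y = 10, S = 6, W = 9,
            K = 12, M = 3, B = 14, D = 13, H = 11, V = 7, N = 15)
  subsc <- function(x, y) {
    nx <- chartr("U", "T", toupper(x)); ny <- chartr("U", "T", toupper(y))
    if (nx == "N" || ny == "N") return(0)
    if (nx == ny) return(p$match)
    if (bitwAnd(bits[[nx]], bits[[ny]]) > 0) return(p$match)
    p$mismatch
  }
  best <- -Inf
  price <- function(ops) {
    sc <- 0; qi <- 0; ti <- 0
    r <- rle(ops)
    for (k in seq_along(r$lengths)) {
      op <- r$values[k]; len <- r$lengths[k]
      if (op == "M") {
        for (t in 1:len) { qi <- qi + 1; ti <- ti + 1
          sc <- sc + subsc(ac[qi], bc[ti]) }
      } else if (op == "D") {  # gap in the query at query position qi
        term <- qi == 0 || qi == m
        sc <- sc -
          (if (term) p$gap_open_terminal_query else p$gap_open_interior_query) -
          len * (if (term) p$gap_extend_terminal else p$gap_extend_interior)
        ti <- ti + len
      } else {                 # I: gap in the target at target position ti
        term <- ti == 0 || ti == n
        sc <- sc -
          (if (term) p$gap_open_terminal_target else p$gap_open_interior_target) -
          len * (if (term) p$gap_extend_terminal else p$gap_extend_interior)
        qi <- qi + len
      }
    }
    sc
  }
  rec <- function(i, j, ops) {
    if (i == m && j == n) {
      s <- price(ops)
      if (s > best) best <<- s
      return(invisible())
    }
    if (i < m && j < n) rec(i + 1, j + 1, c(ops, "M"))
    if (j < n) rec(i, j + 1, c(ops, "D"))
    if (i < m) rec(i + 1, j, c(ops, "I"))
  }
  rec(0, 0, character(0))
  best
}

# two centroids plus a query lying between them: C2 differs from C1 at 12
# fixed positions; q carries the first 4 of those changes.  Identities are
# exactly q-C1 0.98, q-C2 0.96, C1-C2 0.94, so at threshold 0.95 with
# maxaccepts 2 both centroids accept q while C2 itself seeds a new cluster
make_dgc_agc_fixture <- function() {
  c1c <- strsplit(rand_seq(200), "")[[1]]
  pos <- sample.int(200, 12)
  c2c <- c1c
  for (p in pos) c2c[p] <- sample(setdiff(c("A", "C", "G", "T"), c1c[p]), 1)
  qc <- c1c
  qc[pos[1:4]] <- c2c[pos[1:4]]
  amp_records(vapply(list(c1c, c2c, qc), paste, character(1), collapse = ""),
              label = c("C1", "C2", "q"), abundance = c(5L, 50L, 1L))
}

# a read pair whose only agreeing placement is a 9 bp overlap: the
# forward read is A-homopolymer plus a CG-alphabet junction O, the reverse
# (before reverse-complementing) covers O plus a T-homopolymer.  Every
# placement with overlap >= 10 mixes the disjoint alphabets (or shifts O
# against itself, where O is chosen with poor self-similarity) and carries
# at least 6 observed mismatches, so rejection at the default minimum
# overlap of 10 is structural, not statistical
make_overlap9_pair <- function(q = 35L) {
  O <- "CCGCGGCGG"
  fwd <- paste0(strrep("A", 51), O)
  rev_rc <- paste0(O, strrep("T", 51))
  list(forward = amp_records(fwd, label = "p", quality = list(rep(q, 60))),
       reverse = amp_records(reverse_complement(rev_rc), label = "p",
                             quality = list(rep(q, 60))))
}

# mutate a fraction of positions of a sequence (substitutions only)
mutate_at_rate <- function(sequence, rate) {
  chars <- strsplit(sequence, "")[[1]]
  k <- max(0, round(length(chars) * rate))
  if (k == 0) return(sequence)
  idx <- sample.int(length(chars), k)
  for (i in idx)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}
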