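test_that("FNV-1a matches published vectors and is incremental", {
  # offset basis and classic published test vectors
  expect_equal(fnv1a64(""), "cbf29ce484222325")  # 14695981039346656037
  expect_equal(.fnv1a64_prefixes_hex("a")[1], "af63dc4c8601ec8c")
  expect_equal(.fnv1a64_prefixes_hex("foobar")[6], "85944171f73967e8")
  expect_equal(fnv1a64("ACGT"), "9a90178ba8feda4e")
  # extend-by-one equals hashing the concatenation from scratch
  set.seed(77)
  s <- rand_seq(100)
  pref <- fnv1a64_prefixes(s)
  for (i in c(1, 50, 99))
    expect_equal(fnv1a64_extend(pref[i], substr(s, i + 1, i + 1)),
                 pref[i + 1])
  expect_equal(fnv1a64_extend(fnv1a64(""), s), pref[100])
  # normalisation: U/u/t hash like T
  expect_equal(fnv1a64("acgu"), fnv1a64("ACGT"))
  # prefix hashes of a random 1 kb sequence are all distinct
  expect_equal(anyDuplicated(fnv1a64_prefixes(rand_seq(1000))), 0L)
})

test_that("full-length dereplication accumulates and normalises", {
  d <- derep_fulllength(amp_records(c("ACGT", "ACGT", "ACGT")))
  expect_equal(nrow(d), 1L)
  expect_equal(d$abundance, 3L)
  d2 <- derep_fulllength(amp_records(c("acgt", "ACGU"), label = c("a", "b")))
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$abundance, 2L)
  expect_equal(d2$label, "a")        # first-seen representative
  expect_equal(d2$sequence, "acgt")  # original case kept
  # abundance conservation on a random corpus; order-insensitivity
  set.seed(83)
  pool <- replicate(30, rand_seq(sample(20:40, 1)))
  recs <- amp_records(sample(pool, 500, replace = TRUE),
                      abundance = sample(1:5, 500, replace = TRUE))
  d3 <- derep_fulllength(recs)
  expect_equal(sum(d3$abundance), sum(recs$abundance))
  perm <- recs[sample.int(nrow(recs)), ]
  d4 <- derep_fulllength(reindex(perm))
  expect_setequal(paste(norm_seq(d3$sequence), d3$abundance),
                  paste(norm_seq(d4$sequence), d4$abundance))
  # output sorted by abundance descending
  expect_true(all(diff(d3$abundance) <= 0))
  # minuniquesize filters after accumulation
  d5 <- derep_fulllength(amp_records(c("ACGT", "ACGT", "GGGG")),
                         minuniquesize = 2)
  expect_equal(d5$sequence, "ACGT")
})

test_that("prefix dereplication follows the shortest-candidate chain", {
  # a prefix merges into its extension
  dp <- derep_prefix(amp_records(c("ACGT", "ACGTACGT")))
  expect_equal(dp$sequence, "ACGTACGT")
  expect_equal(dp$abundance, 2L)

  # shortest candidate wins
  r1 <- amp_records(c("AC", "ACGT", "ACTTTT"), label = c("s", "short", "long"),
                    abundance = c(1L, 1L, 9L))
  d1 <- derep_prefix(r1)
  # AC merged into ACGT (the shortest candidate), not the abundant ACTTTT
  expect_setequal(d1$sequence, c("ACGT", "ACTTTT"))
  expect_equal(d1$abundance[d1$sequence == "ACGT"], 2L)
  expect_equal(d1$abundance[d1$sequence == "ACTTTT"], 9L)

  # chained prefixes collapse transitively onto the longest survivor
  ch <- derep_prefix(amp_records(c("AC", "ACGT", "ACGTTT"),
                                 abundance = c(1L, 1L, 9L)))
  expect_equal(ch$sequence, "ACGTTT")
  expect_equal(ch$abundance, 11L)

  # equal length: abundance beats label
  r2 <- amp_records(c("AC", "ACGT", "ACTT"), label = c("s", "z", "a"),
                    abundance = c(1L, 1L, 5L))
  d2 <- derep_prefix(r2)
  expect_equal(d2$abundance[d2$sequence == "ACTT"], 6L)
  expect_equal(d2$abundance[d2$sequence == "ACGT"], 1L)

  # equal length and abundance: lexicographically smaller label wins
  r3 <- amp_records(c("AC", "ACGT", "ACTT"), label = c("s", "zz", "aa"),
                    abundance = c(1L, 3L, 3L))
  d3 <- derep_prefix(r3)
  expect_equal(d3$abundance[d3$sequence == "ACTT"], 4L)  # label aa < zz

  # equal everything: earliest original position wins
  r4 <- amp_records(c("AC", "ACGT", "ACTT"), label = c("s", "m", "m"),
                    abundance = c(1L, 3L, 3L))
  d4 <- derep_prefix(r4)
  expect_equal(d4$abundance[d4$sequence == "ACGT"], 4L)  # earlier input
})

test_that("prefix dereplication invariants hold on random corpora", {
  set.seed(89)
  pool <- replicate(15, rand_seq(sample(15:30, 1)))
  seqs <- c(pool, vapply(pool, function(s)
    substr(s, 1, sample(10:nchar(s), 1)), character(1)),
    replicate(10, rand_seq(12)))
  recs <- amp_records(sample(seqs), abundance = sample(1:4, length(seqs),
                                                       replace = TRUE))
  dp <- derep_prefix(recs)
  expect_equal(sum(dp$abundance), sum(recs$abundance))
  # no output sequence is a strict prefix of another
  ns <- norm_seq(dp$sequence)
  for (i in seq_along(ns)) for (j in seq_along(ns)) {
    if (i != j) expect_false(startsWith(ns[j], ns[i]) &&
                               nchar(ns[j]) > nchar(ns[i]))
  }
  # never more output records than full-length dereplication
  expect_lte(nrow(dp), nrow(derep_fulllength(recs)))
})

test_that("rereplication inverts full-length dereplication", {
  r <- amp_records("ACGT", abundance = 5L)
  rr <- rereplicate(r)
  expect_equal(nrow(rr), 5L)
  expect_true(all(rr$abundance == 1L))
  set.seed(97)
  recs <- amp_records(replicate(20, rand_seq(25)),
                      abundance = sample(1:6, 20, replace = TRUE))
  d <- derep_fulllength(recs)
  back <- derep_fulllength(rereplicate(d))
  expect_setequal(paste(norm_seq(back$sequence), back$abundance),
                  paste(norm_seq(d$sequence), d$abundance))
  expect_equal(nrow(rereplicate(d)), sum(d$abundance))
})
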