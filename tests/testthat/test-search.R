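test_that("verbatim queries hit themselves at identity 1", {
  set.seed(41)
  db <- amp_records(replicate(20, rand_seq(150)))
  q <- db[3, ]
  hits <- usearch_global(q, db, search_options(id = 0.97))
  expect_equal(nrow(hits), 1L)  # maxaccepts 1 by default
  expect_equal(hits$id, 1.0)
  expect_equal(hits$target, db$label[3])
})

test_that("queries sharing no words with the database yield no hits", {
  db <- amp_records(strrep("A", 100))
  q <- amp_records(strrep("C", 100))
  expect_equal(nrow(usearch_global(q, db, search_options(id = 0))), 0L)
  # empty database is not an error
  expect_equal(nrow(usearch_global(q, amp_records(character(0)),
                                   search_options(id = 0.5))), 0L)
})

test_that("with unlimited budgets the hit set equals brute force", {
  set.seed(43)
  base <- rand_seq(120)
  seqs <- c(replicate(15, mutate_at_rate(base, runif(1, 0.01, 0.4))),
            replicate(15, rand_seq(120)))
  db <- amp_records(seqs)
  q <- amp_records(c(base, rand_seq(120)), label = c("q1", "q2"))
  for (idt in c(0.5, 0.8)) {
    opts <- search_options(id = idt, maxaccepts = 0, maxrejects = 0,
                           minwordmatches = 1, wordlength = 4,
                           qmask = "none")
    hits <- usearch_global(q, db, opts)
    for (qi in 1:2) {
      brute <- vapply(seq_len(nrow(db)), function(t) {
        aln <- global_align(q$sequence[qi], db$sequence[t])
        compute_identity(aln) >= idt
      }, logical(1))
      got <- sort(hits$target_ord[hits$query_ord == q$ordinal[qi]] + 1)
      expect_equal(got, which(brute))
    }
  }
})

test_that("maxaccepts and maxrejects terminate the candidate loop", {
  set.seed(47)
  base <- rand_seq(150)
  db <- amp_records(replicate(12, mutate_at_rate(base, 0.02)))
  q <- amp_records(base)
  h1 <- usearch_global(q, db, search_options(id = 0.9, maxaccepts = 1,
                                             maxrejects = 32))
  expect_equal(nrow(h1), 1L)
  h3 <- usearch_global(q, db, search_options(id = 0.9, maxaccepts = 3,
                                             maxrejects = 32))
  expect_equal(nrow(h3), 3L)
  # all candidates reject at id 1: the loop stops after maxrejects
  hr <- usearch_global(q, amp_records(replicate(40, mutate_at_rate(base, 0.05))),
                       search_options(id = 1, maxaccepts = 0, maxrejects = 5))
  expect_equal(nrow(hr), 0L)
  # hits are sorted by identity descending
  expect_true(all(diff(h3$id) <= 0))
})

test_that("strand both finds reverse-complemented queries", {
  set.seed(53)
  db <- amp_records(replicate(8, rand_seq(120)))
  q <- amp_records(reverse_complement(db$sequence[5]), label = "rcq")
  plus <- usearch_global(q, db, search_options(id = 0.97, strand = "plus"))
  expect_equal(nrow(plus), 0L)
  both <- usearch_global(q, db, search_options(id = 0.97, strand = "both"))
  expect_equal(nrow(both), 1L)
  expect_equal(both$strand, "-")
  expect_equal(both$target_ord, 4)
  # palindromic tie resolves to plus
  pal <- amp_records("ACGTACGTACGTACGT")
  hp <- usearch_global(pal, pal, search_options(id = 0.9, strand = "both",
                                                minwordmatches = 1))
  expect_equal(hp$strand, "+")
})

test_that("self exclusion and query abundance prefilters apply", {
  set.seed(59)
  s <- rand_seq(130)
  db <- amp_records(c(s, mutate_at_rate(s, 0.01)), label = c("x", "y"))
  q <- amp_records(s, label = "x", abundance = 2)
  h <- usearch_global(q, db, search_options(id = 0.9, self = TRUE))
  expect_false("x" %in% h$target)
  h2 <- usearch_global(q, db, search_options(id = 0.9, minqsize = 5))
  expect_equal(nrow(h2), 0L)
})

test_that("search_exact matches full normalised sequences only", {
  db <- amp_records(c("ACGT", "ACGTACGT", "acgt"), label = c("t1", "t2", "t3"))
  expect_equal(sort(search_exact(amp_records("ACGT"), db)$target),
               c("t1", "t3"))  # case-insensitive
  expect_equal(nrow(search_exact(amp_records("ACG"), db)), 0L)  # prefix only
  expect_equal(search_exact(amp_records("ACGU"), amp_records("ACGT"))$id, 1)
})

test_that("allpairs_global aligns every unordered pair", {
  r <- amp_records(rep("ACGTACGTGGCC", 3))
  h <- allpairs_global(r, search_options(id = 0.5))
  expect_equal(nrow(h), 3L)  # n(n-1)/2
  expect_true(all(h$id == 1))
  set.seed(61)
  r2 <- amp_records(replicate(6, rand_seq(80)))
  h2 <- allpairs_global(r2, search_options(id = 1))
  expect_equal(nrow(h2), 0L)
  # identities are compositional with global_align
  h3 <- allpairs_global(r2, search_options(id = 0))
  for (k in seq_len(nrow(h3))) {
    aln <- global_align(r2$sequence[h3$query_ord[k] + 1],
                        r2$sequence[h3$target_ord[k] + 1])
    expect_equal(h3$id[k], compute_identity(aln))
  }
})
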