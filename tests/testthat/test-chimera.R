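make_parent_pair <- function(len = 300, identity = 0.9) {
  a <- rand_seq(len)
  b <- mutate_at_rate(a, 1 - identity)
  list(a = a, b = b,
       chimera = paste0(substr(a, 1, len / 2), substr(b, len / 2 + 1, len)))
}

test_that("segment search recovers the true parents of a chimera", {
  set.seed(103)
  pp <- make_parent_pair(300, 0.9)
  db <- amp_records(c(pp$a, pp$b, replicate(5, rand_seq(300))),
                    label = c("A", "B", paste0("bg", 1:5)),
                    abundance = rep(50L, 7))
  q <- amp_records(pp$chimera, label = "q", abundance = 1L)
  cand <- find_parent_candidates(q[1, ], db)
  expect_true(all(c(1L, 2L) %in% cand))
  # de novo abundance rule: a parent below abskew * query size is excluded
  q10 <- q; q10$abundance <- 30L  # abskew 2 requires parents >= 60
  cand2 <- find_parent_candidates(q10[1, ], db, denovo = TRUE)
  expect_equal(length(cand2), 0L)
  # empty database
  expect_equal(length(find_parent_candidates(q[1, ],
                                             amp_records(character(0)))), 0L)
})

test_that("vote scoring separates perfect chimeras from clean reads", {
  set.seed(107)
  pp <- make_parent_pair(300, 0.9)
  ev <- score_chimera(pp$chimera, pp$a, pp$b)
  expect_equal(ev$classification, "chimeric")
  expect_gte(ev$h, 0.28)
  expect_gte(ev$divergence, 0.8)
  expect_equal(ev$no, 0)  # the model explains every divergent column

  # query identical to one parent: no yes-votes for any crossover
  ev2 <- score_chimera(pp$a, pp$a, pp$b)
  expect_equal(ev2$classification, "non-chimeric")
  expect_equal(ev2$divergence, 0)

  # one mismatch against parent A with B unrelated stays non-chimeric
  q1 <- mutate_at_rate(pp$a, 1 / 300)
  ev3 <- score_chimera(q1, pp$a, rand_seq(300))
  expect_equal(ev3$classification, "non-chimeric")
})

test_that("h increases with yes votes and decreases with no votes", {
  set.seed(109)
  opts <- chimera_options()
  pp <- make_parent_pair(200, 0.92)
  base <- score_chimera(pp$chimera, pp$a, pp$b, opts)
  # perturbing the query away from the model adds no-votes, lowering h
  noisy <- mutate_at_rate(pp$chimera, 0.05)
  pert <- score_chimera(noisy, pp$a, pp$b, opts)
  expect_lte(pert$h, base$h)
  # the closed form itself
  expect_equal(base$h, base$yes / (opts$xn * (base$no + opts$dn)))
})

test_that("de novo detection flags the chimera and only the chimera", {
  set.seed(113)
  pp <- make_parent_pair(300, 0.9)
  recs <- amp_records(c(pp$a, pp$b, pp$chimera),
                      label = c("A", "B", "chim"),
                      abundance = c(10L, 8L, 1L))
  res <- uchime_denovo(recs)
  expect_equal(res$classification[match(c("A", "B", "chim"),
                                        res$report$query)],
               c("non-chimeric", "non-chimeric", "chimeric"))
  # the three output streams partition the input
  expect_equal(nrow(res$chimeras) + nrow(res$nonchimeras) +
                 nrow(res$borderline), 3L)
  expect_equal(res$report$verdict[res$report$query == "chim"], "Y")
})

test_that("reference search does not call references chimeric against
           their own database", {
  set.seed(127)
  db <- amp_records(replicate(6, rand_seq(250)), label = paste0("ref", 1:6))
  res <- uchime_ref(db[1, ], db)
  expect_equal(res$classification, "non-chimeric")
  # but a chimera of two references is flagged
  ch <- paste0(substr(db$sequence[1], 1, 125), substr(db$sequence[2], 126, 250))
  res2 <- uchime_ref(amp_records(ch, label = "q"), db)
  expect_equal(res2$classification, "chimeric")
})

test_that("borderline classification fires between minh and mindiv", {
  set.seed(131)
  # deterministic construction: parents differ at 4 positions near each
  # end of a 600 bp sequence; the chimera takes the A head and the B tail.
  # The best crossover has 4 yes votes per side and no no-votes:
  # h = 8 / (8 * 1.4) = 0.71 passes minh, while the model improves on
  # either single parent by only 4/600 columns (divergence 0.67% < 0.8%)
  a <- rand_seq(600)
  b <- a
  for (p in c(10, 13, 16, 19, 590, 593, 596, 599)) {
    substr(b, p, p) <- setdiff(c("A", "C", "G", "T"),
                               substr(a, p, p))[1]
  }
  q <- paste0(substr(a, 1, 585), substr(b, 586, 600))
  ev <- score_chimera(q, a, b)
  expect_gte(ev$h, 0.28)
  expect_lt(ev$divergence, 0.8)
  expect_equal(ev$classification, "borderline")
})
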