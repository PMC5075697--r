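test_that("overlap scoring hits the alpha/beta limits at perfect quality", {
  opts <- merge_options()
  f <- list(sequence = "ACGT", quality = c(93L, 93L, 93L, 93L))
  r_same <- list(sequence = "ACGT", quality = c(93L, 93L, 93L, 93L))
  expect_equal(overlap_score(f, r_same, 0, opts) / 4, 4, tolerance = 1e-3)
  r_diff <- list(sequence = "TGCA", quality = c(93L, 93L, 93L, 93L))
  expect_equal(overlap_score(f, r_diff, 0, opts) / 4, -5, tolerance = 1e-3)
  # at q = 3 (p ~ 0.5) the contribution sits strictly between beta and alpha
  f2 <- list(sequence = "A", quality = 3L)
  sc_eq <- overlap_score(f2, list(sequence = "A", quality = 3L), 0, opts)
  sc_ne <- overlap_score(f2, list(sequence = "C", quality = 3L), 0, opts)
  p <- 10^-0.3
  P1 <- (1 - p)^2 + p^2 / 3
  expect_equal(sc_eq, 4 * P1 - 5 * (1 - P1))
  expect_true(sc_eq > -5 && sc_eq < 4)
  expect_true(sc_ne > -5 && sc_ne < 4)
})

test_that("posterior qualities follow the agree/disagree formulas", {
  # agree at q1 = q2 = 2: direct evaluation, confidence must increase
  p <- 10^(-2 / 10)
  p_post <- (p * p / 3) / (1 - 2 * p + 4 * p * p / 3)
  expect_equal(posterior_quality(2, 2, TRUE, 93),
               as.integer(round(-10 * log10(p_post))))
  expect_lt(p_post, p)
  # agree at q40 + q40 caps at the default 41
  expect_equal(posterior_quality(40, 40, TRUE), 41L)
  # disagreement keeps the better observation but cannot beat it
  expect_lte(posterior_quality(40, 2, FALSE), 40L)

  # exhaustive check over all quality pairs 0..42; the confidence
  # monotonicity properties hold wherever both error probabilities are
  # below the uninformative-read point 3/4 (quality >= 2)
  grid <- expand.grid(q1 = 0:42, q2 = 0:42)
  agree <- posterior_quality(grid$q1, grid$q2, TRUE, 93)
  disagree <- posterior_quality(grid$q1, grid$q2, FALSE, 93)
  inf2 <- pmin(grid$q1, grid$q2) >= 2
  expect_true(all(agree[inf2] >= pmax(grid$q1, grid$q2)[inf2]))
  expect_true(all(disagree[inf2] <= pmax(grid$q1, grid$q2)[inf2]))
  capped <- posterior_quality(grid$q1, grid$q2, TRUE, 41)
  expect_true(all(capped <= 41))
  # direct re-evaluation of both closed forms
  p1 <- 10^(-pmin(grid$q1, grid$q2) / 10)  # worse observation
  p2 <- 10^(-pmax(grid$q1, grid$q2) / 10)  # better observation
  lo <- pmin(p1, p2); hi <- pmax(p1, p2)
  pa <- (lo * hi / 3) / (1 - lo - hi + 4 * lo * hi / 3)
  pd <- lo * (1 - hi / 3) / (lo + hi - 4 * lo * hi / 3)
  expect_equal(agree, as.integer(round(-10 * log10(pa))))
  expect_equal(disagree, as.integer(round(-10 * log10(pd))))
})

test_that("constructed pairs with an exact 18 bp overlap merge to 198 bp", {
  pr <- make_read_pairs(n_pairs = 20, read_length = 108, overlap = 18,
                        q = 35, seed = 151)
  res <- merge_pairs(pr$forward, pr$reverse)
  expect_true(all(res$status == "merged"))
  expect_true(all(nchar(res$merged$sequence) == 198))  # 108 + 108 - 18
  expect_equal(res$merged$sequence, pr$truth$templates)
})

test_that("short overlaps, excess mismatches and stagger are rejected", {
  # a true overlap of 9 falls below the default minimum of 10; every other
  # placement of this constructed pair is mismatch-laden
  p9 <- make_overlap9_pair()
  res9 <- merge_pair(p9$forward[1, ], p9$reverse[1, ])
  expect_false(res9$status == "merged")
  # lowering the minimum makes the true placement usable
  res9b <- merge_pair(p9$forward[1, ], p9$reverse[1, ],
                      merge_options(minovlen = 9))
  expect_equal(res9b$status, "merged")
  expect_equal(res9b$overlap, 9L)
  expect_equal(nchar(res9b$merged$sequence), 111L)  # 60 + 60 - 9
  # 6 planted mismatches in an 18 bp overlap at defaults
  pr6 <- make_read_pairs(n_pairs = 5, read_length = 60, overlap = 18,
                         q = 38, errors_per_pair = 6, seed = 163)
  res6 <- merge_pairs(pr6$forward, pr6$reverse)
  expect_true(all(res6$status != "merged"))
  expect_true(any(grepl("differences", res6$status)))
  # the same pairs pass with maxdiffs raised
  res6b <- merge_pairs(pr6$forward, pr6$reverse, merge_options(maxdiffs = 8))
  expect_true(all(res6b$status == "merged"))

  # staggered pair: reverse read extends left of the forward start
  set.seed(167)
  tpl <- rand_seq(80)
  fwd <- amp_records(substr(tpl, 11, 70),  # starts inside the template
                     quality = list(rep(38L, 60)))
  rev <- amp_records(reverse_complement(substr(tpl, 1, 60)),
                     quality = list(rep(38L, 60)))
  def <- merge_pair(fwd[1, ], rev[1, ])
  expect_false(def$status == "merged")
  ok <- merge_pair(fwd[1, ], rev[1, ], merge_options(allow_stagger = TRUE))
  expect_equal(ok$status, "merged")
  # overhangs trimmed: merged covers template positions 11..70
  expect_equal(ok$merged$sequence, substr(tpl, 11, 70))
})

test_that("disagreements keep the higher-quality base, forward on ties", {
  f <- amp_records("AAAAAAAAAAAA", quality = list(rep(40L, 12)))
  r_seq <- "AAAAAAAAAAAA"
  r_seq_mut <- paste0("AAAAA", "C", "AAAAAA")  # disagrees at column 6
  rv <- amp_records(reverse_complement(r_seq_mut),
                    quality = list(rep(20L, 12)))
  res <- merge_pair(f[1, ], rv[1, ])
  expect_equal(res$status, "merged")
  expect_equal(substr(res$merged$sequence, 6, 6), "A")  # forward q40 wins
  # posterior at the disagreeing column is dragged down
  expect_lte(res$merged$quality[[1]][6], 40L)
  # reversed roles: reverse read has the better quality
  f2 <- amp_records(r_seq_mut, quality = list(rep(20L, 12)))
  rv2 <- amp_records(reverse_complement(r_seq), quality = list(rep(40L, 12)))
  res2 <- merge_pair(f2[1, ], rv2[1, ])
  expect_equal(substr(res2$merged$sequence, 6, 6), "A")
  expect_error(merge_pair(amp_records("ACGT"), amp_records("ACGT")),
               "qualit")
})

test_that("merged length bounds apply", {
  pr <- make_read_pairs(n_pairs = 3, read_length = 60, overlap = 20,
                        q = 35, seed = 173)
  long <- merge_pairs(pr$forward, pr$reverse,
                      merge_options(minmergelen = 150))
  expect_true(all(long$status == "merged length out of range"))
  short <- merge_pairs(pr$forward, pr$reverse,
                       merge_options(maxmergelen = 50))
  expect_true(all(short$status == "merged length out of range"))
})
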