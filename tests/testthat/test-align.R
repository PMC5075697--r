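test_that("trivial alignments have the expected structure", {
  p <- align_params()
  a <- global_align("ACGT", "ACGT", p)
  expect_equal(a$score, 4 * p$match)
  expect_equal(a$matches, 4)
  expect_equal(a$internal_gap_columns + a$terminal_gap_columns, 0)
  b <- global_align("ACGT", "AGGT", p)
  expect_equal(b$matches, 3)
  expect_equal(b$mismatches, 1)
  expect_error(global_align("", "ACGT"), "non-empty")
})

test_that("DP score equals exhaustive enumeration on tiny instances", {
  p <- align_params()
  p2 <- align_params(match = 1, mismatch = -1,
                     gap_open_interior_query = 2, gap_open_terminal_query = 1,
                     gap_open_interior_target = 3, gap_open_terminal_target = 0,
                     gap_extend_interior = 1, gap_extend_terminal = 1)
  set.seed(101)
  for (i in 1:40) {
    a <- rand_seq(sample(1:5, 1))
    b <- rand_seq(sample(1:5, 1))
    par <- if (i %% 2) p else p2
    want <- enum_align_score(a, b, par)
    expect_equal(global_align(a, b, par, method = "full")$score, want)
    expect_equal(global_align(a, b, par, method = "linear")$score, want)
  }
})

test_that("full DP agrees with the independent full-matrix scorer", {
  p <- align_params()
  set.seed(7)
  for (i in 1:200) {
    la <- sample(10:60, 1)
    a <- rand_seq(la)
    b <- if (i %% 2) rand_seq(sample(10:60, 1)) else mutate_at_rate(a, 0.15)
    got <- global_align(a, b, p, method = "full")
    expect_equal(got$score, .align_score_oracle_cpp(a, b, unclass(p)))
    # column accounting invariant
    expect_equal(got$matches + got$mismatches + got$internal_gap_columns +
                   got$terminal_gap_columns, got$columns)
  }
})

test_that("linear-memory variant reproduces full DP on score and identity", {
  p <- align_params()
  set.seed(17)
  for (i in 1:50) {
    a <- rand_seq(sample(100:300, 1))
    b <- if (i %% 2) rand_seq(sample(100:300, 1)) else mutate_at_rate(a, 0.1)
    full <- global_align(a, b, p, method = "full")
    lin <- global_align_linear(a, b, p)
    expect_equal(lin$score, full$score)
    expect_equal(compute_identity(lin), compute_identity(full))
    expect_equal(lin$matches, full$matches)
  }
})

test_that("long identical pair takes the linear path and is all-match", {
  set.seed(3)
  a <- rand_seq(6000)  # product 3.6e7 > 25e6: linear path is mandatory
  r <- global_align(a, a)
  expect_equal(r$method, "linear")
  expect_equal(r$matches, 6000)
  expect_equal(r$score, 2 * 6000)
})

test_that("score is symmetric and monotone under shared suffixes", {
  p <- align_params()  # query/target penalties equal by default
  # suffix monotonicity needs uniform gap pricing: with discounted
  # terminal gaps, appending a suffix can turn a cheap trailing gap into
  # an expensive interior one
  pu <- align_params(gap_open_terminal_query = 20,
                     gap_open_terminal_target = 20,
                     gap_extend_terminal = 2)
  set.seed(23)
  for (i in 1:20) {
    a <- rand_seq(sample(10:50, 1)); b <- rand_seq(sample(10:50, 1))
    expect_equal(global_align(a, b, p)$score, global_align(b, a, p)$score)
    suf <- rand_seq(10)
    expect_gte(global_align(paste0(a, suf), paste0(b, suf), pu)$score,
               global_align(a, b, pu)$score)
  }
})

test_that("identity definitions follow their formulas", {
  a <- global_align(strrep("ACGTACGTAC", 1), "ACGTACGTAC")
  for (d in 0:4) expect_equal(compute_identity(a, d), 1.0)
  # 9 matches + 1 mismatch, no gaps
  b <- global_align("ACGTACGTAC", "ACGTACGTAG")
  for (d in 1:4) expect_equal(compute_identity(b, d), 0.9)
  # 90 matches plus a 10-column terminal gap
  core <- rand_seq(90)
  cc <- global_align(core, paste0(core, strrep("A", 10)),
                     align_params(mismatch = -40))
  expect_equal(cc$columns, 100)
  expect_equal(cc$terminal_gap_columns, 10)
  expect_equal(compute_identity(cc, 1), 0.90)
  expect_equal(compute_identity(cc, 2), 1.00)
  expect_equal(compute_identity(cc, 0), 1.00)  # matches / min(len)
})

test_that("N scores zero and never counts as an identity match", {
  p <- align_params()
  r <- global_align("ACNT", "ACGT", p)
  expect_equal(r$score, 3 * p$match)  # N column contributes 0
  expect_equal(r$matches, 3)
  expect_equal(r$mismatches, 1)
  # compatible ambiguity codes score as match but identity counts textual
  r2 <- global_align("ACRT", "ACGT", p)
  expect_equal(r2$score, 4 * p$match)
  expect_equal(r2$matches, 3)
})
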