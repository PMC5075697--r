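test_that("identical inputs form a single cluster; partition holds", {
  r <- amp_records(rep(rand_seq(100), 5), abundance = c(2, 1, 1, 3, 1))
  cl <- cluster_records(r, id = 0.97)
  expect_equal(length(cl$clusters), 1L)
  expect_equal(cl$clusters[[1]]$total_abundance, 8)
  # every record in exactly one cluster; abundance conserved
  expect_equal(sort(unlist(lapply(cl$clusters, function(c0)
    c(c0$centroid, c0$members)))), seq_len(nrow(r)))
})

test_that("well-separated families cluster exactly at 97%", {
  fam <- make_families(n_families = 4, members_per_family = 5,
                       template_length = 250, member_divergence = 0.02,
                       seed = 9)
  cl <- cluster_records(fam$records, id = 0.97, mode = "size")
  expect_equal(length(cl$clusters), 4L)
  got <- cl$assignment$cluster[match(fam$truth$label, cl$assignment$label)]
  expect_equal(mclust::adjustedRandIndex(got, fam$truth$family), 1.0)
  # every member meets the threshold to its centroid
  for (c0 in cl$clusters)
    if (nrow(c0$hits)) expect_true(all(c0$hits$id >= 0.97))
  # abundance partition
  expect_equal(sum(vapply(cl$clusters, function(c0) c0$total_abundance,
                          numeric(1))), sum(fam$records$abundance))
})

test_that("DGC joins the most similar, AGC the most abundant centroid", {
  set.seed(71)
  recs <- make_dgc_agc_fixture()
  opts <- search_options(maxaccepts = 2)
  dgc <- cluster_records(recs, id = 0.95, mode = "smallmem", opts = opts)
  agc <- cluster_records(recs, id = 0.95, mode = "smallmem", opts = opts,
                         sizeorder = TRUE)
  a_dgc <- dgc$assignment
  a_agc <- agc$assignment
  expect_equal(a_dgc$cluster[a_dgc$label == "q"], 1L)  # joins C1 (closest)
  expect_equal(a_agc$cluster[a_agc$label == "q"], 2L)  # joins C2 (biggest)
})

test_that("mode orderings equal cluster_smallmem on pre-sorted input", {
  fam <- make_families(3, 4, 180, 0.02, seed = 13)
  r <- fam$records
  opts <- search_options()
  sizes <- function(cl) vapply(cl$clusters, function(c0)
    c0$total_abundance, numeric(1))
  by_len <- r[order(-nchar(r$sequence), -r$abundance, r$ordinal), ]
  expect_equal(sizes(cluster_records(by_len, 0.97, "smallmem", opts = opts)),
               sizes(cluster_records(r, 0.97, "fast", opts = opts)))
  by_ab <- r[order(-r$abundance, -nchar(r$sequence), r$ordinal), ]
  expect_equal(sizes(cluster_records(by_ab, 0.97, "smallmem", opts = opts)),
               sizes(cluster_records(r, 0.97, "size", opts = opts)))
})

test_that("clustering output is invariant to the threads argument", {
  fam <- make_families(3, 4, 150, 0.02, seed = 29)
  c1 <- cluster_records(fam$records, 0.97, "size", threads = 1)
  c8 <- cluster_records(fam$records, 0.97, "size", threads = 8)
  expect_identical(c1$assignment, c8$assignment)
})

test_that("center-star MSA merges member alignments on the centroid", {
  # singleton: the MSA is the centroid itself
  r1 <- amp_records("ACGTACGT")
  cl1 <- cluster_records(r1, 0.97)
  ms1 <- center_star_msa(cl1, 1)
  expect_equal(unname(ms1$msa), "ACGTACGT")
  expect_equal(ms1$consensus, "ACGTACGT")

  # member with one internal insertion: columns = centroid length + 1 and
  # the centroid row gains exactly one gap
  set.seed(311)
  cen <- rand_seq(24)
  mem <- paste0(substr(cen, 1, 12), "T", substr(cen, 13, 24))
  recs <- amp_records(c(cen, mem), label = c("cen", "mem"),
                      abundance = c(5L, 1L))
  cl <- cluster_records(recs, id = 0.9,
                        opts = search_options(minwordmatches = 1,
                                              wordlength = 3, qmask = "none"))
  expect_equal(length(cl$clusters), 1L)
  ms <- center_star_msa(cl, 1)
  expect_equal(unique(nchar(ms$msa)), 25L)
  expect_equal(sum(strsplit(ms$msa[["cen"]], "")[[1]] == "-"), 1L)
  # abundance-weighted consensus keeps the centroid's letters, minus the gap
  expect_equal(ms$consensus, cen)

  # consensus ties resolve by the fixed symbol order A < C < G < T
  tie <- amp_records(c("AAAA", "AAAC"), abundance = c(1L, 1L))
  clt <- cluster_records(tie, id = 0.7,
                         opts = search_options(minwordmatches = 1,
                                               wordlength = 3, qmask = "none"))
  mst <- center_star_msa(clt, 1)
  expect_equal(substr(mst$consensus, 4, 4), "A")
})
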