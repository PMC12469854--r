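test_that("hypergeom_upper_tail matches the exact pmf-sum oracle", {
  expect_equal(hypergeom_upper_tail(2, 4, 3, 10), 70 / 210, tolerance = 1e-12)
  expect_identical(hypergeom_upper_tail(0, 4, 3, 10), 1.0)
  expect_identical(hypergeom_upper_tail(5, 5, 5, 5), 1.0)
  set.seed(8)
  for (i in 1:200) {
    N <- sample(2:25, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    x <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_upper_tail(x, n, K, N),
                 oracle_upper_tail(x, n, K, N), tolerance = 1e-12)
  }
  expect_error(hypergeom_upper_tail(4, 3, 5, 10), "exceeds")
  expect_error(hypergeom_upper_tail(1, 11, 5, 10), "exceed N")
})

test_that("bh_adjust implements the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(12)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, stats::p.adjust(p, "BH"))
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    # invariant under permutation of input order
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
})

test_that("enrich reproduces the pathway fixture counts", {
  study <- fixture_common_degs("up")
  terms <- fixture_pathways()
  res <- enrich(study, terms, study$members)
  calcium <- res[res$term_id == "hsa04020", ]
  expect_identical(calcium$count, 4L)
  expect_setequal(strsplit(calcium$hit_genes, "/")[[1]],
                  c("PLN", "CASQ2", "CACNA1H", "MET"))
  # every fixture term has >= 2 hits, so all 17 rows survive the filter
  expect_identical(nrow(res), 17L)
  # ordering: count desc, then p asc, then term_id
  expect_identical(res$term_id[1], "hsa04020")
  expect_true(all(diff(res$count) <= 0))
})

test_that("enrich p-values agree with brute-force enumeration on a small universe", {
  uni <- make_universe(sprintf("G%02d", 1:20))
  study <- sprintf("G%02d", 1:6)
  terms <- list(
    list(term_id = "t1", description = "d1", namespace = "pathway",
         members = sprintf("G%02d", c(1, 2, 3, 10))),
    list(term_id = "t2", description = "d2", namespace = "pathway",
         members = sprintf("G%02d", c(4, 5, 15, 16, 17))),
    list(term_id = "t3", description = "d3", namespace = "pathway",
         members = sprintf("G%02d", 11:14)))
  res <- enrich(study, terms, uni, min_count = 0)
  for (i in seq_len(nrow(res))) {
    tm <- terms[[which(vapply(terms, `[[`, "", "term_id") == res$term_id[i])]]
    K <- length(intersect(tm$members, uni$genes))
    x <- res$count[i]
    expect_equal(res$p_value[i], oracle_upper_tail(x, 6, K, 20),
                 tolerance = 1e-12)
  }
  # term disjoint from study is absent under the default min_count = 2
  res2 <- enrich(study, terms, uni)
  expect_false("t3" %in% res2$term_id)
})

test_that("BH runs across all tested terms, before the count filter", {
  uni <- make_universe(sprintf("G%02d", 1:20))
  study <- sprintf("G%02d", 1:6)
  terms <- list(
    list(term_id = "a", description = "", namespace = "pathway",
         members = sprintf("G%02d", 1:3)),
    list(term_id = "b", description = "", namespace = "pathway",
         members = sprintf("G%02d", c(1, 2, 11))),
    list(term_id = "c", description = "", namespace = "pathway",
         members = sprintf("G%02d", 11:13)))
  all_p <- enrich(study, terms, uni, min_count = 0)
  filt <- enrich(study, terms, uni, min_count = 2)
  expect_gt(nrow(filt), 0)
  # adjusted value of a reported term must equal its value when all terms
  # (including later-filtered ones) entered the BH correction
  for (id in filt$term_id) {
    expect_identical(filt$p_adjusted[filt$term_id == id],
                     all_p$p_adjusted[all_p$term_id == id])
  }
})

test_that("study genes outside the universe are dropped with a warning", {
  uni <- make_universe(c("A", "B", "C"))
  terms <- list(list(term_id = "t", description = "", namespace = "BP",
                     members = c("A", "B")))
  expect_warning(res <- enrich(c("A", "B", "Z"), terms, uni), "outside")
  expect_identical(res$count, 2L)
  expect_error(enrich("A", terms, character(0)), "empty universe")
})

test_that("GMT fixtures parse and enrichment report writes", {
  terms <- fixture_pathways()
  expect_length(terms, 17)
  expect_identical(terms[[1]]$term_id, "hsa04020")
  expect_length(terms[[1]]$members, 4)
  res <- enrich(fixture_common_degs("up"), terms,
                fixture_common_degs("up")$members)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment(res, f)
  back <- read_tsv_table(f)
  expect_identical(back$ID, res$term_id)
  expect_identical(back$Count, res$count)
})
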