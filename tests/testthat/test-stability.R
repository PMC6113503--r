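test_that("nearest edition minimizes distance with earlier tie-break", {
  eds <- as.Date(c("2005-03-01", "2005-04-01"))
  expect_equal(nearest_edition("2005-03-20", eds), as.Date("2005-04-01"))
  expect_equal(nearest_edition("2005-03-01", eds), as.Date("2005-03-01"))
  # equidistant (15 days either way) breaks toward the earlier edition
  eds2 <- as.Date(c("2005-03-01", "2005-03-31"))
  expect_equal(nearest_edition("2005-03-16", eds2), as.Date("2005-03-01"))
})

test_that("complete Jaccard covers identity, overlap, disjoint and empty", {
  expect_equal(complete_jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(complete_jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(complete_jaccard(c("a"), c("b")), 0)
  expect_equal(complete_jaccard(character(0), character(0)), 1)
  expect_equal(complete_jaccard(character(0), c("a")), 0)
})

fake_result <- function(term_ids, p = seq_along(term_ids) / 1000) {
  structure(list(table = data.frame(
    term_id = term_ids, p = p, q = p * 2,
    significant = rep(TRUE, length(term_ids)), stringsAsFactors = FALSE),
    significant = term_ids), class = "go_enrichment")
}

test_that("top-term-parents Jaccard expands top terms by their ancestors", {
  ont <- parse_obo(obo_text(
    obo_stanza("GO:0000001", name = "root"),
    obo_stanza("GO:0000002", is_a = "GO:0000001", name = "A"),
    obo_stanza("GO:0000003", is_a = "GO:0000001", name = "B")
  ), "2005-01-01")
  # top terms {A} and {B}, both children of the root: {A, R} vs {B, R} = 1/3
  expect_equal(top_term_parents_jaccard(fake_result("GO:0000002"),
                                        fake_result("GO:0000003"),
                                        ont, ont), 1 / 3)
  expect_equal(top_term_parents_jaccard(fake_result("GO:0000002"),
                                        fake_result("GO:0000002"),
                                        ont, ont), 1)
  expect_equal(top_term_parents_jaccard(fake_result(character(0)),
                                        fake_result("GO:0000002"),
                                        ont, ont), 0)
  # symmetric in its two results
  expect_equal(top_term_parents_jaccard(fake_result("GO:0000003"),
                                        fake_result("GO:0000002"),
                                        ont, ont), 1 / 3)
})

test_that("top-term selection ranks by p with deterministic tie-break", {
  ont <- parse_obo(obo_text(
    obo_stanza("GO:0000001"),
    obo_stanza("GO:0000002", is_a = "GO:0000001"),
    obo_stanza("GO:0000003", is_a = "GO:0000001"),
    obo_stanza("GO:0000004", is_a = "GO:0000001")
  ), "2005-01-01")
  r <- fake_result(c("GO:0000004", "GO:0000002", "GO:0000003"),
                   p = c(0.001, 0.002, 0.003))
  # top_k = 1 keeps only the smallest-p term GO:0000004
  expect_equal(top_term_parents_jaccard(r, fake_result("GO:0000004"),
                                        ont, ont, top_k = 1L), 1)
})

test_that("the permutation null pools derangement re-pairings reproducibly", {
  disjoint <- lapply(1:6, function(i)
    list(E0 = paste0("t", i, letters[1:5]), E1 = paste0("t", i, letters[6:10])))
  null1 <- build_null(disjoint, n_rounds = 20, seed = 5)
  expect_true(all(null1 == 0))
  same <- lapply(1:6, function(i) list(E0 = letters[1:6], E1 = letters[1:6]))
  expect_true(all(build_null(same, n_rounds = 5, seed = 5) == 1))
  expect_identical(build_null(disjoint, n_rounds = 10, seed = 9),
                   build_null(disjoint, n_rounds = 10, seed = 9))
  expect_error(build_null(disjoint[1], n_rounds = 5, seed = 1),
               class = "gochrono_config_error")
  # pairs where both members are below the threshold are not retained
  tiny <- lapply(1:4, function(i) list(E0 = "x", E1 = "y"))
  expect_length(build_null(tiny, n_rounds = 3, seed = 1), 0L)
})

# a compact simulated study for end-to-end stability checks
small_study <- function() {
  sim <- simulate_preset("stable", seed = 7, n_editions = 30L, n_genes = 150L,
                         n_lists = 25L, genes_per_list = 20L)
  series <- build_series(sim$annotation_history, sim$ontology_history)
  list(sim = sim, series = series,
       params = enrichment_params(min_term_size = 5L, max_term_size = 60L))
}

test_that("self-comparison at t0 = t_now yields Jaccard 1 and stable flags", {
  st <- small_study()
  t_now <- max(st$series$dates)
  res <- suppressWarnings(stability_analysis(
    st$sim$hit_lists, st$series, st$params, t_now = t_now, fixed_t0 = t_now,
    n_rounds = 50L, seed = 3L))
  expect_true(all(res$reports$complete_jaccard == 1))
  expect_true(all(res$reports$n_sig_t0 == res$reports$n_sig_now))
  if (res$null_p95 < 1) expect_true(all(res$reports$stable))
  expect_true(all(res$reports$age_years == 0))
})

test_that("stability reports respect the corpus filter and age binning", {
  st <- small_study()
  t_now <- max(st$series$dates)
  res <- suppressWarnings(stability_analysis(
    st$sim$hit_lists, st$series, st$params, t_now = t_now,
    n_rounds = 100L, seed = 3L))
  r <- res$reports
  # retained lists have at least five significant terms at one time point
  expect_true(all(pmax(r$n_sig_t0, r$n_sig_now) >= 5))
  # age bins partition the retained corpus
  expect_true(all(r$age_bin %in% c("recent", "old", "oldest")))
  expect_equal(sum(unlist(res$summary$n_by_bin)), nrow(r))
  # percentile definition: fraction of null strictly below the observation
  i <- which.max(r$complete_jaccard)
  expect_equal(r$null_percentile[[i]],
               100 * mean(res$null < r$complete_jaccard[[i]]))
  # stable flag matches the strict-exceedance rule
  expect_equal(r$stable, r$complete_jaccard > res$null_p95)
  # determinism under the same seed
  res2 <- suppressWarnings(stability_analysis(
    st$sim$hit_lists, st$series, st$params, t_now = t_now,
    n_rounds = 100L, seed = 3L))
  expect_equal(res$reports, res2$reports)
  expect_identical(res$null, res2$null)
})
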