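small_params <- function(...) {
  defaults <- list(n_terms_initial = 60L, term_birth_rate = 1, n_genes = 50L,
                   n_editions = 12L, annotation_gain_rate = 0.3,
                   initial_annotations_per_gene = 3, churn_probability = 0.05,
                   obsolescence_rate = 0.1, seed = 11L)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_params, args)
}

test_that("generated histories are deterministic functions of the seed", {
  p <- small_params()
  o1 <- simulate_ontology_history(p)
  o2 <- simulate_ontology_history(p)
  expect_identical(lapply(o1, gochrono:::canonical_ontology),
                   lapply(o2, gochrono:::canonical_ontology))
  a1 <- simulate_annotation_history(o1, p)
  a2 <- simulate_annotation_history(o2, p)
  expect_identical(lapply(a1, gochrono:::canonical_annotations),
                   lapply(a2, gochrono:::canonical_annotations))
  c1 <- simulate_hitlist_corpus(a1, o1, p, n_lists = 6L, genes_per_list = 10L)
  c2 <- simulate_hitlist_corpus(a2, o2, p, n_lists = 6L, genes_per_list = 10L)
  expect_identical(c1$truth, c2$truth)
  expect_identical(lapply(c1$hit_lists, `[[`, "genes"),
                   lapply(c2$hit_lists, `[[`, "genes"))
})

test_that("a zero-growth ontology history is stationary", {
  p <- small_params(term_birth_rate = 0, obsolescence_rate = 0)
  oh <- simulate_ontology_history(p)
  first <- gochrono:::canonical_ontology(oh[[1]])
  for (o in oh[-1]) {
    cc <- gochrono:::canonical_ontology(o)
    expect_identical(cc$terms, first$terms)
    expect_identical(cc$edges, first$edges)
  }
})

test_that("term counts grow over a long seeded history", {
  p <- small_params(n_editions = 50L, term_birth_rate = 2)
  oh <- simulate_ontology_history(p)
  n <- vapply(oh, function(o) sum(!o$terms$obsolete), integer(1))
  expect_gt(n[[50]], n[[1]])
  expect_true(all(diff(vapply(oh, function(o) nrow(o$terms), integer(1))) >= 0))
})

test_that("every simulated edition passes the validators by construction", {
  p <- small_params()
  oh <- simulate_ontology_history(p)
  ah <- simulate_annotation_history(oh, p)
  for (o in oh) expect_s3_class(o, "go_ontology")
  for (a in ah) {
    expect_s3_class(a, "go_annotations")
    expect_false(any(duplicated(
      a$records[c("accession", "term_id", "evidence_code")])))
  }
})

test_that("accretion without churn or purges never loses annotations", {
  p <- small_params(churn_probability = 0, obsolescence_rate = 0)
  oh <- simulate_ontology_history(p)
  ah <- simulate_annotation_history(oh, p)
  for (g in syn_genes <- unique(ah[[1]]$records$accession)) {
    counts <- vapply(ah, function(a)
      length(unique(a$records$term_id[a$records$accession == g])), integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("a discontinuity purges redundant directs, leaving closures intact", {
  p <- small_params(n_editions = 16L, discontinuity_editions = 9L,
                    n_genes = 120L, annotation_gain_rate = 0.25)
  oh <- simulate_ontology_history(p)
  ah <- simulate_annotation_history(oh, p)
  tr <- species_trends(build_series(ah, oh))
  expect_lt(tr$mean_direct_per_gene[[9]], tr$mean_direct_per_gene[[8]])
  expect_identical(tr$mean_inferred_per_gene[[9]], tr$mean_inferred_per_gene[[8]])
  expect_identical(tr$annotated_genes[[9]], tr$annotated_genes[[8]])
})

test_that("annotation inequality persists across the history", {
  p <- small_params(n_editions = 30L, inequality_exponent = 0.8)
  oh <- simulate_ontology_history(p)
  ah <- simulate_annotation_history(oh, p)
  s <- build_series(ah, oh)
  rho <- annotation_rank_stability(s, s$dates[[1]], s$dates[[30]])
  expect_gt(rho, 0)
})

test_that("churned annotations disappear and come back (IEA only)", {
  p <- small_params(n_editions = 20L, churn_probability = 0.2,
                    annotation_gain_rate = 0.05)
  oh <- simulate_ontology_history(p)
  ah <- simulate_annotation_history(oh, p)
  key <- function(a) paste(a$records$accession, a$records$term_id,
                           a$records$evidence_code)
  keys <- lapply(ah, key)
  # find a pair present, absent, then present again
  all_keys <- unique(unlist(keys))
  present <- vapply(all_keys, function(k)
    paste(vapply(keys, function(ks) k %in% ks, logical(1)) + 0, collapse = ""),
    character(1))
  churned <- grepl("10+1", present)
  expect_true(any(churned))
  # churned pairs carry the automatic evidence code
  ev <- vapply(strsplit(all_keys[churned], " "), `[[`, character(1), 3L)
  expect_true(all(ev == "IEA"))
})

test_that("hit lists sample their module genes and validate sizes", {
  p <- small_params()
  oh <- simulate_ontology_history(p)
  ah <- simulate_annotation_history(oh, p)
  co <- simulate_hitlist_corpus(ah, oh, p, n_lists = 6L, genes_per_list = 10L)
  expect_length(co$hit_lists, 6L)
  for (i in seq_along(co$hit_lists)) {
    h <- co$hit_lists[[i]]
    expect_length(h$genes, 10L)
    expect_false(is.null(h$publication_date))
    e <- co$truth$pub_edition[[i]]
    pe <- propagate_edition(co$annotation_history[[e]], oh[[e]], quiet = TRUE)
    in_module <- vapply(h$genes, function(g)
      co$truth$module_term[[i]] %in% (pe$gene_to_propagated[[g]] %||% character(0)),
      logical(1))
    expect_gte(sum(in_module), ceiling(0.5 * length(h$genes)))
  }
  expect_error(
    simulate_hitlist_corpus(ah, oh, p, n_lists = 2L, genes_per_list = 999L),
    class = "gochrono_config_error")
})

test_that("generated editions round-trip through the OBO and GAF writers", {
  p <- small_params(n_editions = 6L)
  oh <- simulate_ontology_history(p)
  ah <- simulate_annotation_history(oh, p)
  for (e in c(1L, 6L)) {
    o <- oh[[e]]
    o2 <- parse_obo(write_obo(o), o$edition_date)
    expect_identical(gochrono:::canonical_ontology(o2),
                     gochrono:::canonical_ontology(o))
    a <- ah[[e]]
    a2 <- parse_gaf(write_gaf(a), a$species, a$edition_date)
    expect_identical(gochrono:::canonical_annotations(a2),
                     gochrono:::canonical_annotations(a))
  }
})
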