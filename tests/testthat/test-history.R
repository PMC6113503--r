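# Fixture: chain ontology a <- b <- c with a small two-edition series.
history_series <- function() {
  chain <- chain_ontology()
  e1 <- toy_edition(c(gaf_line("P1", "GO:0000002", "IEA"),
                      gaf_line("P2", "GO:0000002", "IDA")),
                    chain, date = "2005-01-05")
  e2 <- toy_edition(c(gaf_line("P1", "GO:0000002", "IEA"),
                      gaf_line("P1", "GO:0000003", "IEA"),
                      gaf_line("P2", "GO:0000001", "IDA")),
                    chain, date = "2005-02-05")
  edition_series(list(e1, e2))
}

test_that("gene count series reports per-edition counts and taxon mean", {
  s <- history_series()
  g <- gene_count_series(s, "P1", mode = "direct")
  expect_equal(g$count, c(1L, 2L))
  expect_equal(g$species_mean, c(1, 1.5))
  # absent gene reports zero
  expect_equal(gene_count_series(s, "P9", mode = "direct")$count, c(0L, 0L))
  # propagated counts are closure sizes
  gp <- gene_count_series(s, "P1", mode = "propagated")
  expect_equal(gp$count, c(2L, 3L))
})

test_that("semantic similarity is the Jaccard against the reference edition", {
  s <- history_series()
  ss <- semantic_similarity_series(s, "P1", "2005-02-05", mode = "direct")
  # edition 1 {b} vs reference {b, c}: 1/2; reference vs itself: 1
  expect_equal(ss$similarity, c(0.5, 1))
  # unannotated gene: both sets empty at every edition
  expect_equal(semantic_similarity_series(s, "P9", "2005-02-05")$similarity,
               c(1, 1))
  expect_error(semantic_similarity_series(s, "P1", "1999-01-01"),
               class = "gochrono_lookup_error")
  # direct check of the stated 1/3 case
  expect_equal(jaccard(c("a", "b"), c("b", "c")), 1 / 3)
})

test_that("multifunctionality follows the specificity-weighted formula", {
  ont <- parse_obo(obo_text(
    obo_stanza("GO:0000001", name = "root"),
    obo_stanza("GO:0000002", is_a = "GO:0000001"),
    obo_stanza("GO:0000003", is_a = "GO:0000001")
  ), "2005-01-01")
  pe <- toy_edition(c(gaf_line("P1", "GO:0000002"), gaf_line("P2", "GO:0000002"),
                      gaf_line("P3", "GO:0000003"), gaf_line("P4", "GO:0000003")),
                    ont)
  # N = 4; each gene has one term with n_t = 2 (weight 1/4) plus the
  # universal root (weight 0)
  expect_equal(as.numeric(multifunctionality(pe, "P1")), 0.25)
  # identical propagated sets give identical scores
  expect_equal(as.numeric(multifunctionality(pe, "P1")),
               as.numeric(multifunctionality(pe, "P2")))
  # a gene annotated only to the universal term scores 0
  pe2 <- toy_edition(c(gaf_line("P1", "GO:0000001"), gaf_line("P2", "GO:0000002"),
                       gaf_line("P3", "GO:0000002"), gaf_line("P4", "GO:0000001")),
                     ont)
  expect_equal(as.numeric(multifunctionality(pe2, "P1")), 0)
  expect_error(multifunctionality(pe, "P9"), class = "gochrono_lookup_error")
  # relabeling accessions leaves the score set unchanged
  scores <- multifunctionality(pe)
  expect_setequal(scores$score, c(0.25, 0.25, 0.25, 0.25))
})

test_that("term gene count series counts direct vs propagated support", {
  chain <- chain_ontology()
  # 3 genes direct on b; 2 more via descendant c
  pe <- toy_edition(c(gaf_line("P1", "GO:0000002"), gaf_line("P2", "GO:0000002"),
                      gaf_line("P3", "GO:0000002", "IDA"),
                      gaf_line("P4", "GO:0000003"), gaf_line("P5", "GO:0000003")),
                    chain, date = "2005-01-05")
  s <- edition_series(list(pe))
  expect_equal(term_gene_count_series(s, "GO:0000002", mode = "direct")$count, 3L)
  expect_equal(term_gene_count_series(s, "GO:0000002", mode = "propagated")$count, 5L)
  # evidence split: IEA-only support is automatic, any curated record wins
  tb <- term_gene_count_series(s, "GO:0000002",
                               breakdown = "by_evidence_category",
                               mode = "propagated")
  expect_equal(tb$automatic, 4L)
  expect_equal(tb$curated, 1L)
  # unknown/absent term reports zero
  expect_equal(term_gene_count_series(s, "GO:0009999")$count, 0L)
})

test_that("species trends compute per-edition means over annotated genes", {
  chain <- chain_ontology()
  # P1 direct {c}; P2 direct {a, b, c} -> mean direct 2; both propagate to 3
  pe <- toy_edition(c(gaf_line("P1", "GO:0000003"),
                      gaf_line("P2", "GO:0000001"), gaf_line("P2", "GO:0000002"),
                      gaf_line("P2", "GO:0000003")),
                    chain, date = "2005-01-05")
  tr <- species_trends(edition_series(list(pe)))
  expect_equal(tr$annotated_genes, 2L)
  expect_equal(tr$mean_direct_per_gene, 2)
  expect_equal(tr$mean_inferred_per_gene, 3)
  expect_gte(tr$mean_inferred_per_gene, tr$mean_direct_per_gene)
  # terms a, b, c each cover both genes after propagation
  expect_equal(tr$mean_annotations_per_term, 2)
  # empty edition degenerates to zeros
  empty <- toy_edition(character(0), chain, date = "2005-03-05")
  tr0 <- species_trends(edition_series(list(empty)))
  expect_equal(tr0$annotated_genes, 0L)
  expect_equal(tr0$mean_direct_per_gene, 0)
})

test_that("rank stability matches a rank-then-Pearson oracle", {
  chain <- chain_ontology()
  mk <- function(counts, date) {
    lines <- unlist(lapply(seq_along(counts), function(i) {
      terms <- c("GO:0000001", "GO:0000002", "GO:0000003")[seq_len(counts[[i]])]
      vapply(terms, function(t) gaf_line(sprintf("P%02d", i), t), character(1))
    }))
    toy_edition(lines, chain, date = date)
  }
  s <- edition_series(list(mk(c(1, 2, 3), "2005-01-05"),
                           mk(c(1, 2, 3), "2005-02-05"),
                           mk(c(3, 2, 1), "2005-03-05")))
  expect_equal(annotation_rank_stability(s, "2005-01-05", "2005-02-05"), 1)
  expect_equal(annotation_rank_stability(s, "2005-01-05", "2005-03-05"), -1)

  # oracle equivalence on random count vectors: spearman == pearson of ranks
  set.seed(303)
  x <- sample(0:20, 50, replace = TRUE)
  y <- sample(0:20, 50, replace = TRUE)
  expect_equal(cor(x, y, method = "spearman"),
               cor(rank(x), rank(y)), tolerance = 1e-12)

  s2 <- edition_series(list(mk(1, "2005-01-05"), mk(c(2, 1), "2005-02-05")))
  expect_error(annotation_rank_stability(s2, "2005-01-05", "2005-02-05"),
               class = "gochrono_insufficient_data")
})
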