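# Historical statistics over an edition series: per-gene and per-term
# count series, semantic similarity, multifunctionality, taxon trends.

#' Per-gene annotation count series
#'
#' Number of terms annotated to one gene at every edition, either direct
#' or propagated, together with the taxon average over annotated genes
#' at each edition (for overlay plots).
#'
#' @param series a `go_series`.
#' @param accession gene accession.
#' @param mode `"direct"` or `"propagated"`.
#' @return data.frame with columns `edition_date`, `count`,
#'   `species_mean`. Editions where the gene is unannotated report 0.
#' @export
gene_count_series <- function(series, accession,
                              mode = c("direct", "propagated")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "go_series"), length(accession) == 1L)
  rows <- lapply(series$editions, function(e) {
    sets <- if (mode == "direct") e$gene_to_direct else e$gene_to_propagated
    n <- length(sets[[accession]] %||% character(0))
    mu <- if (length(sets)) mean(lengths(sets)) else 0
    data.frame(edition_date = e$edition_date, count = n, species_mean = mu)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Semantic-similarity series for one gene
#'
#' Jaccard index between the gene's annotation set at each edition and
#' its set at a fixed reference edition. Two empty sets have similarity
#' 1; at the reference edition itself the value is always 1.
#'
#' @inheritParams gene_count_series
#' @param reference_date an edition date in the series (typically the
#'   most recent edition).
#' @return data.frame with columns `edition_date`, `similarity`.
#' @export
semantic_similarity_series <- function(series, accession, reference_date,
                                       mode = c("direct", "propagated")) {
  mode <- match.arg(mode)
  ref <- series_edition(series, reference_date)
  pick <- function(e) {
    sets <- if (mode == "direct") e$gene_to_direct else e$gene_to_propagated
    sets[[accession]] %||% character(0)
  }
  aref <- pick(ref)
  out <- data.frame(
    edition_date = series$dates,
    similarity = vapply(series$editions, function(e) jaccard(pick(e), aref),
                        numeric(1))
  )
  rownames(out) <- NULL
  out
}

# Raw and rank-normalized multifunctionality for all genes in one edition.
multifunctionality_scores <- function(pedition) {
  stopifnot(inherits(pedition, "go_propagated"))
  cache <- pedition$.cache
  if (!is.null(cache$mf)) return(cache$mf)
  sets <- pedition$gene_to_propagated
  N <- length(sets)
  counts <- term_gene_counts(pedition, "propagated")
  # per-term specificity weight 1 / (n_t (N - n_t)); universal terms get 0
  w <- ifelse(counts == N, 0, 1 / (counts * (N - counts)))
  score <- vapply(sets, function(t) sum(w[t]), numeric(1))
  rank_score <- if (N > 1L) (rank(score, ties.method = "average") - 1) / (N - 1)
                else rep(1, N)
  out <- data.frame(accession = names(sets), score = unname(score),
                    rank_score = unname(rank_score), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  cache$mf <- out
  out
}

#' Gene multifunctionality
#'
#' How heavily annotated a gene is relative to other genes, weighting
#' each of its propagated terms by specificity: the score is the sum
#' over the gene's propagated terms t of \eqn{1 / (n_t (N - n_t))},
#' where \eqn{n_t} is the number of genes annotated (after propagation)
#' to t and N the number of annotated genes in the edition. Terms
#' annotated to every gene carry no information and contribute 0. The
#' rank-normalized version rescales the within-edition ranks to
#' \[0, 1\].
#'
#' @param pedition a `go_propagated` edition.
#' @param accession a gene accession, or `NULL` for all genes.
#' @return for one accession, its numeric score (with the
#'   rank-normalized score as attribute `rank_score`); for `NULL`, a
#'   data.frame of all genes with columns `accession`, `score`,
#'   `rank_score`.
#' @export
multifunctionality <- function(pedition, accession = NULL) {
  scores <- multifunctionality_scores(pedition)
  if (is.null(accession)) return(scores)
  i <- match(accession, scores$accession)
  if (is.na(i)) {
    stop_gochrono(paste0("gene not annotated in this edition: ", accession),
                  "gochrono_lookup_error")
  }
  structure(scores$score[[i]], rank_score = scores$rank_score[[i]])
}

# Evidence category of a direct record: IEA is automatic, all else curated.
evidence_category <- function(evidence_code) {
  ifelse(evidence_code == "IEA", "automatic", "curated")
}

#' Per-term gene count series
#'
#' Number of distinct genes carrying one term at every edition, counted
#' on direct or propagated annotations, optionally split into
#' automatic (IEA) versus curated support. For the split, a gene counts
#' as curated when any direct record at or beneath the term is
#' non-IEA, otherwise as automatic.
#'
#' @param series a `go_series`.
#' @param term_id GO accession.
#' @param breakdown `"total"` or `"by_evidence_category"`.
#' @param mode `"direct"` or `"propagated"`.
#' @return data.frame with `edition_date` and `count` (plus `automatic`
#'   and `curated` for the split). Terms absent from an edition report 0.
#' @export
term_gene_count_series <- function(series, term_id,
                                   breakdown = c("total", "by_evidence_category"),
                                   mode = c("direct", "propagated")) {
  breakdown <- match.arg(breakdown)
  mode <- match.arg(mode)
  stopifnot(inherits(series, "go_series"), length(term_id) == 1L)
  rows <- lapply(series$editions, function(e) {
    id <- resolve_term_id(e$ontology, term_id)
    sets <- if (mode == "direct") e$gene_to_direct else e$gene_to_propagated
    genes <- if (is.na(id)) character(0) else {
      names(sets)[vapply(sets, function(t) id %in% t, logical(1))]
    }
    row <- data.frame(edition_date = e$edition_date, count = length(genes))
    if (breakdown == "by_evidence_category") {
      if (length(genes)) {
        rec <- e$annotations$records
        rec <- rec[rec$accession %in% genes, , drop = FALSE]
        # supporting records: direct annotations whose term propagates to id
        anc <- ancestor_map(e$ontology)
        supports <- rec$term_id == id |
          vapply(rec$term_id, function(t) id %in% anc[[t]], logical(1))
        rec <- rec[supports, , drop = FALSE]
        cat_by_gene <- tapply(evidence_category(rec$evidence_code),
                              rec$accession,
                              function(x) if ("curated" %in% x) "curated" else "automatic")
        row$automatic <- sum(cat_by_gene == "automatic")
        row$curated <- sum(cat_by_gene == "curated")
      } else {
        row$automatic <- 0L
        row$curated <- 0L
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Taxon-wide annotation trends
#'
#' One row per edition: the number of annotated genes, the mean number
#' of direct and of propagated (direct + inferred) annotations per
#' annotated gene, and the mean number of propagated genes per term
#' (over terms with at least one annotated gene at that date).
#'
#' @param series a `go_series`.
#' @return data.frame with columns `edition_date`, `annotated_genes`,
#'   `mean_direct_per_gene`, `mean_inferred_per_gene`,
#'   `mean_annotations_per_term`.
#' @export
species_trends <- function(series) {
  stopifnot(inherits(series, "go_series"))
  rows <- lapply(series$editions, function(e) {
    nd <- lengths(e$gene_to_direct)
    np <- lengths(e$gene_to_propagated)
    counts <- term_gene_counts(e, "propagated")
    data.frame(
      edition_date = e$edition_date,
      annotated_genes = length(nd),
      mean_direct_per_gene = if (length(nd)) mean(nd) else 0,
      mean_inferred_per_gene = if (length(np)) mean(np) else 0,
      mean_annotations_per_term = if (length(counts)) mean(counts) else 0
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank stability of per-gene annotation counts
#'
#' Spearman rank correlation (average ranks for ties) between per-gene
#' direct annotation counts at two editions, over the genes annotated at
#' both. Measures whether the inequality in annotation attention
#' persists over time.
#'
#' @param series a `go_series`.
#' @param date_a,date_b edition dates in the series.
#' @return a correlation in \[-1, 1\].
#' @export
annotation_rank_stability <- function(series, date_a, date_b) {
  ea <- series_edition(series, date_a)
  eb <- series_edition(series, date_b)
  shared <- intersect(names(ea$gene_to_direct), names(eb$gene_to_direct))
  if (length(shared) < 3L) {
    stop_gochrono("fewer than 3 genes annotated at both editions",
                  "gochrono_insufficient_data")
  }
  xa <- lengths(ea$gene_to_direct[shared])
  xb <- lengths(eb$gene_to_direct[shared])
  cor(xa, xb, method = "spearman")
}
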