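# Time-point-anchored overrepresentation analysis: hypergeometric upper
# tail over size-filtered terms, Benjamini-Hochberg FDR control.

#' Enrichment parameters
#'
#' Defaults follow standard practice for GO overrepresentation analysis
#' of curated hit lists: Biological Process terms with between 20 and
#' 200 annotated genes, FDR controlled at 5%.
#'
#' @param min_term_size,max_term_size inclusive bounds on the number of
#'   genes annotated to a term in the background for it to be tested.
#' @param aspect_filter GO aspects whose terms are tested.
#' @param fdr_threshold significance threshold on BH-adjusted q values.
#' @param term_size_mode whether term sizes count propagated (default)
#'   or direct annotations.
#' @return a `go_enrichment_params` object.
#' @export
enrichment_params <- function(min_term_size = 20L, max_term_size = 200L,
                              aspect_filter = "biological_process",
                              fdr_threshold = 0.05,
                              term_size_mode = c("propagated", "direct")) {
  term_size_mode <- match.arg(term_size_mode)
  stopifnot(min_term_size >= 0, min_term_size <= max_term_size,
            all(aspect_filter %in% ASPECTS),
            fdr_threshold > 0, fdr_threshold <= 1)
  structure(list(min_term_size = as.integer(min_term_size),
                 max_term_size = as.integer(max_term_size),
                 aspect_filter = aspect_filter,
                 fdr_threshold = fdr_threshold,
                 term_size_mode = term_size_mode),
            class = "go_enrichment_params")
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X hypergeometric: the probability of observing at
#' least `k` term-annotated genes in a hit list of size `n` drawn from a
#' background of `N` genes of which `K` carry the term. Vectorized over
#' its arguments.
#'
#' @param k hits in the term; `0 <= k <= min(n, K)`.
#' @param K term size in the background.
#' @param n hit-list size (within the background).
#' @param N background size.
#' @return upper-tail probabilities in (0, 1].
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  bad <- k < 0 | k > pmin(n, K) | n > N | K > N | K < 0 | n < 0
  if (any(bad)) {
    stop_gochrono(sprintf(
      "invalid contingency counts: k=%s K=%s n=%s N=%s",
      k[bad][[1L]], K[bad][[1L]], n[bad][[1L]], N[bad][[1L]]),
      "gochrono_domain_error")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment: each q value is the smallest
#' FDR level at which the corresponding hypothesis would be rejected.
#' Values are returned in input order.
#'
#' @param pvalues numeric vector of p values in \[0, 1\].
#' @return numeric vector of q values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop_gochrono("p values must lie in [0, 1]", "gochrono_domain_error")
  }
  p.adjust(pvalues, method = "BH")
}

#' Overrepresentation analysis at one time point
#'
#' Tests, for every ontology term that passes the aspect and size
#' filters, whether the hit list contains more genes annotated
#' (propagated) to the term than expected under hypergeometric sampling
#' from the background. The background is the set of all annotated
#' genes in the edition; hit-list genes absent from the background are
#' dropped before testing. BH adjustment is applied over the tested
#' terms only.
#'
#' @param hit_list character vector of gene accessions.
#' @param pedition a `go_propagated` edition (defines both the
#'   background and the annotation sets).
#' @param params a `go_enrichment_params` object.
#' @return a `go_enrichment` object: `table` (one row per tested term
#'   with k, K, n, N, p, q, significant), `significant` (term ids with
#'   q at or below the threshold), `background_size`, `n_hits_used`,
#'   `n_hits_dropped`, `edition_date`, `params`.
#' @export
run_enrichment <- function(hit_list, pedition, params = enrichment_params()) {
  stopifnot(inherits(pedition, "go_propagated"),
            inherits(params, "go_enrichment_params"))
  background <- names(pedition$gene_to_propagated)
  N <- length(background)
  if (N == 0L) {
    stop_gochrono("edition has an empty annotation background",
                  "gochrono_config_error")
  }
  hits <- intersect(unique(as.character(hit_list)), background)
  n_dropped <- length(unique(as.character(hit_list))) - length(hits)
  if (length(hits) == 0L) {
    stop_gochrono("hit list has no overlap with the annotated background",
                  "gochrono_empty_overlap")
  }
  n <- length(hits)

  counts <- term_gene_counts(pedition, params$term_size_mode)
  asp <- setNames(pedition$ontology$terms$aspect, pedition$ontology$terms$term_id)
  in_aspect <- asp[names(counts)] %in% params$aspect_filter
  size_ok <- counts >= params$min_term_size & counts <= params$max_term_size
  tested <- sort(names(counts)[in_aspect & size_ok])

  if (length(tested)) {
    k_tab <- table(unlist(pedition$gene_to_propagated[hits], use.names = FALSE))
    k <- integer(length(tested))
    found <- tested %in% names(k_tab)
    k[found] <- as.integer(k_tab[tested[found]])
    K <- as.integer(counts[tested])
    p <- hypergeometric_tail(k, K, n, N)
    q <- bh_adjust(p)
  } else {
    k <- integer(0); K <- integer(0); p <- numeric(0); q <- numeric(0)
  }
  nm <- setNames(pedition$ontology$terms$name, pedition$ontology$terms$term_id)
  tab <- data.frame(term_id = tested, name = unname(nm[tested]),
                    k = k, K = K,
                    n = rep(n, length(tested)), N = rep(N, length(tested)),
                    p = p, q = q,
                    significant = q <= params$fdr_threshold,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$p, tab$q, tab$term_id), , drop = FALSE]
  rownames(tab) <- NULL
  structure(
    list(edition_date = pedition$edition_date,
         table = tab,
         significant = tab$term_id[tab$significant],
         background_size = N,
         n_hits_used = n,
         n_hits_dropped = n_dropped,
         params = params),
    class = "go_enrichment"
  )
}

#' @export
print.go_enrichment <- function(x, n = 10L, ...) {
  cat(sprintf(
    "<go_enrichment> edition %s: %d/%d hit genes in background of %d; %d terms tested, %d significant (FDR %.2g)\n",
    format(x$edition_date), x$n_hits_used, x$n_hits_used + x$n_hits_dropped,
    x$background_size, nrow(x$table), length(x$significant),
    x$params$fdr_threshold))
  if (nrow(x$table)) {
    print(head(x$table[c("term_id", "name", "k", "K", "p", "q", "significant")], n))
  }
  invisible(x)
}
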