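# The full-scale drift study is expensive, so it is built once on first
# use and shared by the stability and acceptance tests.

.study_cache <- new.env(parent = emptyenv())

analysis_params <- function() {
  # term-size band proportionate to the 400-gene synthetic background
  enrichment_params(min_term_size = 10L, max_term_size = 100L)
}

drift_study <- function() {
  if (is.null(.study_cache$drift)) {
    sim <- simulate_preset("drift", seed = 42)
    series <- build_series(sim$annotation_history, sim$ontology_history)
    res <- suppressWarnings(stability_analysis(
      sim$hit_lists, series, analysis_params(),
      t_now = max(series$dates), n_rounds = 1000L, seed = 1L))
    .study_cache$drift <- list(sim = sim, series = series, res = res)
  }
  .study_cache$drift
}

# significant-term sets for the retained lists, for null re-pairing
drift_corpus_pairs <- function() {
  if (is.null(.study_cache$pairs)) {
    st <- drift_study()
    r <- st$res$reports
    idx <- match(r$name, vapply(st$sim$hit_lists, function(h) h$name,
                                character(1)))
    sig_at <- function(h, d) {
      tryCatch(
        run_enrichment(h$genes, gochrono:::series_edition(st$series, d),
                       analysis_params())$significant,
        gochrono_empty_overlap = function(e) character(0))
    }
    .study_cache$pairs <- lapply(seq_along(idx), function(i) {
      h <- st$sim$hit_lists[[idx[[i]]]]
      list(E0 = sig_at(h, r$t0[[i]]), E1 = sig_at(h, r$t_now[[i]]))
    })
  }
  .study_cache$pairs
}
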