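# Enrichment-result stability between two time points: Jaccard measures
# calibrated against a permutation null of re-paired hit lists.

#' A dated hit list
#'
#' @param name label for the gene set.
#' @param genes nonempty character vector of gene accessions.
#' @param publication_date optional date of the source publication,
#'   used to anchor the historical analysis time point.
#' @return a `go_hitlist` object.
#' @export
hitlist <- function(name, genes, publication_date = NULL) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) {
    stop_gochrono("hit list must contain at least one gene",
                  "gochrono_config_error")
  }
  structure(list(name = as.character(name), genes = genes,
                 publication_date = if (is.null(publication_date)) NULL
                                    else as_edition_date(publication_date,
                                                         "publication_date")),
            class = "go_hitlist")
}

#' Edition nearest to a date
#'
#' The edition whose date minimizes the absolute day difference to the
#' target; ties break toward the earlier edition. (Contrast with
#' [match_ontology()], which pairs annotation files with the closest
#' ontology release *before* them.)
#'
#' @param date target date (e.g. a publication date).
#' @param edition_dates nonempty vector of edition dates.
#' @return the nearest edition date.
#' @export
nearest_edition <- function(date, edition_dates) {
  d <- as_edition_date(date, "date")
  ed <- sort(as.Date(edition_dates))
  if (length(ed) == 0L) {
    stop_gochrono("no edition dates supplied", "gochrono_config_error")
  }
  dist <- abs(as.numeric(ed - d))
  ed[[which.min(dist)]]   # which.min takes the first (earlier) on ties
}

#' Complete Jaccard between two significant-term sets
#'
#' \eqn{|E0 \cap E1| / |E0 \cup E1|} over all significantly enriched
#' terms; both-empty is defined as 1.
#'
#' @param E0,E1 character vectors of significant term ids.
#' @return a number in \[0, 1\].
#' @export
complete_jaccard <- function(E0, E1) jaccard(E0, E1)

#' Top-term-parents Jaccard
#'
#' From each enrichment result take the `top_k` significant terms with
#' the smallest p values (ties broken by q, then term id), expand each
#' set by its ancestors in that result's own ontology edition, and
#' return the complete Jaccard of the two expanded sets. Focuses the
#' comparison on the headline findings while crediting agreement at
#' coarser granularity.
#'
#' @param R0,R1 `go_enrichment` results at the two time points.
#' @param ont0,ont1 the `go_ontology` editions the results were
#'   computed against.
#' @param top_k number of top terms to keep (fewer are used when a
#'   result has fewer significant terms).
#' @return a number in \[0, 1\].
#' @export
top_term_parents_jaccard <- function(R0, R1, ont0, ont1, top_k = 5L) {
  expand <- function(R, ont) {
    tab <- R$table[R$table$significant, , drop = FALSE]
    tab <- tab[order(tab$p, tab$q, tab$term_id), , drop = FALSE]
    top <- head(tab$term_id, top_k)
    if (length(top) == 0L) return(character(0))
    propagate_terms(top, ont)
  }
  complete_jaccard(expand(R0, ont0), expand(R1, ont1))
}

# Draw a uniform random permutation of 1..n with no fixed point.
random_derangement <- function(n) {
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Permutation null for enrichment-result similarity
#'
#' Builds the null distribution of the complete Jaccard index by
#' re-pairing results from unrelated hit lists: in each round, the
#' early-time-point result of each list is compared with the
#' late-time-point result of a different, randomly selected list
#' (a derangement), keeping pairs where at least one member has five or
#' more significant terms — the same constraint applied to the observed
#' corpus. Jaccard values from all rounds are pooled.
#'
#' @param corpus list of pairs; each element is a list with character
#'   vectors `E0` and `E1` (significant term ids at the two time
#'   points).
#' @param n_rounds number of permutation rounds.
#' @param seed integer seed; the pooled sample is reproducible.
#' @param min_terms retention threshold on the larger member of a pair.
#' @return numeric vector, the pooled null sample.
#' @export
build_null <- function(corpus, n_rounds = 1000L, seed = 1L, min_terms = 5L) {
  if (length(corpus) < 2L) {
    stop_gochrono("null construction needs at least 2 hit lists",
                  "gochrono_config_error")
  }
  E0 <- lapply(corpus, `[[`, "E0")
  E1 <- lapply(corpus, `[[`, "E1")
  n <- length(corpus)
  n0 <- lengths(E0)
  n1 <- lengths(E1)
  with_seed(seed, {
    out <- vector("list", n_rounds)
    for (r in seq_len(n_rounds)) {
      p <- random_derangement(n)
      keep <- n0 >= min_terms | n1[p] >= min_terms
      idx <- which(keep)
      out[[r]] <- vapply(idx, function(i) jaccard(E0[[i]], E1[[p[[i]]]]),
                         numeric(1))
    }
    unlist(out, use.names = FALSE)
  })
}

age_bin <- function(age_years) {
  if (any(age_years > 16)) {
    warning("hit list(s) older than 16 years assigned to the 'oldest' bin",
            call. = FALSE)
  }
  cut(pmin(age_years, 16), breaks = c(-Inf, 10, 12, 16),
      labels = c("recent", "old", "oldest"), right = TRUE)
}

#' Stability of enrichment results over time
#'
#' For each dated hit list, runs the overrepresentation analysis at an
#' early time point t0 (the edition nearest its publication date, or a
#' fixed t0 for undated corpora) and at a current time point t_now,
#' then compares the two significant-term sets with the complete
#' Jaccard index and the top-term-parents Jaccard. Hit lists with fewer
#' than `min_terms` significant terms at both time points are excluded.
#' The observed complete Jaccard is calibrated against a permutation
#' null of re-paired lists ([build_null()]): a result is *stable* when
#' it is more similar than 95% of the null trials (strictly above the
#' empirical 95th percentile).
#'
#' @param hit_lists list of `go_hitlist` objects.
#' @param series a `go_series` holding every needed propagated edition.
#' @param params a `go_enrichment_params`.
#' @param t_now an edition date in the series, the current time point.
#' @param fixed_t0 optional date; when given, every hit list uses the
#'   edition nearest this date as t0 (for corpora without per-list
#'   publication dates).
#' @param n_rounds permutation rounds for the null.
#' @param seed integer seed for the null.
#' @param top_k top terms for the top-term-parents measure.
#' @param min_terms corpus retention threshold (significant terms at
#'   either time point).
#' @return a `go_stability` object: `reports` (one row per retained hit
#'   list: t0, counts, both Jaccard measures, null percentile, stable
#'   flag, age and age bin), `null` (pooled null sample), `null_p95`,
#'   and `summary` (fractions stable overall and per age bin, mean
#'   significant-term counts, Spearman correlation of Jaccard with
#'   age).
#' @export
stability_analysis <- function(hit_lists, series, params = enrichment_params(),
                               t_now, fixed_t0 = NULL, n_rounds = 1000L,
                               seed = 1L, top_k = 5L, min_terms = 5L) {
  stopifnot(inherits(series, "go_series"),
            all(vapply(hit_lists, inherits, logical(1), "go_hitlist")))
  t_now <- as_edition_date(t_now, "t_now")
  e_now <- series_edition(series, t_now)
  if (!is.null(fixed_t0)) fixed_t0 <- as_edition_date(fixed_t0, "fixed_t0")

  run_one <- function(hl) {
    anchor <- if (!is.null(fixed_t0)) fixed_t0 else hl$publication_date
    if (is.null(anchor)) {
      stop_gochrono(sprintf(
        "hit list '%s' has no publication date and no fixed_t0 was given",
        hl$name), "gochrono_config_error")
    }
    t0 <- nearest_edition(anchor, series$dates)
    e0 <- series_edition(series, t0)
    enr <- function(ed) {
      tryCatch(run_enrichment(hl$genes, ed, params),
               gochrono_empty_overlap = function(e) NULL)
    }
    list(name = hl$name, t0 = t0, R0 = enr(e0), R1 = enr(e_now),
         ont0 = e0$ontology, ont1 = e_now$ontology)
  }
  runs <- lapply(hit_lists, run_one)

  sig <- function(R) if (is.null(R)) character(0) else R$significant
  n0 <- vapply(runs, function(r) length(sig(r$R0)), integer(1))
  n1 <- vapply(runs, function(r) length(sig(r$R1)), integer(1))
  retained <- which(n0 >= min_terms | n1 >= min_terms)
  if (length(retained) < 2L) {
    stop_gochrono(sprintf(
      "only %d hit list(s) pass the >=%d significant-terms filter; need at least 2",
      length(retained), min_terms), "gochrono_config_error")
  }
  runs <- runs[retained]
  corpus <- lapply(runs, function(r) list(E0 = sig(r$R0), E1 = sig(r$R1)))
  null_sample <- build_null(corpus, n_rounds = n_rounds, seed = seed,
                            min_terms = min_terms)
  null_p95 <- unname(quantile(null_sample, 0.95, type = 1))

  cj <- vapply(runs, function(r) complete_jaccard(sig(r$R0), sig(r$R1)),
               numeric(1))
  tj <- vapply(runs, function(r) {
    if (is.null(r$R0) || is.null(r$R1)) return(0)
    top_term_parents_jaccard(r$R0, r$R1, r$ont0, r$ont1, top_k = top_k)
  }, numeric(1))
  pct <- vapply(cj, function(x) 100 * mean(null_sample < x), numeric(1))
  stable <- cj > null_p95
  t0s <- as.Date(vapply(runs, function(r) as.character(r$t0), character(1)))
  age <- as.numeric(t_now - t0s) / 365.25
  bins <- age_bin(age)

  reports <- data.frame(
    name = vapply(runs, `[[`, character(1), "name"),
    t0 = t0s, t_now = t_now,
    n_sig_t0 = vapply(runs, function(r) length(sig(r$R0)), integer(1)),
    n_sig_now = vapply(runs, function(r) length(sig(r$R1)), integer(1)),
    complete_jaccard = cj,
    top_parents_jaccard = tj,
    null_percentile = pct,
    stable = stable,
    age_years = age,
    age_bin = as.character(bins),
    stringsAsFactors = FALSE
  )
  rownames(reports) <- NULL

  frac_by_bin <- tapply(stable, bins, mean)
  n_by_bin <- tapply(stable, bins, length)
  n_by_bin[is.na(n_by_bin)] <- 0L
  summary <- list(
    n_input = length(hit_lists),
    n_retained = nrow(reports),
    fraction_stable = mean(stable),
    fraction_stable_by_bin = as.list(frac_by_bin),
    n_by_bin = as.list(n_by_bin),
    mean_sig_t0 = mean(reports$n_sig_t0),
    mean_sig_now = mean(reports$n_sig_now),
    null_p95 = null_p95,
    null_size = length(null_sample),
    jaccard_age_spearman = if (length(unique(age)) > 1L && length(unique(cj)) > 1L)
      cor(cj, age, method = "spearman") else NA_real_
  )
  structure(list(reports = reports, null = null_sample, null_p95 = null_p95,
                 summary = summary, params = params, seed = seed),
            class = "go_stability")
}

#' @export
print.go_stability <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<go_stability> %d/%d hit lists retained; %.1f%% stable (null 95%%ile = %.4f)\n",
    s$n_retained, s$n_input, 100 * s$fraction_stable, s$null_p95))
  fb <- s$fraction_stable_by_bin
  for (b in names(fb)) {
    if (!is.na(fb[[b]])) {
      cat(sprintf("  %-7s %5.1f%% stable (n = %d)\n", b, 100 * fb[[b]],
                  s$n_by_bin[[b]]))
    }
  }
  cat(sprintf("  mean significant terms: %.1f at t0 -> %.1f at t_now\n",
              s$mean_sig_t0, s$mean_sig_now))
  invisible(x)
}
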