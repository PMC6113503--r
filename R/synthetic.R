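# Synthetic GO/GOA histories: a growing DAG ontology, annotation
# editions with churn, redundancy-purge discontinuities, persistent
# per-gene annotation inequality, and hit-list corpora with drifting
# ground-truth modules.

SYN_SPECIES <- "synthetic"
SYN_ROOTS <- c("GO:0000001", "GO:0000002", "GO:0000003")
SYN_CURATED_CODES <- c("IDA", "IMP", "ISS", "TAS", "IGI")
SYN_REWIRE_FRACTION <- 0.1   # fraction of module genes rewired per drift event

#' Parameters for the synthetic history generator
#'
#' @param n_terms_initial terms in the first ontology edition (beyond
#'   the three aspect roots).
#' @param term_birth_rate expected new terms per edition (Poisson).
#' @param n_genes number of gene accessions.
#' @param n_editions number of (monthly) editions; at least 2.
#' @param edition_spacing_days days between editions (28 matches the
#'   median inter-edition gap of the real archives).
#' @param date_jitter when `TRUE`, gaps are drawn uniformly from 13-40
#'   days (the observed range) instead of being constant.
#' @param annotation_gain_rate expected new direct annotations per gene
#'   per edition (before inequality weighting).
#' @param initial_annotations_per_gene expected direct annotations per
#'   gene in the first edition.
#' @param churn_probability per-edition probability that an active
#'   automatic (IEA) annotation disappears for 1-2 editions and then
#'   returns.
#' @param discontinuity_editions edition indices at which every direct
#'   annotation whose term is an ancestor of another direct annotation
#'   of the same gene is purged (a redundancy clean-up: direct counts
#'   drop, propagated counts are untouched). The ontology is frozen at
#'   these editions so the purge is the only change.
#' @param inequality_exponent strength of the heavy-tailed per-gene
#'   annotation rates (gene i gains at a rate proportional to
#'   `i^-inequality_exponent`); 0 gives equal rates.
#' @param drift_rate per-edition probability, after publication, that a
#'   hit list's true term module is partially rewired in the annotation
#'   history.
#' @param obsolescence_rate expected leaf-term obsoletions per edition.
#' @param iea_fraction fraction of new annotations carrying the
#'   automatic IEA evidence code.
#' @param start_date date of the first edition.
#' @param seed integer seed; every generated artifact is a
#'   deterministic function of the parameters.
#' @return a `go_sim_params` object.
#' @export
simulation_params <- function(n_terms_initial = 150L, term_birth_rate = 1.2,
                              n_genes = 400L, n_editions = 60L,
                              edition_spacing_days = 28L, date_jitter = FALSE,
                              annotation_gain_rate = 0.1,
                              initial_annotations_per_gene = 3,
                              churn_probability = 0.02,
                              discontinuity_editions = integer(0),
                              inequality_exponent = 0.7, drift_rate = 0,
                              obsolescence_rate = 0.05, iea_fraction = 0.7,
                              start_date = as.Date("2001-01-01"), seed = 1L) {
  stopifnot(n_editions >= 2L, n_terms_initial >= 1L, n_genes >= 1L,
            term_birth_rate >= 0, annotation_gain_rate >= 0,
            initial_annotations_per_gene >= 0,
            churn_probability >= 0, churn_probability <= 1,
            drift_rate >= 0, drift_rate <= 1,
            inequality_exponent >= 0, obsolescence_rate >= 0,
            iea_fraction >= 0, iea_fraction <= 1,
            all(discontinuity_editions >= 2 & discontinuity_editions <= n_editions))
  structure(list(
    n_terms_initial = as.integer(n_terms_initial),
    term_birth_rate = term_birth_rate,
    n_genes = as.integer(n_genes),
    n_editions = as.integer(n_editions),
    edition_spacing_days = as.integer(edition_spacing_days),
    date_jitter = isTRUE(date_jitter),
    annotation_gain_rate = annotation_gain_rate,
    initial_annotations_per_gene = initial_annotations_per_gene,
    churn_probability = churn_probability,
    discontinuity_editions = as.integer(discontinuity_editions),
    inequality_exponent = inequality_exponent,
    drift_rate = drift_rate,
    obsolescence_rate = obsolescence_rate,
    iea_fraction = iea_fraction,
    start_date = as.Date(start_date),
    seed = as.integer(seed)
  ), class = "go_sim_params")
}

syn_term_id <- function(i) sprintf("GO:%07d", i)
syn_gene_id <- function(i) sprintf("G%04d", i)

edition_dates <- function(params) {
  gaps <- if (params$date_jitter) {
    sample(13:40, params$n_editions - 1L, replace = TRUE)
  } else {
    rep(params$edition_spacing_days, params$n_editions - 1L)
  }
  params$start_date + cumsum(c(0L, gaps))
}

#' Simulate a growing ontology history
#'
#' Edition 1 is a random rooted DAG per aspect (each new term attaches
#' under 1-2 existing same-aspect terms via IS_A or PART_OF). Later
#' editions add Poisson-many new terms and occasionally obsolete unused
#' leaf terms, so the term count grows in expectation. Editions listed
#' in `discontinuity_editions` are frozen copies of their predecessor
#' (only the date changes).
#'
#' @param params a `go_sim_params` object.
#' @return list of `go_ontology` editions, one per edition date.
#' @export
simulate_ontology_history <- function(params) {
  stopifnot(inherits(params, "go_sim_params"))
  with_seed(params$seed, {
    dates <- edition_dates(params)
    aspect_probs <- c(biological_process = 0.7, molecular_function = 0.15,
                      cellular_component = 0.15)
    terms <- data.frame(
      term_id = SYN_ROOTS,
      name = paste("synthetic", names(aspect_probs), "root"),
      aspect = names(aspect_probs),
      obsolete = FALSE, stringsAsFactors = FALSE)
    edges <- data.frame(child = character(0), parent = character(0),
                        relation = character(0), stringsAsFactors = FALSE)
    next_id <- 4L

    add_terms <- function(k) {
      for (i in seq_len(k)) {
        asp <- sample(names(aspect_probs), 1L, prob = aspect_probs)
        id <- syn_term_id(next_id)
        next_id <<- next_id + 1L
        pool <- terms$term_id[terms$aspect == asp & !terms$obsolete]
        n_par <- min(length(pool), sample(1:2, 1L, prob = c(0.7, 0.3)))
        pars <- sample(pool, n_par)
        terms[nrow(terms) + 1L, ] <<- list(id, paste("synthetic term", next_id - 1L),
                                           asp, FALSE)
        edges <<- rbind(edges, data.frame(
          child = id, parent = pars,
          relation = sample(c("IS_A", "PART_OF"), n_par, replace = TRUE,
                            prob = c(0.8, 0.2)),
          stringsAsFactors = FALSE))
      }
    }

    out <- vector("list", params$n_editions)
    for (e in seq_len(params$n_editions)) {
      if (e == 1L) {
        add_terms(params$n_terms_initial)
      } else if (!(e %in% params$discontinuity_editions)) {
        add_terms(rpois(1L, params$term_birth_rate))
        n_obs <- rpois(1L, params$obsolescence_rate)
        if (n_obs > 0L) {
          leaves <- setdiff(terms$term_id[!terms$obsolete],
                            c(SYN_ROOTS, edges$parent))
          pick <- sample(leaves, min(n_obs, length(leaves)))
          if (length(pick)) {
            terms$obsolete[terms$term_id %in% pick] <- TRUE
            edges <- edges[!(edges$child %in% pick | edges$parent %in% pick), ,
                           drop = FALSE]
          }
        }
      }
      out[[e]] <- new_ontology(dates[[e]], terms, edges)
    }
    out
  })
}

#' Simulate an annotation history over an ontology history
#'
#' Direct annotations accrete edition by edition. Per-gene gain rates
#' follow a heavy-tailed (Zipf-like) profile so a persistent inequality
#' in annotation counts emerges. Active automatic (IEA) annotations
#' churn: with some probability they disappear for 1-2 editions and
#' then return. At each discontinuity edition all other dynamics pause
#' and every direct annotation whose term is an ancestor of another
#' direct annotation of the same gene is purged, which lowers direct
#' counts while leaving propagated counts untouched. Annotation
#' editions are dated 3 days after their ontology edition, so
#' [match_ontology()] pairs each with the ontology it was generated
#' against.
#'
#' @param ontology_history output of [simulate_ontology_history()].
#' @param params the same `go_sim_params` object.
#' @return list of `go_annotations` editions.
#' @export
simulate_annotation_history <- function(ontology_history, params) {
  stopifnot(inherits(params, "go_sim_params"),
            length(ontology_history) == params$n_editions)
  with_seed(params$seed + 1L, {
    n <- params$n_genes
    genes <- syn_gene_id(seq_len(n))
    w <- seq_len(n)^(-params$inequality_exponent)
    rates <- params$annotation_gain_rate * n * w / sum(w)
    init_rates <- params$initial_annotations_per_gene * n * w / sum(w)

    # record store (parallel vectors; state: active / dormant / dead)
    r_acc <- character(0); r_term <- character(0); r_ev <- character(0)
    r_state <- character(0); r_return <- integer(0)
    key <- function(a, t, v) paste(a, t, v, sep = "\r")

    # birth edition of each term, for the recency bias of new annotations
    born <- integer(0)
    for (e in seq_along(ontology_history)) {
      ids <- ontology_history[[e]]$terms$term_id
      fresh <- setdiff(ids, names(born))
      born[fresh] <- e
    }

    out <- vector("list", params$n_editions)
    for (e in seq_len(params$n_editions)) {
      ont <- ontology_history[[e]]
      live <- ont$terms$term_id[!ont$terms$obsolete]
      targets <- setdiff(live, SYN_ROOTS)
      recent <- targets[born[targets] > e - 24L & born[targets] > 1L]
      if (e %in% params$discontinuity_editions) {
        # redundancy purge: drop direct annotations implied by another
        # direct annotation of the same gene; everything else pauses
        r_return[r_state == "dormant"] <- r_return[r_state == "dormant"] + 1L
        anc <- ancestor_map(ont)
        act <- which(r_state == "active")
        for (g in unique(r_acc[act])) {
          gi <- act[r_acc[act] == g]
          tg <- unique(r_term[gi])
          redundant <- intersect(tg, unlist(anc[tg], use.names = FALSE))
          if (length(redundant)) {
            r_state[gi[r_term[gi] %in% redundant]] <- "dead"
          }
        }
      } else {
        # annotations to terms now obsolete or missing are retired
        gone <- !(r_term %in% live)
        r_state[gone & r_state != "dead"] <- "dead"
        # churned annotations come back after their pause
        back <- r_state == "dormant" & r_return <= e
        r_state[back] <- "active"
        # churn: active IEA records pause for 1-2 editions
        ch <- r_state == "active" & r_ev == "IEA" &
          runif(length(r_state)) < params$churn_probability
        if (any(ch)) {
          r_state[ch] <- "dormant"
          r_return[ch] <- e + sample(1:2, sum(ch), replace = TRUE)
        }
        # accretion
        lambda <- if (e == 1L) init_rates else rates
        n_new <- rpois(n, lambda)
        gi <- rep.int(seq_len(n), n_new)
        if (length(gi)) {
          new_acc <- genes[gi]
          # curation favours newly minted, finer-grained terms: a share of
          # new annotations lands on terms added in the last two years
          new_term <- sample(targets, length(gi), replace = TRUE)
          if (length(recent)) {
            to_recent <- runif(length(gi)) < 0.4
            new_term[to_recent] <- sample(recent, sum(to_recent), replace = TRUE)
          }
          new_ev <- ifelse(runif(length(gi)) < params$iea_fraction, "IEA",
                           sample(SYN_CURATED_CODES, length(gi), replace = TRUE))
          dup_new <- duplicated(key(new_acc, new_term, new_ev))
          new_acc <- new_acc[!dup_new]; new_term <- new_term[!dup_new]
          new_ev <- new_ev[!dup_new]
          idx <- match(key(new_acc, new_term, new_ev),
                       key(r_acc, r_term, r_ev))
          revive <- !is.na(idx)
          # re-adding a previously seen pair reactivates it (churn-like)
          r_state[idx[revive]] <- "active"
          if (any(!revive)) {
            r_acc <- c(r_acc, new_acc[!revive])
            r_term <- c(r_term, new_term[!revive])
            r_ev <- c(r_ev, new_ev[!revive])
            r_state <- c(r_state, rep("active", sum(!revive)))
            r_return <- c(r_return, rep(0L, sum(!revive)))
          }
        }
      }
      act <- r_state == "active"
      asp <- setNames(ont$terms$aspect, ont$terms$term_id)
      rec <- data.frame(accession = r_acc[act], term_id = r_term[act],
                        evidence_code = r_ev[act],
                        qualifier = "",
                        aspect = unname(asp[r_term[act]]),
                        stringsAsFactors = FALSE)
      rec <- rec[order(rec$accession, rec$term_id, rec$evidence_code), ,
                 drop = FALSE]
      out[[e]] <- new_annotations(SYN_SPECIES, ont$edition_date + 3L, rec)
    }
    out
  })
}

#' Simulate a dated hit-list corpus with known ground truth
#'
#' Each hit list is built around a "true" module: a mid-size Biological
#' Process term at the list's publication edition. Its genes are a
#' sample of the genes propagated-annotated to that term, topped up with
#' random noise genes. Publication dates are spread across the
#' editions. With `drift_rate > 0`, the annotation history is rewired
#' after each list's publication: at each later edition, with the given
#' probability, a quarter of the module genes lose their annotations
#' tied to the module term and gain annotations elsewhere — so older
#' lists accumulate more drift.
#'
#' @param annotation_history output of [simulate_annotation_history()].
#' @param ontology_history the matching ontology history.
#' @param params the same `go_sim_params` object.
#' @param n_lists number of hit lists.
#' @param genes_per_list genes per hit list.
#' @return a list with elements `hit_lists` (list of `go_hitlist`),
#'   `annotation_history` (the possibly rewired history), and `truth`
#'   (data.frame: name, module term, publication edition and date).
#' @export
simulate_hitlist_corpus <- function(annotation_history, ontology_history,
                                    params, n_lists = 50L,
                                    genes_per_list = 30L) {
  stopifnot(inherits(params, "go_sim_params"),
            length(annotation_history) == length(ontology_history))
  if (genes_per_list > params$n_genes) {
    stop_gochrono("genes_per_list exceeds the number of simulated genes",
                  "gochrono_config_error")
  }
  E <- length(annotation_history)
  with_seed(params$seed + 2L, {
    prop_cache <- new.env(parent = emptyenv())
    prop <- function(e) {
      k <- as.character(e)
      if (is.null(prop_cache[[k]])) {
        prop_cache[[k]] <- propagate_edition(annotation_history[[e]],
                                             ontology_history[[e]], quiet = TRUE)
      }
      prop_cache[[k]]
    }

    dates_all <- as.Date(vapply(annotation_history,
                                function(a) as.character(a$edition_date),
                                character(1)))
    age_all <- as.numeric(dates_all[[E]] - dates_all) / 365.25
    # publications span the studied age range (up to 16 years before t_now)
    pub_pool <- which(age_all <= 16 & seq_len(E) < E)
    pub_e <- sample(pub_pool, n_lists, replace = TRUE)
    hl <- vector("list", n_lists)
    truth <- data.frame(name = character(n_lists), module_term = character(n_lists),
                        pub_edition = integer(n_lists),
                        publication_date = as.Date(rep(NA, n_lists)),
                        stringsAsFactors = FALSE)
    # drift events: (list, edition, genes to rewire) collected, applied after
    del_acc <- character(0); del_term <- character(0); del_from <- integer(0)
    add_acc <- character(0); add_term <- character(0); add_from <- integer(0)

    for (i in seq_len(n_lists)) {
      e <- pub_e[[i]]
      pe <- prop(e)
      tgs <- term_gene_sets(pe)
      sizes <- lengths(tgs)
      asp <- setNames(pe$ontology$terms$aspect, pe$ontology$terms$term_id)
      cand <- names(sizes)[asp[names(sizes)] == "biological_process" &
                             !(names(sizes) %in% SYN_ROOTS) &
                             sizes >= max(5L, round(0.5 * genes_per_list)) &
                             sizes <= 5L * genes_per_list]
      if (length(cand) == 0L) {
        cand <- names(sizes)[asp[names(sizes)] == "biological_process" &
                               !(names(sizes) %in% SYN_ROOTS) & sizes >= 5L]
      }
      module <- sample(cand, 1L)
      pool <- tgs[[module]]
      m_mod <- min(length(pool), ceiling(0.75 * genes_per_list))
      members <- sample(pool, m_mod)
      noise_pool <- setdiff(names(pe$gene_to_propagated), members)
      members <- c(members, sample(noise_pool,
                                   min(length(noise_pool),
                                       genes_per_list - m_mod)))
      nm <- sprintf("synthetic_hitlist_%03d", i)
      pub_date <- pe$edition_date
      hl[[i]] <- hitlist(nm, members, pub_date)
      truth[i, c("name", "module_term")] <- list(nm, module)
      truth$pub_edition[[i]] <- e
      truth$publication_date[[i]] <- pub_date

      if (params$drift_rate > 0 && e < E) {
        module_genes <- head(members, m_mod)
        anc_pub <- ancestor_map(pe$ontology)
        for (e2 in seq(e + 1L, E)) {
          if (runif(1L) >= params$drift_rate) next
          rewire <- sample(module_genes,
                           max(1L, ceiling(SYN_REWIRE_FRACTION * length(module_genes))))
          rec2 <- annotation_history[[e2]]$records
          ont2 <- ontology_history[[e2]]
          anc2 <- ancestor_map(ont2)
          live2 <- setdiff(ont2$terms$term_id[!ont2$terms$obsolete], SYN_ROOTS)
          for (g in rewire) {
            tg <- unique(rec2$term_id[rec2$accession == g])
            tied <- tg[tg == module |
                         vapply(tg, function(t) module %in% (anc2[[t]] %||% character(0)),
                                logical(1))]
            if (length(tied) == 0L) next
            del_acc <- c(del_acc, rep(g, length(tied)))
            del_term <- c(del_term, tied)
            del_from <- c(del_from, rep(e2, length(tied)))
            repl <- sample(setdiff(live2, tied), length(tied), replace = FALSE)
            add_acc <- c(add_acc, rep(g, length(tied)))
            add_term <- c(add_term, repl)
            add_from <- c(add_from, rep(e2, length(tied)))
          }
        }
      }
    }

    if (length(del_acc)) {
      dkey <- paste(del_acc, del_term, sep = "\r")
      for (e3 in seq_len(E)) {   # rewiring applies cumulatively from its edition on
        cur_del <- unique(dkey[del_from <= e3])
        cur_add <- which(add_from <= e3)
        if (length(cur_del) == 0L && length(cur_add) == 0L) next
        ed <- annotation_history[[e3]]
        rec <- ed$records
        rec <- rec[!(paste(rec$accession, rec$term_id, sep = "\r") %in% cur_del), ,
                   drop = FALSE]
        if (length(cur_add)) {
          ont3 <- ontology_history[[e3]]
          live3 <- ont3$terms$term_id[!ont3$terms$obsolete]
          asp3 <- setNames(ont3$terms$aspect, ont3$terms$term_id)
          at <- add_term[cur_add]; aa <- add_acc[cur_add]
          ok <- at %in% live3 &
            !(paste(aa, at, sep = "\r") %in% cur_del)
          if (any(ok)) {
            rec <- rbind(rec, data.frame(
              accession = aa[ok], term_id = at[ok], evidence_code = "IEA",
              qualifier = "", aspect = unname(asp3[at[ok]]),
              stringsAsFactors = FALSE))
          }
        }
        rec <- rec[order(rec$accession, rec$term_id, rec$evidence_code), ,
                   drop = FALSE]
        annotation_history[[e3]] <- new_annotations(ed$species, ed$edition_date,
                                                    rec)
      }
    }

    list(hit_lists = hl, annotation_history = annotation_history, truth = truth)
  })
}

#' Propagate every edition of a simulated history into a series
#'
#' Matches each annotation edition to the closest ontology release at or
#' before it and materializes the propagated annotations.
#'
#' @param annotation_history list of `go_annotations` editions.
#' @param ontology_history list of `go_ontology` editions.
#' @return a `go_series`.
#' @export
build_series <- function(annotation_history, ontology_history) {
  ont_dates <- as.Date(vapply(ontology_history,
                              function(o) as.character(o$edition_date),
                              character(1)))
  eds <- lapply(annotation_history, function(a) {
    d <- match_ontology(a$edition_date, ont_dates)
    propagate_edition(a, ontology_history[[match(d, ont_dates)]], quiet = TRUE)
  })
  edition_series(eds)
}

#' Generate a complete synthetic study under a named preset
#'
#' Builds ontology history, annotation history and a dated hit-list
#' corpus under one of three regimes:
#' \describe{
#'   \item{`stable`}{no module drift and no discontinuities; enrichment
#'     results should largely remain recognizable over time.}
#'   \item{`drift`}{heavy post-publication rewiring of hit-list modules,
#'     so older lists lose their enrichment signal.}
#'   \item{`churn`}{high annotation churn plus a mid-history
#'     redundancy-purge discontinuity.}
#' }
#' The default scale (210 editions at 28-day spacing, so roughly 16
#' years; 400 genes; 300 hit lists) spans the full range of the age
#' bins used in the stability analysis.
#'
#' @param preset one of `"stable"`, `"drift"`, `"churn"`.
#' @param seed integer seed.
#' @param n_editions,n_genes,n_lists,genes_per_list scale overrides.
#' @return list with `params`, `ontology_history`, `annotation_history`
#'   (after any drift rewiring), `hit_lists`, `truth`.
#' @export
simulate_preset <- function(preset = c("stable", "drift", "churn"), seed = 1L,
                            n_editions = 210L, n_genes = 400L,
                            n_lists = 300L, genes_per_list = 30L) {
  preset <- match.arg(preset)
  base <- list(n_terms_initial = 400L, term_birth_rate = 4,
               n_genes = as.integer(n_genes),
               n_editions = as.integer(n_editions),
               annotation_gain_rate = 0.06,
               initial_annotations_per_gene = 3,
               churn_probability = 0.02,
               inequality_exponent = 0.7,
               obsolescence_rate = 0.05,
               seed = as.integer(seed))
  extra <- switch(preset,
    stable = list(drift_rate = 0),
    drift = list(drift_rate = 0.01),
    churn = list(churn_probability = 0.15,
                 discontinuity_editions = as.integer(max(2L, n_editions %/% 2L))))
  params <- do.call(simulation_params, utils::modifyList(base, extra))
  onts <- simulate_ontology_history(params)
  anns <- simulate_annotation_history(onts, params)
  corpus <- simulate_hitlist_corpus(anns, onts, params, n_lists = n_lists,
                                    genes_per_list = genes_per_list)
  list(params = params, ontology_history = onts,
       annotation_history = corpus$annotation_history,
       hit_lists = corpus$hit_lists, truth = corpus$truth)
}
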