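# Shared fixtures built in code: toy ontologies, GAF builders, and
# independent brute-force oracles used to check the implementation.

`%||%` <- function(a, b) if (is.null(a)) b else a

obo_stanza <- function(id, ns = "biological_process", is_a = character(0),
                       part_of = character(0), obsolete = FALSE,
                       alt = character(0), name = "t") {
  c("[Term]", paste0("id: ", id), paste0("name: ", name),
    paste0("namespace: ", ns),
    paste0("alt_id: ", alt)[seq_along(alt)],
    paste0("is_a: ", is_a)[seq_along(is_a)],
    paste0("relationship: part_of ", part_of)[seq_along(part_of)],
    if (obsolete) "is_obsolete: true", "")
}

obo_text <- function(...) c("format-version: 1.2", "", ...)

# chain: c -> b -> a
chain_ontology <- function(date = "2005-01-01") {
  parse_obo(obo_text(
    obo_stanza("GO:0000001", name = "a"),
    obo_stanza("GO:0000002", name = "b", is_a = "GO:0000001"),
    obo_stanza("GO:0000003", name = "c", is_a = "GO:0000002")
  ), date)
}

# diamond: d -> b, d -> c, b -> a, c -> a
diamond_ontology <- function(date = "2005-01-01") {
  parse_obo(obo_text(
    obo_stanza("GO:0000001", name = "a"),
    obo_stanza("GO:0000002", name = "b", is_a = "GO:0000001"),
    obo_stanza("GO:0000003", name = "c", is_a = "GO:0000001"),
    obo_stanza("GO:0000004", name = "d", is_a = "GO:0000002",
               part_of = "GO:0000003")
  ), date)
}

gaf_line <- function(accession, term, evidence = "IEA", qualifier = "",
                     aspect = "P") {
  paste("DB", accession, accession, qualifier, term, "REF:1", evidence, "",
        aspect, "", "", "protein", "taxon:1", "20050101", "DB", "", "",
        sep = "\t")
}

gaf_text <- function(...) c("!gaf-version: 2.2", ...)

# --- independent oracles -------------------------------------------------

# random DAG as OBO text: each term may link to earlier terms only
random_dag_obo <- function(n_terms, p_edge = 0.08) {
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  stanzas <- lapply(seq_len(n_terms), function(i) {
    parents <- if (i == 1L) character(0) else {
      cand <- ids[seq_len(i - 1L)]
      pick <- cand[runif(length(cand)) < p_edge]
      if (length(pick) == 0L && runif(1) < 0.9) pick <- sample(cand, 1L)
      pick
    }
    obo_stanza(ids[[i]], is_a = parents)
  })
  do.call(obo_text, stanzas)
}

# brute-force reachability closure over an edge list (child -> parent)
reach_closure_oracle <- function(start, edges) {
  out <- unique(start)
  frontier <- out
  while (length(frontier)) {
    nxt <- unique(edges$parent[edges$child %in% frontier])
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  sort(out)
}

# exact hypergeometric upper tail by rational binomial summation
hyper_tail_oracle <- function(k, K, n, N) {
  num <- sum(vapply(k:min(n, K), function(i)
    choose(K, i) * choose(N - K, n - i), numeric(1)))
  num / choose(N, n)
}

# literal step-up BH: q_(i) = min over j >= i of m p_(j) / j, input order
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- vapply(seq_len(m), function(i) min(1, min(m * ps[i:m] / (i:m))),
               numeric(1))
  q <- numeric(m)
  q[o] <- qs
  q
}

# small propagated edition built through the parsers
toy_edition <- function(gaf_lines, ontology, species = "toy",
                        date = "2005-01-05") {
  propagate_edition(parse_gaf(gaf_text(gaf_lines), species, date), ontology,
                    quiet = TRUE)
}
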