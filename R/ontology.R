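# Dated Gene Ontology editions: OBO parsing, validation, ancestor queries.

GO_ID_PATTERN <- "^GO:[0-9]{7}$"

ASPECTS <- c("biological_process", "molecular_function", "cellular_component")

#' Construct an ontology edition
#'
#' Internal constructor shared by [parse_obo()] and the synthetic
#' generator. Validates the edition invariants: every edge endpoint is a
#' declared term, obsolete terms carry no edges, no edge crosses GO
#' aspects, and the graph over non-obsolete terms is acyclic.
#'
#' @param edition_date date of the edition.
#' @param terms data.frame with columns `term_id`, `name`, `aspect`,
#'   `obsolete` (logical).
#' @param edges data.frame with columns `child`, `parent`, `relation`
#'   (`"IS_A"` or `"PART_OF"`).
#' @param alt named character vector mapping alternate (secondary) term
#'   ids to their primary term id.
#' @return an object of class `go_ontology`.
#' @keywords internal
new_ontology <- function(edition_date, terms, edges, alt = character(0)) {
  stopifnot(is.data.frame(terms), is.data.frame(edges))
  if (anyDuplicated(terms$term_id)) {
    stop_gochrono("duplicate term ids in ontology edition", "gochrono_structure_error")
  }
  bad_id <- terms$term_id[!grepl(GO_ID_PATTERN, terms$term_id)]
  if (length(bad_id)) {
    stop_gochrono(paste0("invalid GO accession: ", bad_id[[1L]]),
                  "gochrono_structure_error")
  }
  if (length(alt)) {
    alt <- alt[names(alt) != alt]           # an id is never its own alt
    alt <- alt[!(names(alt) %in% terms$term_id)]
  } else {
    alt <- setNames(character(0), character(0))
  }
  if (nrow(edges)) {
    known <- c(terms$term_id)
    miss <- setdiff(c(edges$child, edges$parent), known)
    if (length(miss)) {
      stop_gochrono(paste0("edge references undeclared term: ", miss[[1L]]),
                    "gochrono_structure_error")
    }
    asp <- setNames(terms$aspect, terms$term_id)
    obs <- setNames(terms$obsolete, terms$term_id)
    # obsolete terms carry no relationships; cross-aspect links are excluded
    keep <- !obs[edges$child] & !obs[edges$parent] &
      asp[edges$child] == asp[edges$parent] &
      edges$relation %in% c("IS_A", "PART_OF")
    edges <- edges[keep, , drop = FALSE]
    edges <- unique(edges)
    rownames(edges) <- NULL
    cyc <- find_cycle_member(terms$term_id[!terms$obsolete], edges)
    if (!is.null(cyc)) {
      stop_gochrono(paste0("cycle detected in ontology involving term ", cyc),
                    "gochrono_structure_error")
    }
  }
  parents <- split(edges$parent, factor(edges$child, levels = terms$term_id))
  structure(
    list(
      edition_date = as_edition_date(edition_date, "edition_date"),
      terms = terms,
      edges = edges,
      alt = alt,
      parents = parents,
      .cache = new.env(parent = emptyenv())
    ),
    class = "go_ontology"
  )
}

# Kahn's algorithm; returns NULL for a DAG, else the id of one term on a cycle.
find_cycle_member <- function(ids, edges) {
  indeg <- setNames(integer(length(ids)), ids)
  tab <- table(edges$parent)      # edges run child -> parent; count incoming
  indeg[names(tab)] <- as.integer(tab)
  children_of <- split(edges$parent, edges$child)
  queue <- names(indeg)[indeg == 0L]
  n_seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    n_seen <- n_seen + 1L
    for (p in children_of[[v]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (n_seen == length(ids)) NULL else names(indeg)[indeg > 0L][[1L]]
}

#' Parse one dated OBO edition
#'
#' Reads an OBO 1.2 file (one `[Term]` stanza per term) into a validated
#' ontology edition. Only `is_a:` and `relationship: part_of` lines
#' create edges; every other relationship type is discarded, as are
#' edges that would cross the three GO aspects. `is_obsolete: true`
#' marks a term obsolete (its edges are dropped) and `alt_id:` lines
#' record secondary accessions that resolve to the primary id.
#'
#' @param file path to an OBO file, or a character vector of OBO lines.
#' @param edition_date the release date of this edition (coerced with
#'   [as.Date()]).
#' @return a `go_ontology` object.
#' @examples
#' obo <- c("format-version: 1.2", "",
#'          "[Term]", "id: GO:0000001", "name: root",
#'          "namespace: biological_process", "",
#'          "[Term]", "id: GO:0000002", "name: child",
#'          "namespace: biological_process", "is_a: GO:0000001 ! root")
#' ont <- parse_obo(obo, "2005-01-01")
#' go_ancestors(ont, "GO:0000002")
#' @export
parse_obo <- function(file, edition_date) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(as.character(file), "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\r$", "", lines)
  stanza_at <- grep("^\\[[A-Za-z-]+\\]\\s*$", lines)
  header_end <- if (length(stanza_at)) stanza_at[[1L]] - 1L else length(lines)
  default_ns <- NA_character_
  m <- grep("^default-namespace:", lines[seq_len(header_end)], value = TRUE)
  if (length(m)) default_ns <- trimws(sub("^default-namespace:", "", m[[1L]]))
  # normalise legacy default namespace labels
  if (!is.na(default_ns) && !(default_ns %in% ASPECTS)) default_ns <- NA_character_

  term_ids <- character(0); term_names <- character(0)
  term_aspects <- character(0); term_obs <- logical(0)
  alt_from <- character(0); alt_to <- character(0)
  e_child <- character(0); e_parent <- character(0); e_rel <- character(0)

  bounds <- c(stanza_at, length(lines) + 1L)
  for (si in seq_along(stanza_at)) {
    start <- stanza_at[[si]]
    if (!identical(lines[[start]], "[Term]")) next
    body_idx <- seq(start + 1L, bounds[[si + 1L]] - 1L)
    body <- lines[body_idx]
    kv <- regmatches(body, regexec("^([A-Za-z_]+):\\s*(.*)$", body))
    id <- NA_character_; nm <- ""; ns <- NA_character_; obs <- FALSE
    for (bi in seq_along(body)) {
      if (!nzchar(trimws(body[[bi]]))) next
      if (length(kv[[bi]]) != 3L) {
        stop_gochrono(sprintf("unparseable OBO line %d: %s",
                              body_idx[[bi]], body[[bi]]),
                      "gochrono_parse_error")
      }
      key <- kv[[bi]][[2L]]; val <- trimws(kv[[bi]][[3L]])
      val_id <- trimws(sub("!.*$", "", val))   # strip trailing "! comment"
      if (key == "id") {
        id <- val_id
        if (!grepl(GO_ID_PATTERN, id)) {
          stop_gochrono(sprintf("invalid term id at line %d: %s",
                                body_idx[[bi]], val), "gochrono_parse_error")
        }
      } else if (key == "name") {
        nm <- val
      } else if (key == "namespace") {
        ns <- val
      } else if (key == "alt_id") {
        alt_from <- c(alt_from, val_id); alt_to <- c(alt_to, NA_character_)
      } else if (key == "is_obsolete") {
        obs <- identical(val, "true")
      } else if (key == "is_a") {
        e_child <- c(e_child, NA_character_)
        e_parent <- c(e_parent, val_id)
        e_rel <- c(e_rel, "IS_A")
      } else if (key == "relationship") {
        parts <- strsplit(val_id, "\\s+")[[1L]]
        if (length(parts) >= 2L && parts[[1L]] == "part_of") {
          e_child <- c(e_child, NA_character_)
          e_parent <- c(e_parent, parts[[2L]])
          e_rel <- c(e_rel, "PART_OF")
        }
        # every other relationship type (regulates, occurs_in, ...) is dropped
      }
    }
    if (is.na(id)) {
      stop_gochrono(sprintf("stanza at line %d has no id", start),
                    "gochrono_parse_error")
    }
    if (is.na(ns)) ns <- default_ns
    if (is.na(ns) && !obs) {
      stop_gochrono(sprintf("term %s has no namespace and the file declares no default", id),
                    "gochrono_parse_error")
    }
    if (!is.na(ns) && !(ns %in% ASPECTS)) {
      stop_gochrono(sprintf("term %s has unknown namespace '%s'", id, ns),
                    "gochrono_parse_error")
    }
    term_ids <- c(term_ids, id); term_names <- c(term_names, nm)
    term_aspects <- c(term_aspects, if (is.na(ns)) ASPECTS[[1L]] else ns)
    term_obs <- c(term_obs, obs)
    e_child[is.na(e_child)] <- id
    alt_to[is.na(alt_to)] <- id
  }

  terms <- data.frame(term_id = term_ids, name = term_names,
                      aspect = term_aspects, obsolete = term_obs,
                      stringsAsFactors = FALSE)
  edges <- data.frame(child = e_child, parent = e_parent, relation = e_rel,
                      stringsAsFactors = FALSE)
  alt <- setNames(alt_to, alt_from)
  new_ontology(edition_date, terms, edges, alt)
}

#' @export
print.go_ontology <- function(x, ...) {
  cat(sprintf("<go_ontology> edition %s: %d terms (%d obsolete), %d edges\n",
              format(x$edition_date), nrow(x$terms), sum(x$terms$obsolete),
              nrow(x$edges)))
  invisible(x)
}

# Resolve a (possibly secondary) accession to its primary term id, or NA.
resolve_term_id <- function(ontology, term_id) {
  hit <- term_id %in% ontology$terms$term_id
  out <- term_id
  out[!hit] <- unname(ontology$alt[term_id[!hit]])
  out
}

# Full ancestor closure (excluding self), memoized per edition.
ancestor_map <- function(ontology) {
  cache <- ontology$.cache
  if (!is.null(cache$anc)) return(cache$anc)
  ids <- ontology$terms$term_id
  parents <- ontology$parents
  anc <- vector("list", length(ids))
  names(anc) <- ids
  done <- setNames(logical(length(ids)), ids)
  for (id in ids) {
    if (done[[id]]) next
    # iterative DFS with an explicit stack; finishes parents before children
    stack <- id
    while (length(stack)) {
      v <- stack[[length(stack)]]
      ps <- parents[[v]]
      pending <- ps[!done[ps]]
      if (length(pending)) {
        stack <- c(stack, pending[[1L]])
      } else {
        anc[[v]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
        done[[v]] <- TRUE
        stack <- stack[-length(stack)]
      }
    }
  }
  cache$anc <- anc
  anc
}

#' Ancestors of a term
#'
#' All terms reachable from `term_id` by following IS_A / PART_OF edges
#' child-to-parent, excluding the term itself. Secondary (alt) ids are
#' resolved to their primary term first.
#'
#' @param ontology a `go_ontology`.
#' @param term_id a single GO accession.
#' @return character vector of ancestor term ids (possibly empty).
#' @export
go_ancestors <- function(ontology, term_id) {
  stopifnot(inherits(ontology, "go_ontology"), length(term_id) == 1L)
  id <- resolve_term_id(ontology, term_id)
  if (is.na(id)) {
    stop_gochrono(paste0("unknown term: ", term_id), "gochrono_lookup_error")
  }
  if (ontology$terms$obsolete[match(id, ontology$terms$term_id)]) {
    stop_gochrono(paste0("term is obsolete in this edition: ", id),
                  "gochrono_lookup_error")
  }
  sort(ancestor_map(ontology)[[id]] %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Propagate a term set up the ontology (true-path rule)
#'
#' Returns the reflexive transitive closure of `term_ids` under the
#' IS_A / PART_OF parent relation: the input terms together with all of
#' their ancestors. A gene directly annotated to the input terms is
#' implicitly annotated to every term in the result.
#'
#' @param term_ids character vector of GO accessions (alt ids allowed).
#' @param ontology a `go_ontology`.
#' @return sorted character vector, a superset of the resolved input.
#' @export
propagate_terms <- function(term_ids, ontology) {
  stopifnot(inherits(ontology, "go_ontology"))
  if (length(term_ids) == 0L) return(character(0))
  ids <- resolve_term_id(ontology, unique(as.character(term_ids)))
  if (anyNA(ids)) {
    bad <- unique(as.character(term_ids))[is.na(ids)][[1L]]
    stop_gochrono(paste0("unknown term: ", bad), "gochrono_lookup_error")
  }
  anc <- ancestor_map(ontology)
  sort(unique(c(ids, unlist(anc[ids], use.names = FALSE))))
}
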