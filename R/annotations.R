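# Dated annotation (GOA) editions: GAF parsing, accession harmonization,
# ontology matching, true-path propagation.

GAF_NCOL <- 17L
ASPECT_CODES <- c(P = "biological_process", F = "molecular_function",
                  C = "cellular_component")

new_annotations <- function(species, edition_date, records) {
  stopifnot(is.data.frame(records))
  need <- c("accession", "term_id", "evidence_code", "qualifier", "aspect")
  stopifnot(all(need %in% names(records)))
  records <- records[!duplicated(records[c("accession", "term_id", "evidence_code")]), ,
                     drop = FALSE]
  rownames(records) <- NULL
  structure(
    list(species = species,
         edition_date = as_edition_date(edition_date, "edition_date"),
         records = records),
    class = "go_annotations"
  )
}

#' @export
print.go_annotations <- function(x, ...) {
  cat(sprintf("<go_annotations> %s edition %s: %d records, %d genes, %d terms\n",
              x$species, format(x$edition_date), nrow(x$records),
              length(unique(x$records$accession)),
              length(unique(x$records$term_id))))
  invisible(x)
}

#' Parse one dated GAF edition
#'
#' Reads a GAF 2.x tab-separated annotation file into a set of direct
#' annotation records. Records whose qualifier contains `NOT` are
#' excluded (they assert the absence of an association). Duplicate
#' (accession, term, evidence) triples collapse to one record.
#'
#' @param file path to a GAF file (plain or gzipped), or a character
#'   vector of GAF lines.
#' @param species label for the species/taxon this edition covers.
#' @param edition_date release date of the edition.
#' @return a `go_annotations` object holding direct annotations only.
#' @export
parse_gaf <- function(file, species, edition_date) {
  lines <- if (length(file) == 1L && !grepl("\n|\t", file) && file.exists(file)) {
    readLines(if (grepl("\\.gz$", file)) gzfile(file) else file, warn = FALSE)
  } else {
    unlist(strsplit(as.character(file), "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\r$", "", lines)
  body <- !startsWith(lines, "!") & nzchar(lines)
  idx <- which(body)
  if (length(idx) == 0L) {
    return(new_annotations(species, edition_date, data.frame(
      accession = character(0), term_id = character(0),
      evidence_code = character(0), qualifier = character(0),
      aspect = character(0), stringsAsFactors = FALSE)))
  }
  # sentinel keeps strsplit from dropping trailing empty fields
  fields <- lapply(strsplit(paste0(lines[idx], "\t\001"), "\t", fixed = TRUE),
                   function(f) f[-length(f)])
  nc <- lengths(fields)
  if (any(nc != GAF_NCOL)) {
    bad <- which(nc != GAF_NCOL)[[1L]]
    stop_gochrono(sprintf("GAF line %d has %d columns (expected %d)",
                          idx[[bad]], nc[[bad]], GAF_NCOL),
                  "gochrono_parse_error")
  }
  m <- do.call(rbind, fields)
  accession <- m[, 2L]
  qualifier <- m[, 4L]
  term_id <- m[, 5L]
  evidence <- m[, 7L]
  aspect_code <- m[, 9L]
  bad_ev <- !grepl("^[A-Z]{2,3}$", evidence)
  if (any(bad_ev)) {
    w <- which(bad_ev)[[1L]]
    stop_gochrono(sprintf("GAF line %d has malformed evidence code '%s'",
                          idx[[w]], evidence[[w]]), "gochrono_parse_error")
  }
  bad_asp <- !(aspect_code %in% names(ASPECT_CODES))
  if (any(bad_asp)) {
    w <- which(bad_asp)[[1L]]
    stop_gochrono(sprintf("GAF line %d has unknown aspect '%s'",
                          idx[[w]], aspect_code[[w]]), "gochrono_parse_error")
  }
  # drop negative annotations: any NOT token in the pipe-separated qualifier
  is_not <- vapply(strsplit(qualifier, "|", fixed = TRUE),
                   function(q) "NOT" %in% q, logical(1))
  keep <- !is_not
  records <- data.frame(
    accession = accession[keep],
    term_id = term_id[keep],
    evidence_code = evidence[keep],
    qualifier = qualifier[keep],
    aspect = unname(ASPECT_CODES[aspect_code[keep]]),
    stringsAsFactors = FALSE
  )
  new_annotations(species, edition_date, records)
}

#' Parse a secondary-to-primary accession mapping
#'
#' Reads a two-column whitespace-separated table (secondary accession,
#' primary accession), the format UniProt distributes as `sec_ac.txt`.
#' Header/decoration lines (anything that is not exactly two
#' accession-like tokens) are tolerated and skipped. Chains (A maps to B,
#' B maps to C) are collapsed so every secondary resolves directly to its
#' terminal primary.
#'
#' @param file path to the mapping file, or a character vector of lines.
#' @return a `go_accession_map`: a named character vector
#'   (names = secondary, values = primary).
#' @export
parse_secondary_mapping <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(as.character(file), "\n", fixed = TRUE), use.names = FALSE)
  }
  toks <- strsplit(trimws(lines), "\\s+")
  ok <- vapply(toks, function(t) {
    length(t) == 2L && all(grepl("^[A-Za-z0-9_-]+$", t)) &&
      !any(grepl("^_+$", t))
  }, logical(1))
  toks <- toks[ok]
  if (length(toks) == 0L) {
    return(structure(setNames(character(0), character(0)),
                     class = "go_accession_map"))
  }
  sec <- vapply(toks, `[[`, character(1), 1L)
  pri <- vapply(toks, `[[`, character(1), 2L)
  drop_self <- sec == pri
  sec <- sec[!drop_self]; pri <- pri[!drop_self]
  dup <- duplicated(paste(sec, pri))
  sec <- sec[!dup]; pri <- pri[!dup]
  amb <- unique(sec[duplicated(sec)])
  if (length(amb)) {
    stop_gochrono(paste0("secondary accession maps to multiple primaries: ",
                         paste(amb, collapse = ", ")),
                  "gochrono_ambiguity_error")
  }
  map <- setNames(pri, sec)
  # collapse chains to terminal primaries
  for (i in seq_along(map)) {
    seen <- names(map)[[i]]
    v <- map[[i]]
    while (v %in% names(map)) {
      if (v %in% seen) {
        stop_gochrono(paste0("accession mapping contains a cycle involving ", v),
                      "gochrono_ambiguity_error")
      }
      seen <- c(seen, v)
      v <- map[[v]]
    }
    map[[i]] <- v
  }
  structure(map, class = "go_accession_map")
}

#' Harmonize gene accessions across time
#'
#' Rewrites every record whose accession appears as a secondary in the
#' mapping to its current primary accession. Records with accessions not
#' covered by the mapping pass through unchanged (most accessions are
#' already primary). Duplicates created by merges collapse to a single
#' record; the number of rewritten records is attached as attribute
#' `n_mapped`.
#'
#' @param edition a `go_annotations` edition.
#' @param mapping a `go_accession_map` from [parse_secondary_mapping()].
#' @return a `go_annotations` edition with harmonized accessions.
#' @export
harmonize <- function(edition, mapping) {
  stopifnot(inherits(edition, "go_annotations"),
            inherits(mapping, "go_accession_map"))
  rec <- edition$records
  hit <- rec$accession %in% names(mapping)
  rec$accession[hit] <- unname(unclass(mapping)[rec$accession[hit]])
  out <- new_annotations(edition$species, edition$edition_date, rec)
  attr(out, "n_mapped") <- sum(hit)
  out
}

#' Match an annotation edition to an ontology edition
#'
#' The ontology release paired with an annotation edition is the one
#' with the closest release date at or before the annotation date.
#'
#' @param annotation_date date of the annotation edition.
#' @param ontology_dates vector of available ontology release dates.
#' @return the matched ontology date.
#' @export
match_ontology <- function(annotation_date, ontology_dates) {
  ad <- as_edition_date(annotation_date, "annotation_date")
  od <- sort(as.Date(ontology_dates))
  if (length(od) == 0L) {
    stop_gochrono("no ontology dates supplied", "gochrono_match_error")
  }
  cand <- od[od <= ad]
  if (length(cand) == 0L) {
    stop_gochrono(sprintf("no ontology edition at or before %s (earliest is %s)",
                          format(ad), format(od[[1L]])),
                  "gochrono_match_error")
  }
  cand[[length(cand)]]
}

#' Materialize propagated annotations for one edition
#'
#' Joins an annotation edition to its matched ontology edition and
#' applies the true-path rule: each gene's propagated set is the
#' reflexive transitive closure of its direct terms. Secondary term ids
#' are resolved through `alt_id`; annotations to terms that are unknown
#' or obsolete in the matched ontology are dropped (the count is kept in
#' the `dropped` element and reported via a warning when nonzero).
#'
#' @param edition a `go_annotations` edition (direct annotations).
#' @param ontology the `go_ontology` edition matched to it (see
#'   [match_ontology()]).
#' @param quiet suppress the dropped-annotation warning.
#' @return a `go_propagated` object with elements `annotations` (the
#'   cleaned direct records), `ontology`, `gene_to_direct` and
#'   `gene_to_propagated` (named lists of term-id vectors), and
#'   `dropped` (counts of discarded records).
#' @export
propagate_edition <- function(edition, ontology, quiet = FALSE) {
  stopifnot(inherits(edition, "go_annotations"), inherits(ontology, "go_ontology"))
  rec <- edition$records
  res <- resolve_term_id(ontology, rec$term_id)
  known <- !is.na(res)
  obs_tab <- setNames(ontology$terms$obsolete, ontology$terms$term_id)
  live <- known
  live[known] <- !obs_tab[res[known]]
  n_unknown <- sum(!known)
  n_obsolete <- sum(known & !live)
  if ((n_unknown + n_obsolete) > 0L && !quiet) {
    warning(sprintf(
      "dropped %d annotation record(s): %d to unknown terms, %d to obsolete terms",
      n_unknown + n_obsolete, n_unknown, n_obsolete), call. = FALSE)
  }
  rec <- rec[live, , drop = FALSE]
  rec$term_id <- res[live]
  rec <- rec[!duplicated(rec[c("accession", "term_id", "evidence_code")]), ,
             drop = FALSE]
  rownames(rec) <- NULL
  # refresh aspect from the matched ontology (authoritative for this edition)
  asp <- setNames(ontology$terms$aspect, ontology$terms$term_id)
  rec$aspect <- unname(asp[rec$term_id])

  gene_to_direct <- lapply(split(rec$term_id, rec$accession),
                           function(t) sort(unique(t)))
  anc <- ancestor_map(ontology)
  gene_to_propagated <- lapply(gene_to_direct, function(t) {
    sort(unique(c(t, unlist(anc[t], use.names = FALSE))))
  })
  structure(
    list(
      annotations = new_annotations(edition$species, edition$edition_date, rec),
      ontology = ontology,
      ontology_date = ontology$edition_date,
      edition_date = edition$edition_date,
      species = edition$species,
      gene_to_direct = gene_to_direct,
      gene_to_propagated = gene_to_propagated,
      dropped = c(unknown = n_unknown, obsolete = n_obsolete),
      .cache = new.env(parent = emptyenv())
    ),
    class = "go_propagated"
  )
}

#' @export
print.go_propagated <- function(x, ...) {
  cat(sprintf(
    "<go_propagated> %s annotations %s (ontology %s): %d genes, mean direct %.2f, mean propagated %.2f\n",
    x$species, format(x$edition_date), format(x$ontology_date),
    length(x$gene_to_direct),
    if (length(x$gene_to_direct)) mean(lengths(x$gene_to_direct)) else 0,
    if (length(x$gene_to_propagated)) mean(lengths(x$gene_to_propagated)) else 0))
  invisible(x)
}

# Per-term propagated/direct gene counts for one edition, memoized.
term_gene_counts <- function(pedition, mode = c("propagated", "direct")) {
  mode <- match.arg(mode)
  key <- paste0("tgc_", mode)
  cache <- pedition$.cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  sets <- if (mode == "propagated") pedition$gene_to_propagated else pedition$gene_to_direct
  counts <- table(unlist(sets, use.names = FALSE))
  out <- setNames(as.integer(counts), names(counts))
  cache[[key]] <- out
  out
}

# Per-term -> genes map (propagated), memoized; used by enrichment and
# the synthetic corpus sampler.
term_gene_sets <- function(pedition) {
  cache <- pedition$.cache
  if (!is.null(cache$tgs)) return(cache$tgs)
  sets <- pedition$gene_to_propagated
  genes <- rep(names(sets), lengths(sets))
  terms <- unlist(sets, use.names = FALSE)
  out <- split(genes, terms)
  cache$tgs <- out
  out
}

#' A date-ordered series of propagated editions
#'
#' @param editions list of `go_propagated` objects for one species, in
#'   any order; they are sorted by edition date.
#' @return a `go_series` object.
#' @export
edition_series <- function(editions) {
  stopifnot(length(editions) >= 1L,
            all(vapply(editions, inherits, logical(1), "go_propagated")))
  dates <- as.Date(vapply(editions, function(e) as.character(e$edition_date),
                          character(1)))
  o <- order(dates)
  editions <- editions[o]
  dates <- dates[o]
  if (anyDuplicated(dates)) {
    stop_gochrono("duplicate edition dates in series", "gochrono_structure_error")
  }
  sp <- unique(vapply(editions, function(e) e$species, character(1)))
  if (length(sp) != 1L) {
    stop_gochrono("edition series mixes species", "gochrono_structure_error")
  }
  structure(list(species = sp, dates = dates, editions = editions),
            class = "go_series")
}

#' @export
print.go_series <- function(x, ...) {
  cat(sprintf("<go_series> %s: %d editions from %s to %s\n", x$species,
              length(x$editions), format(min(x$dates)), format(max(x$dates))))
  invisible(x)
}

series_edition <- function(series, date) {
  d <- as_edition_date(date, "edition date")
  i <- match(d, series$dates)
  if (is.na(i)) {
    stop_gochrono(paste0("no edition dated ", format(d), " in series"),
                  "gochrono_lookup_error")
  }
  series$editions[[i]]
}
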