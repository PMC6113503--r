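# Writers and readers for the plain-text interchange formats: OBO, GAF,
# GMT, hit lists, publication-date tables, propagated-annotation exports.

#' Write an ontology edition as OBO 1.2 text
#'
#' Stanzas are emitted in term-id order so output is byte-stable for a
#' given edition. Round-trips through [parse_obo()].
#'
#' @param ontology a `go_ontology`.
#' @param path output file; when `NULL`, the lines are returned.
#' @return invisibly, the character vector of lines.
#' @export
write_obo <- function(ontology, path = NULL) {
  stopifnot(inherits(ontology, "go_ontology"))
  terms <- ontology$terms[order(ontology$terms$term_id), , drop = FALSE]
  edges <- ontology$edges
  alt_by_term <- if (length(ontology$alt)) {
    split(names(ontology$alt), unname(ontology$alt))
  } else {
    list()
  }
  out <- c("format-version: 1.2",
           "default-namespace: biological_process", "")
  for (i in seq_len(nrow(terms))) {
    id <- terms$term_id[[i]]
    stanza <- c("[Term]",
                paste0("id: ", id),
                paste0("name: ", terms$name[[i]]),
                paste0("namespace: ", terms$aspect[[i]]))
    alts <- sort(alt_by_term[[id]] %||% character(0))
    if (length(alts)) stanza <- c(stanza, paste0("alt_id: ", alts))
    ei <- which(edges$child == id)
    ei <- ei[order(edges$parent[ei])]
    for (j in ei) {
      stanza <- c(stanza, if (edges$relation[[j]] == "IS_A") {
        paste0("is_a: ", edges$parent[[j]])
      } else {
        paste0("relationship: part_of ", edges$parent[[j]])
      })
    }
    if (terms$obsolete[[i]]) stanza <- c(stanza, "is_obsolete: true")
    out <- c(out, stanza, "")
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Write an annotation edition as GAF 2.2 text
#'
#' Emits one 17-column row per record, in (accession, term, evidence)
#' order; round-trips through [parse_gaf()].
#'
#' @param annotations a `go_annotations` edition.
#' @param path output file; when `NULL`, the lines are returned.
#' @return invisibly, the character vector of lines.
#' @export
write_gaf <- function(annotations, path = NULL) {
  stopifnot(inherits(annotations, "go_annotations"))
  rec <- annotations$records
  rec <- rec[order(rec$accession, rec$term_id, rec$evidence_code), , drop = FALSE]
  aspect_code <- setNames(names(ASPECT_CODES), ASPECT_CODES)
  date_col <- format(annotations$edition_date, "%Y%m%d")
  rows <- if (nrow(rec)) {
    paste("SYNT", rec$accession, rec$accession, rec$qualifier, rec$term_id,
          "SYNT_REF:0000001", rec$evidence_code, "",
          unname(aspect_code[rec$aspect]), "", "", "protein", "taxon:0000",
          date_col, "SYNT", "", "", sep = "\t")
  } else {
    character(0)
  }
  out <- c("!gaf-version: 2.2",
           paste0("!date-generated: ", format(annotations$edition_date)),
           rows)
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Write hit lists as a GMT gene-set file
#'
#' One set per line: name, description (the publication date in ISO
#' format when present), then the member genes, tab-separated.
#'
#' @param hit_lists list of `go_hitlist` objects.
#' @param path output file; when `NULL`, the lines are returned.
#' @return invisibly, the character vector of lines.
#' @export
write_gmt <- function(hit_lists, path = NULL) {
  out <- vapply(hit_lists, function(h) {
    desc <- if (is.null(h$publication_date)) "na" else format(h$publication_date)
    paste(c(h$name, desc, sort(h$genes)), collapse = "\t")
  }, character(1))
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Read a GMT gene-set file
#'
#' @param file path to a GMT file, or a character vector of lines.
#' @param dates optional named vector/data.frame of publication dates to
#'   attach (names or first column = set names). When the GMT
#'   description field itself parses as a date, it is used as fallback.
#' @return list of `go_hitlist` objects.
#' @export
read_gmt <- function(file, dates = NULL) {
  lines <- if (length(file) == 1L && !grepl("\n|\t", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(as.character(file), "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[nzchar(lines)]
  if (is.data.frame(dates)) {
    dates <- setNames(as.character(dates[[2L]]), as.character(dates[[1L]]))
  }
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop_gochrono(paste0("malformed GMT line: ", substr(l, 1, 60)),
                    "gochrono_parse_error")
    }
    nm <- f[[1L]]
    pd <- if (!is.null(dates) && nm %in% names(dates)) {
      dates[[nm]]
    } else {
      d <- tryCatch(suppressWarnings(as.Date(f[[2L]])),
                    error = function(e) as.Date(NA))
      if (is.na(d)) NULL else d
    }
    hitlist(nm, f[-(1:2)], pd)
  })
}

#' Read a one-gene-per-line hit list
#'
#' @param file path to a text file (blank lines and `#` comments are
#'   skipped).
#' @return character vector of accessions.
#' @export
read_hitlist <- function(file) {
  lines <- trimws(readLines(file, warn = FALSE))
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Write / read a name-to-publication-date table
#'
#' Two tab-separated columns: set name, ISO date.
#'
#' @param hit_lists list of `go_hitlist` objects.
#' @param path output file.
#' @return `write_dates_tsv` invisibly returns the lines;
#'   `read_dates_tsv` returns a data.frame with `name`, `date`.
#' @export
write_dates_tsv <- function(hit_lists, path = NULL) {
  out <- vapply(hit_lists, function(h) {
    paste(h$name,
          if (is.null(h$publication_date)) "na" else format(h$publication_date),
          sep = "\t")
  }, character(1))
  out <- c("name\tdate", out)
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' @rdname write_dates_tsv
#' @export
read_dates_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("name", "date")
  df
}

#' Export propagated annotations as a tidy TSV
#'
#' One row per (gene, term): accession, term id, `direct` or `inferred`
#' status, and evidence category (`curated` when any supporting direct
#' record at or beneath the term is non-IEA, else `automatic`).
#'
#' @param pedition a `go_propagated` edition.
#' @param path output file; when `NULL`, the data.frame is returned.
#' @return invisibly (or visibly when `path` is `NULL`) the exported
#'   data.frame.
#' @export
export_propagated <- function(pedition, path = NULL) {
  stopifnot(inherits(pedition, "go_propagated"))
  rec <- pedition$annotations$records
  anc <- ancestor_map(pedition$ontology)
  rows <- lapply(names(pedition$gene_to_propagated), function(g) {
    direct <- pedition$gene_to_direct[[g]]
    prop <- pedition$gene_to_propagated[[g]]
    gr <- rec[rec$accession == g, , drop = FALSE]
    # per propagated term: curated if any supporting direct record is curated
    curated_reach <- unique(unlist(lapply(
      gr$term_id[gr$evidence_code != "IEA"],
      function(t) c(t, anc[[t]])), use.names = FALSE))
    data.frame(accession = g, term_id = prop,
               status = ifelse(prop %in% direct, "direct", "inferred"),
               evidence_category = ifelse(prop %in% curated_reach,
                                          "curated", "automatic"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Export a gene-to-term-list table
#'
#' A two-column tab-separated export (accession, space-separated term
#' ids) compatible with generic enrichment tools.
#'
#' @param pedition a `go_propagated` edition.
#' @param path output file; when `NULL`, the lines are returned.
#' @param mode `"propagated"` or `"direct"` term sets.
#' @return invisibly, the character vector of lines.
#' @export
export_gene_sets <- function(pedition, path = NULL,
                             mode = c("propagated", "direct")) {
  mode <- match.arg(mode)
  sets <- if (mode == "propagated") pedition$gene_to_propagated
          else pedition$gene_to_direct
  genes <- sort(names(sets))
  out <- vapply(genes, function(g) paste(g, paste(sets[[g]], collapse = " "),
                                         sep = "\t"), character(1))
  if (!is.null(path)) writeLines(out, path)
  invisible(unname(out))
}

# Canonical forms for round-trip comparisons in tests and the store.
canonical_ontology <- function(ontology) {
  terms <- ontology$terms[order(ontology$terms$term_id), , drop = FALSE]
  rownames(terms) <- NULL
  edges <- ontology$edges[order(ontology$edges$child, ontology$edges$parent,
                                ontology$edges$relation), , drop = FALSE]
  rownames(edges) <- NULL
  alt <- ontology$alt
  alt <- if (length(alt)) alt[order(names(alt))] else setNames(character(0), character(0))
  list(edition_date = ontology$edition_date, terms = terms, edges = edges,
       alt = alt)
}

canonical_annotations <- function(annotations) {
  rec <- annotations$records
  rec <- rec[order(rec$accession, rec$term_id, rec$evidence_code),
             c("accession", "term_id", "evidence_code", "aspect"), drop = FALSE]
  rownames(rec) <- NULL
  list(species = annotations$species, edition_date = annotations$edition_date,
       records = rec)
}
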