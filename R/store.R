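# A small on-disk, plain-text edition store: dated OBO and GAF files
# plus a manifest, standing in for a relational database at desk scale.

#' Build a local edition store
#'
#' Registers dated ontology (OBO) and annotation (GAF) editions into a
#' directory with a tab-separated manifest. Files are copied in, so the
#' store is self-contained and diff-able.
#'
#' @param obo_files named character vector: names are ISO edition
#'   dates, values are OBO file paths.
#' @param gaf_files named character vector: names are ISO edition
#'   dates, values are GAF file paths.
#' @param species species label recorded in the manifest.
#' @param out_dir store directory (created if needed).
#' @param mapping_file optional secondary-accession mapping file,
#'   copied in and applied at load time.
#' @return invisibly, the manifest data.frame.
#' @export
build_db <- function(obo_files, gaf_files, species, out_dir,
                     mapping_file = NULL) {
  stopifnot(length(obo_files) >= 1L, length(gaf_files) >= 1L,
            !is.null(names(obo_files)), !is.null(names(gaf_files)))
  dir.create(file.path(out_dir, "ontology"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "annotations"), showWarnings = FALSE)
  copy_in <- function(files, sub, ext) {
    dates <- vapply(names(files), function(d)
      as.character(as_edition_date(d, "edition date")), character(1))
    dest <- file.path(out_dir, sub, paste0(dates, ext))
    ok <- file.copy(files, dest, overwrite = TRUE)
    if (!all(ok)) {
      stop_gochrono(paste0("could not copy: ", files[!ok][[1L]]),
                    "gochrono_config_error")
    }
    data.frame(kind = sub, edition_date = dates,
               path = file.path(sub, basename(dest)), stringsAsFactors = FALSE)
  }
  manifest <- rbind(copy_in(obo_files, "ontology", ".obo"),
                    copy_in(gaf_files, "annotations", ".gaf"))
  if (!is.null(mapping_file)) {
    file.copy(mapping_file, file.path(out_dir, "sec_ac.txt"), overwrite = TRUE)
  }
  manifest <- manifest[order(manifest$kind, manifest$edition_date), ,
                       drop = FALSE]
  attr(manifest, "species") <- species
  writeLines(c(paste0("# species\t", species),
               "kind\tedition_date\tpath",
               paste(manifest$kind, manifest$edition_date, manifest$path,
                     sep = "\t")),
             file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}

#' Load an edition store into a propagated series
#'
#' Parses every registered edition, harmonizes accessions when a
#' mapping file is present, matches each annotation edition to the
#' closest ontology release at or before it, and propagates.
#'
#' @param dir store directory written by [build_db()].
#' @return list with `series` (a `go_series`), `ontologies` (list of
#'   `go_ontology` by date), and `species`.
#' @export
load_db <- function(dir) {
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf)) {
    stop_gochrono(paste0("no manifest.tsv in ", dir), "gochrono_config_error")
  }
  lines <- readLines(mf, warn = FALSE)
  species <- sub("^# species\t", "", lines[[1L]])
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  manifest <- data.frame(kind = vapply(body, `[[`, character(1), 1L),
                         edition_date = vapply(body, `[[`, character(1), 2L),
                         path = vapply(body, `[[`, character(1), 3L),
                         stringsAsFactors = FALSE)
  onts <- manifest[manifest$kind == "ontology", , drop = FALSE]
  gafs <- manifest[manifest$kind == "annotations", , drop = FALSE]
  ontologies <- lapply(seq_len(nrow(onts)), function(i)
    parse_obo(file.path(dir, onts$path[[i]]), onts$edition_date[[i]]))
  names(ontologies) <- onts$edition_date
  ont_dates <- as.Date(onts$edition_date)
  map_file <- file.path(dir, "sec_ac.txt")
  mapping <- if (file.exists(map_file)) parse_secondary_mapping(map_file)
             else NULL
  editions <- lapply(seq_len(nrow(gafs)), function(i) {
    ann <- parse_gaf(file.path(dir, gafs$path[[i]]), species,
                     gafs$edition_date[[i]])
    if (!is.null(mapping)) ann <- harmonize(ann, mapping)
    d <- match_ontology(ann$edition_date, ont_dates)
    propagate_edition(ann, ontologies[[as.character(d)]], quiet = TRUE)
  })
  list(series = edition_series(editions), ontologies = ontologies,
       species = species)
}
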