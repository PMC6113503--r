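# Internal helpers: structured conditions, seed scoping, set utilities.

stop_gochrono <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "gochrono_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

as_edition_date <- function(x, what = "date") {
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (length(d) != 1L || is.na(d)) {
    stop_gochrono(sprintf("invalid %s: %s", what, paste(x, collapse = ", ")),
                  "gochrono_date_error")
  }
  d
}

#' Jaccard index of two sets
#'
#' \eqn{|A \cap B| / |A \cup B|}, with the both-empty case defined as 1
#' (two empty annotation or result sets are identical).
#'
#' @param a,b character vectors (treated as sets).
#' @return a number in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}
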