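# Term normalization and MedDRA system-organ-class (SOC) mapping.
#
# The registry reports adverse events as free text in mixed terminologies.
# Analyses here resolve each term to one of the 26 MedDRA SOCs through a
# deterministic exact-match table on canonicalized strings; a registry-
# provided SOC annotation, when present, wins over the table.

.aecohort_env <- new.env(parent = emptyenv())

#' Sentinel label for events no SOC can be resolved for
#'
#' @return The string `"UNCLASSIFIED"`.
#' @export
unclassifiedLabel <- function() "UNCLASSIFIED"

#' The 26 MedDRA system organ classes
#'
#' Returns the packaged vocabulary of the 26 top-level MedDRA system organ
#' classes (the pre-2016 set, without the later "Product issues" class, to
#' which no events are mapped here).
#'
#' @return Character vector of 26 unique class names.
#' @export
soc_classes <- function() {
  if (is.null(.aecohort_env$socs)) {
    path <- system.file("extdata", "soc_classes.txt",
                        package = "aecohort", mustWork = TRUE)
    x <- readLines(path, encoding = "UTF-8")
    x <- trimws(x)
    x <- x[nzchar(x) & !startsWith(x, "#")]
    if (length(x) != 26L || anyDuplicated(x)) {
      stop("packaged SOC vocabulary must contain exactly 26 unique classes")
    }
    .aecohort_env$socs <- x
  }
  .aecohort_env$socs
}

#' Canonicalize an adverse-event term
#'
#' Lower-cases, strips leading/trailing whitespace, replaces punctuation by
#' spaces and collapses whitespace runs, so that superficial reporting
#' variants ("Nausea/Vomiting", "nausea  vomiting") share one key. The
#' transform is idempotent.
#'
#' @param term Character vector of free-text terms.
#' @return Character vector of canonical terms.
#' @examples
#' normalize_term("  Pharyngitis ")
#' normalize_term("nausea/vomiting")
#' @export
normalize_term <- function(term) {
  if (!is.character(term)) stop("`term` must be character")
  x <- tolower(term)
  x <- gsub("[[:punct:]]", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  x <- trimws(x)
  if (any(!is.na(x) & !nzchar(x))) {
    stop("term is empty after normalization")
  }
  x
}

#' Build a term -> SOC map from vectors
#'
#' @param terms Character vector of terms (canonicalized on construction).
#' @param socs Character vector of SOC names, one per term; every value must
#'   be one of [soc_classes()].
#' @return A `term_map`: a named character vector (canonical term -> SOC).
#' @export
term_map <- function(terms, socs) {
  if (length(terms) != length(socs)) stop("`terms` and `socs` lengths differ")
  bad <- !(socs %in% soc_classes())
  if (any(bad)) {
    stop("unknown SOC name(s): ", paste(unique(socs[bad]), collapse = "; "))
  }
  keys <- normalize_term(terms)
  # identical duplicate rows collapse; conflicting duplicates are an error
  tab <- unique(data.frame(key = keys, soc = socs, stringsAsFactors = FALSE))
  dup <- tab$key[duplicated(tab$key)]
  if (length(dup)) {
    stop("conflicting SOC assignments for term(s): ",
         paste(unique(dup), collapse = "; "))
  }
  structure(stats::setNames(tab$soc, tab$key), class = "term_map")
}

#' Load a term -> SOC map from a two-column TSV
#'
#' The file has two tab-separated columns (term, SOC name), UTF-8, with
#' `#`-prefixed comment lines and blank lines ignored. Keys are
#' canonicalized via [normalize_term()]; identical duplicate rows are
#' deduplicated and conflicting duplicates are an error.
#'
#' @param path Path to the TSV file.
#' @return A `term_map`.
#' @export
load_term_map <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  if (!length(lines)) {
    return(structure(stats::setNames(character(0), character(0)),
                     class = "term_map"))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    stop("term map row(s) without exactly 2 tab-separated fields: line(s) ",
         paste(which(keep)[nf != 2L], collapse = ", "))
  }
  terms <- vapply(parts, `[[`, character(1), 1L)
  socs <- trimws(vapply(parts, `[[`, character(1), 2L))
  bad <- !(socs %in% soc_classes())
  if (any(bad)) {
    stop("unknown SOC name in term map at line(s) ",
         paste(which(keep)[bad], collapse = ", "), ": ",
         paste(unique(socs[bad]), collapse = "; "))
  }
  term_map(terms, socs)
}

#' The term map shipped with the package
#'
#' A table of common registry adverse-event terms mapped to MedDRA SOCs.
#' It is an exact-match lookup, not a concept normalizer: synonyms can be
#' aliased by adding rows that share a SOC.
#'
#' @return A `term_map`.
#' @export
default_term_map <- function() {
  if (is.null(.aecohort_env$default_map)) {
    .aecohort_env$default_map <- load_term_map(
      system.file("extdata", "term_soc_map.tsv",
                  package = "aecohort", mustWork = TRUE))
  }
  .aecohort_env$default_map
}

#' Resolve adverse-event terms to a system organ class
#'
#' A registry-provided SOC annotation (`soc_hint`) naming a valid class is
#' returned as-is; otherwise the canonicalized term is looked up in `map`;
#' terms resolved by neither route get [unclassifiedLabel()]. Never errors.
#'
#' @param term Character vector of free-text terms.
#' @param map A `term_map`.
#' @param soc_hint Optional character vector (recycled) of registry-provided
#'   SOC names; `NA` means absent.
#' @return Character vector of SOC names or `"UNCLASSIFIED"`.
#' @examples
#' map_to_soc("Pharyngitis", default_term_map())
#' @export
map_to_soc <- function(term, map, soc_hint = NULL) {
  socs <- soc_classes()
  n <- length(term)
  hint <- if (is.null(soc_hint)) rep(NA_character_, n) else
    rep_len(as.character(soc_hint), n)
  out <- rep(unclassifiedLabel(), n)
  hinted <- !is.na(hint) & hint %in% socs
  out[hinted] <- hint[hinted]
  if (any(!hinted)) {
    key <- normalize_term(term[!hinted])
    hit <- unclass(map)[key]
    out[!hinted] <- ifelse(is.na(hit), unclassifiedLabel(), hit)
  }
  out
}

#' Load a nonserious-event filter list
#'
#' One term per line, `#` comments and blank lines ignored; terms are
#' canonicalized. Used by [top_events()] to drop commonly shared nonserious
#' events before ranking.
#'
#' @param path Path to the list; defaults to the small placeholder list
#'   shipped with the package.
#' @return Character vector of canonical terms.
#' @export
load_filter_list <- function(path = system.file("extdata",
                                                "nonserious_filter.txt",
                                                package = "aecohort",
                                                mustWork = TRUE)) {
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(normalize_term(lines))
}

#' @export
print.term_map <- function(x, ...) {
  cat("<term_map> ", length(x), " canonical terms -> ",
      length(unique(unclass(x))), " SOCs\n", sep = "")
  invisible(x)
}
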