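#' Lexicon driving filtering and categorization
#'
#' A lexicon bundles every keyword resource the pipeline needs: the medical
#' terms list feeding the inclusion stage of the health filter, exclusion
#' patterns mechanizing the manual relevance pass, the keyword-to-category
#' map for the 14 symptom categories, a medical-conditions list for the
#' engagement filter, and gynaecological-cancer terms for control
#' exclusion.  `default_lexicon()` loads the lexicon bundled with the
#' package; `read_lexicon()` loads user-supplied files with the same layout
#' (the bundled condition list and symptom map are synthetic stand-ins for
#' unpublished resources and should be replaced for production use).
#'
#' @param dir directory containing `medical_terms.txt`, `exclusions.yaml`,
#'   `categories.yaml`, `conditions.txt` and `gynae_terms.txt`.
#' @return an object of class `qs_lexicon`: a list with elements
#'   `medical_terms` (character), `medical_words` (character; the unique
#'   normalized words of all terms), `exclusion_pairs` (tibble with columns
#'   `trigger`, `context`), `exclusion_phrases` (character), `category_map`
#'   (named list keyword -> character vector of categories), `categories`
#'   (the 14 category names), `conditions` (character) and `gynae_terms`
#'   (character).
#' @export
read_lexicon <- function(dir) {
  path <- function(f) file.path(dir, f)
  terms <- read_term_file(path("medical_terms.txt"))
  excl <- yaml::read_yaml(path("exclusions.yaml"))
  cats <- yaml::read_yaml(path("categories.yaml"))
  new_lexicon(
    medical_terms = terms,
    exclusion_pairs = dplyr::bind_rows(lapply(excl$pairs, tibble::as_tibble)),
    exclusion_phrases = as.character(excl$phrases %||% character(0)),
    categories_by_name = lapply(cats, function(x) unique(normalize_text(x))),
    conditions = read_term_file(path("conditions.txt")),
    gynae_terms = read_term_file(path("gynae_terms.txt"))
  )
}

#' @rdname read_lexicon
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon", package = "querysift"))
}

read_term_file <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

new_lexicon <- function(medical_terms, exclusion_pairs, exclusion_phrases,
                        categories_by_name, conditions, gynae_terms) {
  medical_terms <- unique(normalize_text(medical_terms))
  if (length(medical_terms) == 0L)
    qs_stop("lexicon has an empty medical terms list", "qs_config_error")
  # word-level inclusion: every word of a multi-word phrase matches on its own
  medical_words <- unique(unlist(tokenize(medical_terms)))
  # invert category -> keywords into keyword -> categories
  kw <- unlist(lapply(names(categories_by_name), function(cn) {
    stats::setNames(rep(cn, length(categories_by_name[[cn]])),
                    categories_by_name[[cn]])
  }))
  category_map <- split(unname(kw), names(kw))
  structure(list(
    medical_terms = sort(medical_terms),
    medical_words = sort(medical_words),
    exclusion_pairs = exclusion_pairs,
    exclusion_phrases = normalize_text(exclusion_phrases),
    category_map = category_map,
    categories = names(categories_by_name),
    conditions = unique(normalize_text(conditions)),
    gynae_terms = unique(normalize_text(gynae_terms))
  ), class = "qs_lexicon")
}

#' @export
print.qs_lexicon <- function(x, ...) {
  cat("<qs_lexicon>\n",
      " medical terms: ", length(x$medical_terms),
      " (", length(x$medical_words), " words)\n",
      " exclusion pairs/phrases: ", nrow(x$exclusion_pairs), "/",
      length(x$exclusion_phrases), "\n",
      " categories: ", length(x$categories), "\n",
      " conditions: ", length(x$conditions),
      "; gynae-cancer terms: ", length(x$gynae_terms), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
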