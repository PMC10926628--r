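#' Normalize and tokenize query text
#'
#' Lowercases, folds Unicode accents to ASCII (so "douleur pelvienne" and
#' "dolor pélvico" match unaccented lexicon entries), replaces anything that
#' is not a letter or digit with a space, and splits on whitespace.  Word
#' order is preserved; no stemming or spelling correction is applied.
#'
#' @param text character vector of raw query strings.
#' @return a list (one element per input string) of character vectors of
#'   tokens; an empty string yields `character(0)`.
#' @export
#' @examples
#' tokenize(c("Club Foot!", "douleur pelvienne", ""))
tokenize <- function(text) {
  norm <- normalize_text(text)
  out <- stringi::stri_split_regex(norm, "\\s+", omit_empty = TRUE)
  out[is.na(norm)] <- list(character(0))
  out
}

# Normalized form of a query: lowercase, accent-folded, punctuation
# collapsed to single spaces, trimmed.  The unit of "verbatim repeat"
# comparison and of phrase matching.
normalize_text <- function(text) {
  x <- stringi::stri_trans_tolower(text)
  x <- stringi::stri_trans_general(x, "Latin-ASCII")
  x <- stringi::stri_replace_all_regex(x, "[^a-z0-9]+", " ")
  stringi::stri_trim_both(x)
}

# Does each normalized text contain any of `phrases` as a consecutive word
# sequence?  Phrases are normalized the same way; single-word phrases match
# single tokens.  Vectorized over `norm_text`.
contains_phrase <- function(norm_text, phrases) {
  if (length(phrases) == 0L) return(rep(FALSE, length(norm_text)))
  pat <- paste0("\\b(", paste(stringi::stri_replace_all_regex(
    normalize_text(phrases), " ", "\\\\s"), collapse = "|"), ")\\b")
  stringi::stri_detect_regex(norm_text, pat)
}
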