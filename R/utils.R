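#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed percentages in clinical
#' reports conventionally round half up.  Used by [enrolment_accounting()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` places.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Salted FNV-1a hash for pseudo-anonymisation
#'
#' Replaces identifiers at ingest so that original account names are never
#' persisted.  A 32-bit FNV-1a hash of `salt || id` rendered as 8 hex
#' characters; deterministic given the salt, not reversible in practice but
#' not cryptographic — choose a private salt.
#'
#' @param ids character vector of identifiers.
#' @param salt character scalar mixed into every hash.
#' @return character vector of 8-character hex digests, prefixed "u".
#' @export
#' @examples
#' anonymise_user_ids(c("alice@example.org", "bob@example.org"), salt = "s1")
anonymise_user_ids <- function(ids, salt = "") {
  stopifnot(is.character(ids), is.character(salt), length(salt) == 1L)
  vapply(ids, function(id) {
    bytes <- utf8ToInt(enc2utf8(paste0(salt, id)))
    h <- 2166136261
    for (b in bytes) {
      # XOR touches only the low byte (b < 256); done by hand because the
      # running hash exceeds R's 32-bit integer range
      low <- h %% 256
      h <- h - low + bitwXor(low, b)
      # 32-bit modular multiply by the FNV prime 16777619, in two halves
      # to stay within double precision
      lo <- h %% 65536
      hi <- (h - lo) / 65536
      h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
    }
    sprintf("u%04x%04x", h %/% 65536, h %% 65536)
  }, character(1), USE.NAMES = FALSE)
}

#' Total-variation distance between two discrete distributions
#'
#' @param p,q non-negative numeric vectors of equal length; each is
#'   normalized to sum to one before comparison.
#' @return half the L1 distance between the normalized vectors, in `[0, 1]`.
#' @export
tv_distance <- function(p, q) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0),
            sum(p) > 0, sum(q) > 0)
  sum(abs(p / sum(p) - q / sum(q))) / 2
}

# Content hash of a file (FNV-1a over bytes), used in run manifests.
file_digest <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# stop() with a class so callers/tests can distinguish error kinds
qs_stop <- function(msg, class) {
  stop(structure(class = c(class, "querysift_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
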