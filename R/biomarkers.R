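# Canonical identifiers for the five urinary steroid ratios monitored by the
# steroidal module of the athlete biological passport.

.BIOMARKERS <- c(
  te          = "T/E",
  aetio       = "A/Etio",
  adiol_ratio = "5a-ADiol/5b-ADiol",
  adiol_e     = "5a-ADiol/E",
  at          = "A/T"
)

#' Canonical biomarker keys
#'
#' The five urinary steroid ratios tracked by the steroidal passport module,
#' in the fixed package-wide order: `te` (T/E), `aetio` (A/Etio),
#' `adiol_ratio` (5a-ADiol/5b-ADiol), `adiol_e` (5a-ADiol/E), `at` (A/T).
#'
#' @return Character vector of the five canonical keys.
#' @export
#' @examples
#' biomarker_keys()
biomarker_keys <- function() {
  names(.BIOMARKERS)
}

#' Display labels for biomarker keys
#'
#' @param keys Character vector of canonical keys (default all five).
#' @return Named character vector mapping key to human-readable ratio label.
#' @export
biomarker_labels <- function(keys = biomarker_keys()) {
  keys <- match.arg(keys, biomarker_keys(), several.ok = TRUE)
  .BIOMARKERS[keys]
}

#' Canonicalise biomarker names
#'
#' Accepts canonical keys, the display labels (with ASCII `a`/`b` or Greek
#' alpha/beta spellings), and a few common punctuation variants, and returns
#' the canonical key. Unknown names are an error.
#'
#' @param x Character vector of biomarker names.
#' @return Character vector of canonical keys, same length as `x`.
#' @export
#' @examples
#' canonical_biomarker(c("T/E", "a/etio", "5a-ADiol/E"))
canonical_biomarker <- function(x) {
  stopifnot(is.character(x))
  norm <- tolower(gsub("[^a-z0-9/]+", "", gsub("α", "a", gsub("β", "b", tolower(x)))))
  lookup <- c(
    "te" = "te", "t/e" = "te",
    "aetio" = "aetio", "a/etio" = "aetio",
    "adiolratio" = "adiol_ratio", "adiol_ratio" = "adiol_ratio",
    "5aadiol/5badiol" = "adiol_ratio", "5adiol/5bdiol" = "adiol_ratio",
    "adiole" = "adiol_e", "adiol_e" = "adiol_e", "5aadiol/e" = "adiol_e",
    "at" = "at", "a/t" = "at"
  )
  norm2 <- gsub("_", "", tolower(x))
  out <- lookup[norm]
  out[is.na(out)] <- lookup[norm2][is.na(out)]
  if (anyNA(out)) {
    stop("unknown biomarker name(s): ", paste(unique(x[is.na(out)]), collapse = ", "))
  }
  unname(out)
}
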