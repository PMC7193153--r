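#' Canonical amino-acid state order
#'
#' The 20 amino acids in the order used by the original empirical-model
#' publications (and by their de-facto plain-text interchange files):
#' A R N D C Q E G H I L K M F P S T W Y V. Every matrix, partial-likelihood
#' vector and posterior-probability vector in this package is indexed in this
#' order; it is the single source of truth for state indices.
#'
#' @return Character vector of length 20.
#' @export
aa_states <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# index lookup; gap '-' and unknown 'X' map to NA (missing data)
aa_index <- function(x) {
  idx <- match(x, aa_states())
  bad <- !is.na(x) & is.na(idx) & !(x %in% c("-", "X", "?"))
  if (any(bad)) {
    stop("invalid amino-acid state(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  idx
}
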