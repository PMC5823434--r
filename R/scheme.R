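#' Amino-acid equivalency groups
#'
#' Conservation is scored over reduced amino-acid alphabets: residues within
#' one group are treated as interchangeable. The default scheme partitions
#' the 20 standard residues into six physicochemical groups --
#' aliphatic/small hydrophobic (AVLIMC), aromatic (FWYH), polar uncharged
#' (STNQ), basic (KR), acidic (DE) and conformationally special (GP).
#'
#' @return A named list of character vectors, one per group; names are the
#'   concatenated group letters.
#' @examples
#' defaultEquivalencyGroups()
#' @export
defaultEquivalencyGroups <- function() {
  lapply(
    c(AVLIMC = "AVLIMC", FWYH = "FWYH", STNQ = "STNQ",
      KR = "KR", DE = "DE", GP = "GP"),
    function(s) strsplit(s, "")[[1]]
  )
}

STANDARD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Validate an equivalency scheme
#'
#' A scheme must contain at least two disjoint groups whose union is a
#' subset of the 20 standard amino-acid letters.
#'
#' @param scheme named list of character vectors of single residue letters.
#' @return The scheme, invisibly, after validation.
#' @export
validateScheme <- function(scheme) {
  if (!is.list(scheme) || length(scheme) < 2L)
    stop("equivalency scheme must be a list of at least 2 groups")
  letters_all <- unlist(scheme, use.names = FALSE)
  if (anyDuplicated(letters_all))
    stop("equivalency groups must be disjoint")
  bad <- setdiff(letters_all, STANDARD_AA)
  if (length(bad))
    stop("non-standard residue letters in scheme: ", paste(bad, collapse = ", "))
  if (is.null(names(scheme)) || any(!nzchar(names(scheme))))
    stop("equivalency groups must be named")
  invisible(scheme)
}

# residue letter -> group index; unassigned letters (gaps, ambiguity codes)
# are absent from the table and map to NA
schemeLookup <- function(scheme) {
  validateScheme(scheme)
  idx <- rep.int(seq_along(scheme), lengths(scheme))
  stats::setNames(idx, unlist(scheme, use.names = FALSE))
}
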