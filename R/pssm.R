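#' Build an equivalency-group PSSM from an ortholog alignment
#'
#' Counts, at each canonical position, how many alignment rows carry a
#' residue from each equivalency group, and normalises each position's
#' counts to frequencies summing to one. Insertion and flank columns are
#' not counted, so every family member shares the same 60-position frame;
#' canonical positions missing from the alignment (shorter spans, all-gap
#' columns) keep zero rows rather than being dropped.
#'
#' @param alignment a [DomainAlignment-class].
#' @param map a [CanonicalMap-class] built from this alignment.
#' @param scheme equivalency scheme.
#' @param domainName domain identifier (default: the map's reference id).
#' @param nPositions canonical frame size (default 60).
#' @return A [PSSM-class].
#' @export
buildPSSM <- function(alignment, map, scheme = defaultEquivalencyGroups(),
                      domainName = map@referenceId, nPositions = 60L) {
  lk <- schemeLookup(scheme)
  if (length(map@labels) != alignmentWidth(alignment))
    stop("map was not built from this alignment (column count differs)")
  m <- as.matrix(alignment)
  k <- length(scheme)
  counts <- matrix(0L, nrow = nPositions, ncol = k,
                   dimnames = list(as.character(seq_len(nPositions)),
                                   names(scheme)))
  canonCols <- canonicalColumns(map)
  for (j in canonCols) {
    pos <- as.integer(map@labels[j])
    grp <- lk[m[, j]]
    counts[pos, ] <- counts[pos, ] + tabulate(grp[!is.na(grp)], nbins = k)
  }
  rs <- rowSums(counts)
  freq <- counts / ifelse(rs > 0, rs, 1)
  new("PSSM", domainName = domainName, counts = counts,
      frequencies = freq, groups = names(scheme))
}

#' Assemble the family master matrix
#'
#' Flattens each domain's PSSM frequencies into one row, position-major:
#' position 1 groups 1..k, position 2 groups 1..k, and so on. With the
#' default 6-group scheme and a 28-member family over 60 positions this is
#' the 28 x 360 matrix used for surface clustering.
#'
#' @param pssms list of [PSSM-class] objects sharing one scheme and frame.
#' @return A [MasterMatrix-class].
#' @export
buildMasterMatrix <- function(pssms) {
  if (!length(pssms)) stop("no PSSMs")
  groups <- pssms[[1L]]@groups
  nPos <- nrow(pssms[[1L]]@counts)
  for (p in pssms) {
    if (!identical(p@groups, groups) || nrow(p@counts) != nPos)
      stop("all PSSMs must share one equivalency scheme and position frame")
  }
  rows <- t(vapply(pssms, function(p) as.vector(t(p@frequencies)),
                   numeric(nPos * length(groups))))
  rownames(rows) <- unname(vapply(pssms, function(p) p@domainName,
                                  character(1)))
  colnames(rows) <- paste0("p", sprintf("%02d", rep(seq_len(nPos),
                                                    each = length(groups))),
                           ".", rep(groups, nPos))
  new("MasterMatrix", rows, groups = groups,
      positions = seq_len(nPos))
}

#' Restrict a master matrix to one surface's position blocks
#'
#' @param master a [MasterMatrix-class].
#' @param positions integer vector of canonical positions (e.g.
#'   `defaultSurfaces()$SI`).
#' @return A [MasterMatrix-class] over those positions only (columns =
#'   `length(positions) * k`).
#' @export
subsetSurface <- function(master, positions) {
  if (!length(positions)) stop("empty surface")
  positions <- sort(unique(as.integer(positions)))
  if (any(!positions %in% master@positions))
    stop("positions outside the master matrix frame")
  k <- length(master@groups)
  blockOf <- match(positions, master@positions)
  cols <- as.vector(vapply(blockOf, function(b) (b - 1L) * k + seq_len(k),
                           integer(k)))
  new("MasterMatrix", unclass(master)[, cols, drop = FALSE],
      groups = master@groups, positions = positions)
}
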