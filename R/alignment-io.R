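#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA or Clustal file into a [DomainAlignment-class].
#' Sequences are upper-cased and `.` gap characters normalised to `-`.
#' A taxon-group tag is parsed from a trailing `_<integer>` suffix on each
#' record name when present; an absent suffix leaves the tag `NA`.
#'
#' @param path file path.
#' @param format `"fasta"` (aligned FASTA) or `"clustal"`.
#' @param kind `"paralog"` or `"ortholog"` (metadata only).
#' @return A [DomainAlignment-class].
#' @export
readAlignment <- function(path, format = c("fasta", "clustal"),
                          kind = "paralog") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "fasta") {
    ss <- Biostrings::readAAStringSet(path)
  } else {
    ss <- Biostrings::unmasked(
      Biostrings::readAAMultipleAlignment(path, format = "clustal"))
  }
  seqs <- stats::setNames(as.character(ss), names(ss))
  DomainAlignment(seqs, kind = kind)   # validity enforces rectangular + ids
}

#' Write an alignment as aligned FASTA
#'
#' @param alignment a [DomainAlignment-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(alignment, path) {
  ss <- Biostrings::AAStringSet(alignment@seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Map alignment columns onto the canonical domain numbering
#'
#' The reference row anchors a standard numbering for the domain core
#' (60 residues for SH3). Columns where the reference carries a residue
#' inside `span` get canonical numbers 1..n in order; columns where the
#' reference has a gap between two canonical residues get insertion labels
#' anchored to their left neighbour (`"14a"`, `"14b"`, ...); columns outside
#' the span get flank labels (`"N1"`, `"N2"`, ... before it, `"C1"`, ...
#' after it, numbered left to right).
#'
#' @param alignment a [DomainAlignment-class].
#' @param referenceId id of the reference row.
#' @param span length-2 integer vector: 1-based inclusive start and end of
#'   the domain in the *ungapped* reference sequence.
#' @param nPositions maximum canonical positions (default 60).
#' @return A [CanonicalMap-class].
#' @export
buildCanonicalMap <- function(alignment, referenceId, span,
                              nPositions = 60L) {
  if (!referenceId %in% alignmentIds(alignment))
    stop("reference row '", referenceId, "' not found in alignment")
  ref <- strsplit(alignment@seqs[[referenceId]], "")[[1]]
  isRes <- ref != "-"
  span <- as.integer(span)
  if (length(span) != 2L || any(is.na(span)) || span[1] > span[2] || span[1] < 1L)
    stop("span must be two increasing 1-based indices")
  if (span[2] > sum(isRes))
    stop("span end (", span[2], ") exceeds ungapped reference length (",
         sum(isRes), ")")
  spanLen <- span[2] - span[1] + 1L
  if (spanLen > nPositions)
    stop("span covers ", spanLen, " residues but at most ", nPositions,
         " canonical positions are allowed")

  ungapped <- cumsum(isRes)
  labels <- character(length(ref))
  nN <- 0L; nC <- 0L; lastCanon <- 0L; insCount <- 0L
  for (col in seq_along(ref)) {
    if (isRes[col]) {
      u <- ungapped[col]
      if (u < span[1]) {
        nN <- nN + 1L; labels[col] <- paste0("N", nN)
      } else if (u > span[2]) {
        nC <- nC + 1L; labels[col] <- paste0("C", nC)
      } else {
        lastCanon <- u - span[1] + 1L
        labels[col] <- as.character(lastCanon)
        insCount <- 0L
      }
    } else {
      if (lastCanon == 0L) {                  # gap left of the span
        nN <- nN + 1L; labels[col] <- paste0("N", nN)
      } else if (lastCanon == spanLen) {      # gap right of the span
        nC <- nC + 1L; labels[col] <- paste0("C", nC)
      } else {                                # insertion between canonicals
        insCount <- insCount + 1L
        labels[col] <- paste0(lastCanon, insertionSuffix(insCount))
      }
    }
  }
  new("CanonicalMap", labels = labels, referenceId = referenceId,
      span = span, refResidues = ref)
}

# a, b, ..., z, aa, ab, ... (base-26 letter suffixes, anchored left)
insertionSuffix <- function(i) {
  out <- ""
  while (i > 0L) {
    r <- (i - 1L) %% 26L
    out <- paste0(letters[r + 1L], out)
    i <- (i - 1L) %/% 26L
  }
  out
}

#' Restrict an alignment to its canonical columns
#'
#' Drops insertion and flank columns, returning the sub-alignment over the
#' canonical positions only, in row order.
#'
#' @param alignment a [DomainAlignment-class].
#' @param map a [CanonicalMap-class] built from this alignment.
#' @return A [DomainAlignment-class] whose width equals the number of
#'   canonical positions.
#' @export
sliceToCanonical <- function(alignment, map) {
  if (length(map@labels) != alignmentWidth(alignment))
    stop("map was not built from this alignment (column count differs)")
  keep <- canonicalColumns(map)
  if (!length(keep)) stop("no canonical columns to slice (empty intersection)")
  m <- as.matrix(alignment)[, keep, drop = FALSE]
  seqs <- apply(m, 1L, paste0, collapse = "")
  new("DomainAlignment", seqs = stats::setNames(seqs, alignmentIds(alignment)),
      species = alignment@species, taxonGroup = alignment@taxonGroup,
      kind = alignment@kind)
}

#' Write a CanonicalMap as TSV
#'
#' Columns: `alignment_column` (1-based), `label`, `reference_residue`.
#'
#' @param map a [CanonicalMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCanonicalMap <- function(map, path) {
  df <- data.frame(alignment_column = seq_along(map@labels),
                   label = map@labels,
                   reference_residue = map@refResidues)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Species paralog counts (SPC)
#'
#' Given a presence table of species (rows) by family members (columns),
#' the SPC of a species is the number of family members for which that
#' species contributes an ortholog. Species with high SPC are the most
#' informative representatives when assembling ortholog alignments.
#'
#' @param presence logical matrix or data.frame, species x members.
#' @return Named integer vector of per-species counts.
#' @export
speciesParalogCount <- function(presence) {
  m <- as.matrix(presence)
  if (!length(m)) stop("empty presence table")
  storage.mode(m) <- "logical"
  stats::setNames(as.integer(rowSums(m)), rownames(m))
}

#' Greedy per-taxon representative selection
#'
#' For each taxon group picks the species with the highest SPC, breaking
#' ties by lexicographic species name. This mirrors the manual practice of
#' building ortholog alignments from the most paralog-complete species of
#' each lineage.
#'
#' @param presence logical species x member table (rownames = species).
#' @param taxonGroup integer vector of taxon-group tags, one per species.
#' @return data.frame with columns `taxon_group`, `species`, `spc`.
#' @export
selectRepresentatives <- function(presence, taxonGroup) {
  spc <- speciesParalogCount(presence)
  if (length(taxonGroup) != length(spc))
    stop("taxonGroup must have one entry per species")
  groups <- sort(unique(taxonGroup))
  rows <- lapply(groups, function(g) {
    cand <- names(spc)[taxonGroup == g]
    cand <- cand[order(-spc[cand], cand)]
    data.frame(taxon_group = g, species = cand[1L], spc = spc[[cand[1L]]])
  })
  do.call(rbind, rows)
}
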