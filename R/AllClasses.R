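## Central S4 containers. Accessors live next to the methods that use them;
## construction is always through the exported constructor functions so the
## validity methods run.

#' DomainAlignment: a gapped protein multiple sequence alignment
#'
#' Rows are gapped amino-acid sequences of equal length with unique ids.
#' Each row carries a species name and an optional small-integer taxon-group
#' tag (0 conventionally marks the reference species). `kind` records
#' whether the alignment compares family members within one species
#' ("paralog") or one member across species ("ortholog").
#'
#' @slot seqs named character vector of gapped, upper-case sequences; names
#'   are the row ids.
#' @slot species character vector, one per row.
#' @slot taxonGroup integer vector, one per row; `NA` when unassigned.
#' @slot kind `"paralog"` or `"ortholog"`.
#' @export
setClass("DomainAlignment",
  representation(seqs = "character", species = "character",
                 taxonGroup = "integer", kind = "character"))

setValidity("DomainAlignment", function(object) {
  n <- length(object@seqs)
  if (n < 2L) return("alignment must contain at least 2 rows")
  ids <- names(object@seqs)
  if (is.null(ids) || any(!nzchar(ids))) return("every row needs a non-empty id")
  if (anyDuplicated(ids))
    return(paste0("duplicate row ids: ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  w <- nchar(object@seqs)
  if (any(w == 0L)) return("empty sequence")
  if (length(unique(w)) != 1L) {
    ref <- max(w)
    bad <- ids[w != ref]
    return(paste0("ragged alignment: rows of differing length: ",
                  paste(bad, collapse = ", ")))
  }
  if (length(object@species) != n || length(object@taxonGroup) != n)
    return("species and taxonGroup must have one entry per row")
  if (!object@kind %in% c("paralog", "ortholog"))
    return("kind must be 'paralog' or 'ortholog'")
  TRUE
})

#' Construct a DomainAlignment
#'
#' @param seqs named character vector of gapped sequences (names = row ids),
#'   or an unnamed vector combined with `ids`.
#' @param ids row identifiers; defaults to `names(seqs)`.
#' @param species per-row species names; by default derived from the id by
#'   stripping a trailing `_<integer>` taxon suffix.
#' @param taxonGroup per-row integer tags; by default parsed from a trailing
#'   `_<integer>` suffix on the id (`NA` when absent).
#' @param kind `"paralog"` or `"ortholog"`.
#' @return A [DomainAlignment-class] object.
#' @export
DomainAlignment <- function(seqs, ids = names(seqs), species = NULL,
                            taxonGroup = NULL, kind = "paralog") {
  force(ids)
  seqs <- toupper(as.character(seqs))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  names(seqs) <- ids
  if (is.null(taxonGroup)) taxonGroup <- parseTaxonSuffix(ids)
  if (is.null(species)) species <- sub("_[0-9]+$", "", ids)
  new("DomainAlignment", seqs = seqs, species = as.character(species),
      taxonGroup = as.integer(taxonGroup), kind = kind)
}

# trailing "_<integer>" on a record name; absent suffix -> NA, never an error
parseTaxonSuffix <- function(ids) {
  m <- regmatches(ids, regexpr("_([0-9]+)$", ids))
  out <- rep(NA_integer_, length(ids))
  has <- grepl("_[0-9]+$", ids)
  out[has] <- as.integer(sub("^_", "", m))
  out
}

setMethod("show", "DomainAlignment", function(object) {
  cat(sprintf("DomainAlignment (%s): %d rows x %d columns\n",
              object@kind, length(object@seqs), nchar(object@seqs[[1L]])))
  ids <- names(object@seqs)
  shown <- utils::head(ids, 4L)
  cat("  rows: ", paste(shown, collapse = ", "),
      if (length(ids) > 4L) ", ..." else "", "\n", sep = "")
})

#' @describeIn DomainAlignment-class row ids.
#' @param x,object a `DomainAlignment`.
#' @export
alignmentIds <- function(x) names(x@seqs)

#' @describeIn DomainAlignment-class number of rows.
#' @export
alignmentDepth <- function(x) length(x@seqs)

#' @describeIn DomainAlignment-class number of columns.
#' @export
alignmentWidth <- function(x) nchar(x@seqs[[1L]])

#' @describeIn DomainAlignment-class `"paralog"` or `"ortholog"`.
#' @export
alignmentKind <- function(x) x@kind

#' @describeIn DomainAlignment-class per-row taxon-group tags.
#' @export
taxonGroups <- function(x) stats::setNames(x@taxonGroup, names(x@seqs))

#' @describeIn DomainAlignment-class per-row species names.
#' @export
alignmentSpecies <- function(x) stats::setNames(x@species, names(x@seqs))

#' Character matrix view of an alignment (rows x columns)
#' @param x a `DomainAlignment`.
#' @param ... ignored.
#' @return character matrix with row names = ids.
#' @export
setMethod("as.matrix", "DomainAlignment", function(x, ...) {
  m <- do.call(rbind, strsplit(x@seqs, ""))
  rownames(m) <- names(x@seqs)
  m
})

#' CanonicalMap: alignment columns labelled on the canonical domain numbering
#'
#' Every column of an alignment gets exactly one label: a canonical position
#' number (`"1"`..`"60"`), an insertion label anchored to the canonical
#' position on its left (`"14a"`, `"14b"`, ...), or a flank label outside
#' the domain span (`"N1"`, `"N2"`, ... left of the span; `"C1"`, ... right
#' of it).
#'
#' @slot labels character vector, one label per alignment column.
#' @slot referenceId id of the reference row the numbering was read from.
#' @slot span 1-based inclusive start/end in the ungapped reference sequence.
#' @slot refResidues reference-row character per column (`"-"` for gaps).
#' @export
setClass("CanonicalMap",
  representation(labels = "character", referenceId = "character",
                 span = "integer", refResidues = "character"))

setValidity("CanonicalMap", function(object) {
  canon <- suppressWarnings(as.integer(object@labels[grepl("^[0-9]+$", object@labels)]))
  if (anyDuplicated(canon)) return("canonical numbers must appear at most once")
  if (is.unsorted(canon, strictly = TRUE)) return("canonical numbers must increase")
  if (length(object@refResidues) != length(object@labels))
    return("refResidues and labels must have equal length")
  TRUE
})

setMethod("show", "CanonicalMap", function(object) {
  canon <- grepl("^[0-9]+$", object@labels)
  cat(sprintf(paste0("CanonicalMap: %d columns (%d canonical, %d insertion,",
                     " %d flank), reference '%s'\n"),
              length(object@labels), sum(canon),
              sum(grepl("^[0-9]+[a-z]", object@labels)),
              sum(grepl("^[NC][0-9]+$", object@labels)), object@referenceId))
})

#' @describeIn CanonicalMap-class per-column labels.
#' @param x,object a `CanonicalMap`.
#' @export
mapLabels <- function(x) x@labels

#' @describeIn CanonicalMap-class indices of canonical (1..60) columns.
#' @export
canonicalColumns <- function(x) which(grepl("^[0-9]+$", x@labels))

#' ConservationProfile: per-position entropies and SC values for one domain
#'
#' @slot domainName domain identifier.
#' @slot positions data.frame over canonical positions with columns
#'   `position`, `paralog_entropy`, `ortholog_entropy`, `sc`, `sc_display`
#'   (1-decimal rounding of `sc`) and `nongap_fraction` (ortholog side).
#'   Entropies are `NA` where the non-gap fraction falls below the gap
#'   threshold; `sc` is defined only where both entropies are.
#' @slot insertions data.frame over insertion/flank labels with columns
#'   `label`, `ortholog_entropy`, `nongap_fraction`.
#' @slot gapThreshold minimum non-gap fraction below which entropy is not
#'   calculated.
#' @export
setClass("ConservationProfile",
  representation(domainName = "character", positions = "data.frame",
                 insertions = "data.frame", gapThreshold = "numeric"))

setValidity("ConservationProfile", function(object) {
  p <- object@positions
  need <- c("position", "paralog_entropy", "ortholog_entropy", "sc")
  if (!all(need %in% names(p))) return("positions missing required columns")
  both <- !is.na(p$paralog_entropy) & !is.na(p$ortholog_entropy)
  if (any(xor(both, !is.na(p$sc)))) return("sc must be defined iff both entropies are")
  if (any(p$sc[!is.na(p$sc)] <= 0)) return("sc must be positive where defined")
  TRUE
})

setMethod("show", "ConservationProfile", function(object) {
  p <- object@positions
  cat(sprintf("ConservationProfile '%s': %d canonical positions (%d with SC), %d insertion/flank columns\n",
              object@domainName, nrow(p), sum(!is.na(p$sc)), nrow(object@insertions)))
  if (any(!is.na(p$sc))) {
    top <- p[order(-p$sc), ][1L, ]
    cat(sprintf("  max SC %.2f at position %d\n", top$sc, top$position))
  }
})

#' @describeIn ConservationProfile-class per-position table.
#' @param x,object a `ConservationProfile`.
#' @export
scPositions <- function(x) x@positions

#' @describeIn ConservationProfile-class insertion/flank table.
#' @export
scInsertions <- function(x) x@insertions

#' PSSM: equivalency-group occurrence matrix for one domain
#'
#' @slot domainName domain identifier.
#' @slot counts integer matrix, canonical positions x groups, of grouped
#'   residue occurrences in the domain's ortholog alignment.
#' @slot frequencies the counts row-normalised to sum to 1; rows with no
#'   counted residue are all zero.
#' @slot groups group names (must match across a family).
#' @export
setClass("PSSM",
  representation(domainName = "character", counts = "matrix",
                 frequencies = "matrix", groups = "character"))

setValidity("PSSM", function(object) {
  if (any(object@counts < 0)) return("counts must be non-negative")
  rs <- rowSums(object@frequencies)
  ok <- abs(rs - 1) < 1e-9 | rs == 0
  if (!all(ok)) return("frequency rows must sum to 0 or 1")
  if (!identical(colnames(object@counts), object@groups))
    return("counts columns must be named by group")
  TRUE
})

setMethod("show", "PSSM", function(object) {
  cat(sprintf("PSSM '%s': %d positions x %d groups (%d residues counted)\n",
              object@domainName, nrow(object@counts), ncol(object@counts),
              sum(object@counts)))
})

#' MasterMatrix: family-wide flattened PSSM frequencies
#'
#' One row per domain; columns are position-major blocks of group
#' frequencies (position 1 groups 1..k, position 2 groups 1..k, ...).
#'
#' @slot .Data numeric matrix, domains x (positions * groups).
#' @slot groups group names.
#' @slot positions canonical positions represented by the column blocks.
#' @export
setClass("MasterMatrix", contains = "matrix",
  representation(groups = "character", positions = "integer"))

setValidity("MasterMatrix", function(object) {
  if (ncol(object) != length(object@groups) * length(object@positions))
    return("column count must equal positions x groups")
  TRUE
})

setMethod("show", "MasterMatrix", function(object) {
  cat(sprintf("MasterMatrix: %d domains x %d columns (%d positions x %d groups)\n",
              nrow(object), ncol(object), length(object@positions),
              length(object@groups)))
})

#' ClusterResult: a partition and/or dendrogram over family members
#'
#' @slot surface name of the surface whose columns were clustered.
#' @slot method `"kmeans"` or `"hierarchical"`.
#' @slot labels named integer cluster labels (1..k; k-means only).
#' @slot k number of clusters (`NA` for a pure dendrogram).
#' @slot seed RNG seed used (k-means only).
#' @slot withinss total within-cluster sum of squares (k-means only).
#' @slot tree the `hclust` object (hierarchical only), else `NULL`.
#' @slot newick Newick serialisation of the tree (hierarchical only).
#' @export
setClass("ClusterResult",
  representation(surface = "character", method = "character",
                 labels = "integer", k = "integer", seed = "integer",
                 withinss = "numeric", tree = "ANY", newick = "character"))

setMethod("show", "ClusterResult", function(object) {
  if (object@method == "kmeans") {
    cat(sprintf("ClusterResult (kmeans, surface %s): k=%d, seed=%d, tot.withinss=%.4g\n",
                object@surface, object@k, object@seed, object@withinss))
  } else {
    cat(sprintf("ClusterResult (hierarchical, surface %s): %d leaves\n",
                object@surface, length(object@tree$labels)))
  }
})

#' @describeIn ClusterResult-class cluster labels (k-means).
#' @param x,object a `ClusterResult`.
#' @export
clusterLabels <- function(x) x@labels

#' @describeIn ClusterResult-class Newick string (hierarchical).
#' @export
exportNewick <- function(x) {
  if (!length(x@newick)) stop("no dendrogram in this ClusterResult")
  x@newick
}

#' BindingMatrix: SPOT peptide-array intensities for one species
#'
#' @slot species species name.
#' @slot intensities non-negative numeric matrix, peptides (rows, named by
#'   peptide id) x domains (columns).
#' @slot peptides named character vector of peptide sequences (15-mers in
#'   the assay emulated here), names = peptide ids.
#' @export
setClass("BindingMatrix",
  representation(species = "character", intensities = "matrix",
                 peptides = "character"))

setValidity("BindingMatrix", function(object) {
  m <- object@intensities
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("peptide ids (row names) must be unique")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    return("domain names (column names) must be unique")
  if (any(!is.finite(m)) || any(m < 0))
    return("intensities must be finite and non-negative")
  if (!identical(sort(names(object@peptides)), sort(rownames(m))))
    return("peptide sequences must be named by the matrix row ids")
  TRUE
})

#' Construct a BindingMatrix
#' @param species species name.
#' @param intensities peptide x domain numeric matrix with dimnames.
#' @param peptides named character vector of peptide sequences.
#' @return A [BindingMatrix-class] object.
#' @export
BindingMatrix <- function(species, intensities, peptides) {
  new("BindingMatrix", species = species,
      intensities = as.matrix(intensities), peptides = peptides)
}

setMethod("show", "BindingMatrix", function(object) {
  cat(sprintf("BindingMatrix '%s': %d peptides x %d domains\n",
              object@species, nrow(object@intensities),
              ncol(object@intensities)))
})

#' @describeIn BindingMatrix-class intensity matrix.
#' @param x,object a `BindingMatrix`.
#' @export
bindingIntensities <- function(x) x@intensities

#' @describeIn BindingMatrix-class domain (column) names.
#' @export
bindingDomains <- function(x) colnames(x@intensities)

#' BindingFractionTable: per-species peptide binding fractions
#'
#' Binding fraction of peptide i for domain d is its intensity to d divided
#' by its summed intensity over every family domain assayed in that species.
#' Peptides whose intensity sum falls below the signal floor are excluded
#' and recorded with the reason.
#'
#' @slot species species name.
#' @slot fractions retained-peptide x domain matrix; each row sums to 1.
#' @slot intensities the retained raw intensities (same shape), kept so
#'   peptides can also be ranked by intensity.
#' @slot excluded data.frame of dropped peptides: `peptide`, `sum`, `reason`.
#' @export
setClass("BindingFractionTable",
  representation(species = "character", fractions = "matrix",
                 intensities = "matrix", excluded = "data.frame"))

setValidity("BindingFractionTable", function(object) {
  f <- object@fractions
  if (nrow(f)) {
    if (any(f < -1e-12) || any(f > 1 + 1e-12)) return("fractions must lie in [0, 1]")
    if (any(abs(rowSums(f) - 1) > 1e-9)) return("fraction rows must sum to 1")
  }
  TRUE
})

setMethod("show", "BindingFractionTable", function(object) {
  cat(sprintf("BindingFractionTable '%s': %d retained peptides x %d domains (%d excluded)\n",
              object@species, nrow(object@fractions), ncol(object@fractions),
              nrow(object@excluded)))
})

#' @describeIn BindingFractionTable-class fraction matrix.
#' @param x,object a `BindingFractionTable`.
#' @export
bindingFractions <- function(x) x@fractions

#' @describeIn BindingFractionTable-class excluded-peptide log.
#' @export
excludedPeptides <- function(x) x@excluded
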