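#' Exponential positional entropy over equivalency groups
#'
#' For an alignment column, residues are binned into equivalency groups and
#' the entropy is `exp(-sum p_i * log(p_i))` over the group fractions
#' `p_i`. The value is the effective number of groups present: 1 for a
#' perfectly conserved column, k when k groups occur equally often.
#' Fractions are taken over the residues that belong to a group; gaps and
#' unassignable letters (ambiguity codes) count neither in the numerator
#' nor the denominator. When the fraction of rows carrying a grouped
#' residue falls below `gapThreshold`, the entropy is not calculated
#' (`NA`): with 29 rows and the default 0.64, at least 19 residues are
#' required.
#'
#' @param column character vector of single letters (residues, `-` gaps,
#'   possibly ambiguity codes).
#' @param scheme equivalency scheme, see [defaultEquivalencyGroups()].
#' @param gapThreshold minimum non-gap fraction (default 0.64).
#' @return Entropy in `[1, k]`, or `NA` below the gap threshold.
#' @examples
#' positionalEntropy(rep(c("A", "F", "S", "K"), each = 7))  # 4 groups at 25%
#' @export
positionalEntropy <- function(column, scheme = defaultEquivalencyGroups(),
                              gapThreshold = 0.64) {
  if (!length(column)) stop("empty column")
  lk <- schemeLookup(scheme)
  grp <- lk[toupper(column)]
  counted <- sum(!is.na(grp))
  if (counted == 0L || counted / length(column) < gapThreshold)
    return(NA_real_)
  p <- tabulate(grp[!is.na(grp)], nbins = length(scheme)) / counted
  p <- p[p > 0]                 # 0 * log(0) contributes nothing
  exp(-sum(p * log(p)))
}

#' Profile every column of an alignment
#'
#' Computes, per column, the non-gap fraction, the exponential
#' group-entropy and the group fractions. Columns are labelled from `map`
#' when given (canonical numbers, insertion labels, flank labels), else by
#' their 1-based column index.
#'
#' @param alignment a [DomainAlignment-class].
#' @param map optional [CanonicalMap-class] built from this alignment.
#' @param scheme equivalency scheme.
#' @param gapThreshold minimum non-gap fraction for a defined entropy.
#' @return data.frame with columns `label`, `column`, `nongap_fraction`,
#'   `entropy` and one `p.<group>` column per group (NA when no residue
#'   was counted).
#' @export
profileAlignment <- function(alignment, map = NULL,
                             scheme = defaultEquivalencyGroups(),
                             gapThreshold = 0.64) {
  lk <- schemeLookup(scheme)
  m <- as.matrix(alignment)
  nc <- ncol(m)
  if (!is.null(map)) {
    if (length(map@labels) != nc)
      stop("map was not built from this alignment (column count differs)")
    labels <- map@labels
  } else {
    labels <- as.character(seq_len(nc))
  }
  k <- length(scheme)
  pm <- matrix(NA_real_, nrow = nc, ncol = k,
               dimnames = list(NULL, paste0("p.", names(scheme))))
  nongap <- numeric(nc)
  entropy <- rep(NA_real_, nc)
  depth <- nrow(m)
  for (j in seq_len(nc)) {
    grp <- lk[m[, j]]
    counted <- sum(!is.na(grp))
    nongap[j] <- counted / depth
    if (counted > 0L) {
      p <- tabulate(grp[!is.na(grp)], nbins = k) / counted
      pm[j, ] <- p
      if (nongap[j] >= gapThreshold) {
        pp <- p[p > 0]
        entropy[j] <- exp(-sum(pp * log(pp)))
      }
    }
  }
  cbind(data.frame(label = labels, column = seq_len(nc),
                   nongap_fraction = nongap, entropy = entropy),
        as.data.frame(pm))
}

#' Specific conservation (SC) profile for one domain
#'
#' SC at a canonical position is the paralog-alignment entropy divided by
#' the ortholog-alignment entropy there. A high SC marks a position that
#' varies across family members but is conserved within the member's own
#' orthologs -- a candidate specificity-determining residue. SC is defined
#' only where both entropies are (each alignment applies the gap threshold
#' independently). Insertion and flank columns of the ortholog profile are
#' carried along with their ortholog entropies.
#'
#' @param paralogProfile profile of the paralog alignment
#'   ([profileAlignment()] output labelled on the canonical numbering of
#'   this domain's row).
#' @param orthologProfile profile of this domain's ortholog alignment,
#'   likewise canonically labelled.
#' @param domainName domain identifier.
#' @param nPositions canonical positions (default 60).
#' @param gapThreshold recorded threshold (metadata).
#' @return A [ConservationProfile-class].
#' @export
scProfile <- function(paralogProfile, orthologProfile, domainName,
                      nPositions = 60L, gapThreshold = 0.64) {
  canon <- as.character(seq_len(nPositions))
  pe <- stats::setNames(paralogProfile$entropy, paralogProfile$label)[canon]
  oe <- stats::setNames(orthologProfile$entropy, orthologProfile$label)[canon]
  ng <- stats::setNames(orthologProfile$nongap_fraction,
                        orthologProfile$label)[canon]
  sc <- ifelse(!is.na(pe) & !is.na(oe), pe / oe, NA_real_)
  pos <- data.frame(position = seq_len(nPositions),
                    paralog_entropy = unname(pe),
                    ortholog_entropy = unname(oe),
                    sc = unname(sc),
                    sc_display = round(unname(sc), 1L),
                    nongap_fraction = unname(ng))
  extra <- orthologProfile[!grepl("^[0-9]+$", orthologProfile$label),
                           c("label", "entropy", "nongap_fraction")]
  names(extra)[2L] <- "ortholog_entropy"
  rownames(extra) <- NULL
  new("ConservationProfile", domainName = domainName, positions = pos,
      insertions = extra, gapThreshold = gapThreshold)
}

#' Default binding-surface definitions
#'
#' Surface I is the canonical PxxP-binding surface of the SH3 fold;
#' surface II is the extended specificity surface between the RT- and
#' N-Src loops; `other` collects the remaining canonical positions.
#'
#' @return Named list of integer position vectors (`SI`, `SII`, `other`).
#' @export
defaultSurfaces <- function() {
  SI <- c(8L, 9L, 10L, 36L, 37L, 51L, 52L, 53L, 54L)
  SII <- c(13:17, 30:35, 38L, 49L)
  list(SI = SI, SII = as.integer(SII),
       other = setdiff(1:60, c(SI, SII)))
}

#' Average SC over a set of canonical positions
#'
#' Positions with undefined SC are excluded from both numerator and
#' denominator; the result is `NA` when no position in the set has a
#' defined SC.
#'
#' @param profile a [ConservationProfile-class].
#' @param positions integer vector of canonical positions (e.g. one entry
#'   of [defaultSurfaces()]).
#' @return Mean SC, or `NA`.
#' @export
averageRegionSC <- function(profile, positions) {
  if (!length(positions)) stop("empty surface/region")
  pos <- profile@positions
  if (any(!positions %in% pos$position))
    stop("positions outside the canonical range")
  vals <- pos$sc[match(positions, pos$position)]
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Family-wide per-position SC matrix and average
#'
#' @param profiles named list of [ConservationProfile-class], one per domain.
#' @return `familySCMatrix`: numeric matrix, domains x positions, of SC
#'   values (NA where undefined).
#' @export
familySCMatrix <- function(profiles) {
  if (!length(profiles)) stop("no profiles")
  rows <- lapply(profiles, function(p) p@positions$sc)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(profiles, function(p) p@domainName, character(1))
  colnames(m) <- as.character(profiles[[1L]]@positions$position)
  m
}

#' @rdname familySCMatrix
#' @return `familyPositionAverage`: named numeric vector of per-position
#'   mean SC across domains (defined values only).
#' @export
familyPositionAverage <- function(profiles) {
  m <- familySCMatrix(profiles)
  colMeans(m, na.rm = TRUE)
}

#' Default region assignment for insertion and flank labels
#'
#' Insertions are assigned to the loop containing their anchor position:
#' RT-loop (anchors 11-19), N-Src loop (29-35), distal loop (42-48);
#' flank labels map to the N-/C-terminus. Anchors outside any loop map to
#' `"other"`. Ranges are overridable.
#'
#' @param labels character vector of insertion/flank labels.
#' @param rtLoop,nSrcLoop,distalLoop integer anchor ranges.
#' @return Named character vector label -> region.
#' @export
defaultInsertionRegions <- function(labels, rtLoop = 11:19,
                                    nSrcLoop = 29:35, distalLoop = 42:48) {
  region <- vapply(labels, function(lab) {
    if (grepl("^N[0-9]+$", lab)) return("N-terminus")
    if (grepl("^C[0-9]+$", lab)) return("C-terminus")
    if (grepl("^[0-9]+[a-z]+$", lab)) {
      anchor <- as.integer(sub("^([0-9]+).*", "\\1", lab))
      if (anchor %in% rtLoop) return("RT-loop")
      if (anchor %in% nSrcLoop) return("N-Src loop")
      if (anchor %in% distalLoop) return("distal loop")
      return("other")
    }
    stop("not an insertion or flank label: '", lab, "'")
  }, character(1))
  stats::setNames(region, labels)
}

INSERTION_REGIONS <- c("N-terminus", "RT-loop", "N-Src loop",
                       "distal loop", "C-terminus")

#' Count conserved insertions per region
#'
#' An insertion (or flank) column counts as conserved when its ortholog
#' entropy is defined and at or below `cutoff` (default 3.3). Counts are
#' returned for the five standard regions plus `"other"`.
#'
#' @param profile a [ConservationProfile-class].
#' @param regions named character vector label -> region covering every
#'   insertion/flank label of the profile; defaults to
#'   [defaultInsertionRegions()] on the profile's labels.
#' @param cutoff entropy cutoff (default 3.3).
#' @return Named integer vector of per-region counts.
#' @export
conservedInsertionCount <- function(profile, regions = NULL, cutoff = 3.3) {
  ins <- profile@insertions
  if (is.null(regions)) regions <- defaultInsertionRegions(ins$label)
  unknown <- setdiff(names(regions), ins$label)
  if (length(unknown))
    stop("unknown label(s) in regions: ", paste(unknown, collapse = ", "))
  uncovered <- setdiff(ins$label, names(regions))
  if (length(uncovered))
    stop("regions must cover all insertion/flank labels; missing: ",
         paste(uncovered, collapse = ", "))
  lv <- union(INSERTION_REGIONS, unique(unname(regions)))
  hit <- !is.na(ins$ortholog_entropy) & ins$ortholog_entropy <= cutoff
  counts <- table(factor(regions[ins$label][hit], levels = lv))
  stats::setNames(as.integer(counts), lv)
}

#' Per-domain conservation summary
#'
#' Average SC per surface with high-SC flags (mean >= `scCutoff`) and
#' conserved-insertion counts per region -- the per-domain row of the
#' family summary table.
#'
#' @param profile a [ConservationProfile-class].
#' @param surfaces named list of position sets (default [defaultSurfaces()]).
#' @param scCutoff high-SC flag threshold (default 1.7).
#' @param insertionCutoff conserved-insertion entropy cutoff (default 3.3).
#' @param regions optional label -> region map, see
#'   [conservedInsertionCount()].
#' @return One-row data.frame: `domain`, `avg_sc_<surface>` and
#'   `high_sc_<surface>` per surface, `ins_<region>` per region.
#' @export
summarizeConservation <- function(profile, surfaces = defaultSurfaces(),
                                  scCutoff = 1.7, insertionCutoff = 3.3,
                                  regions = NULL) {
  avgs <- vapply(surfaces, function(s) averageRegionSC(profile, s),
                 numeric(1))
  flags <- !is.na(avgs) & avgs >= scCutoff
  ins <- conservedInsertionCount(profile, regions, cutoff = insertionCutoff)
  ins <- ins[INSERTION_REGIONS]
  out <- data.frame(domain = profile@domainName)
  for (nm in names(avgs)) out[[paste0("avg_sc_", nm)]] <- avgs[[nm]]
  for (nm in names(avgs)) out[[paste0("high_sc_", nm)]] <- flags[[nm]]
  for (nm in names(ins)) out[[paste0("ins_", gsub("[ -]", "_", nm))]] <- ins[[nm]]
  out
}
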