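#' Read a SPOT binding-intensity table
#'
#' Expects a TSV whose first column is the peptide id, second the peptide
#' sequence, and remaining columns one domain each of normalised binding
#' intensities.
#'
#' @param path TSV file path.
#' @param species species name to record.
#' @return A [BindingMatrix-class].
#' @export
readBindingMatrix <- function(path, species) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("binding table needs id, sequence and >= 1 domain column")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  BindingMatrix(species, m, stats::setNames(as.character(df[[2L]]), ids))
}

#' Write a BindingMatrix as TSV
#' @param matrix a [BindingMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBindingMatrix <- function(matrix, path) {
  m <- matrix@intensities
  df <- data.frame(peptide = rownames(m),
                   sequence = unname(matrix@peptides[rownames(m)]),
                   m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default within-species paralog merge rules
#'
#' Domain paralogs whose binding columns are averaged into one before
#' fraction calculations: the four S. cerevisiae pairs (Lsb1/Lsb2,
#' Lsb3/Lsb4, Myo3/Myo5, Boi1/Boi2, taking a 28-domain panel to 24) plus
#' the multi-domain entries of the other assayed species, whose member
#' columns are expected under `_1`, `_2`, ... suffixes.
#'
#' @return data.frame with columns `species`, `merged_name`, `member`.
#' @export
defaultMergeRules <- function() {
  rbind(
    data.frame(species = "S.cerevisiae", merged_name = "Lsb1/Lsb2",
               member = c("Lsb1", "Lsb2")),
    data.frame(species = "S.cerevisiae", merged_name = "Lsb3/Lsb4",
               member = c("Lsb3", "Lsb4")),
    data.frame(species = "S.cerevisiae", merged_name = "Myo3/Myo5",
               member = c("Myo3", "Myo5")),
    data.frame(species = "S.cerevisiae", merged_name = "Boi1/Boi2",
               member = c("Boi1", "Boi2")),
    data.frame(species = "C.albicans", merged_name = "Abp1",
               member = c("Abp1_1", "Abp1_2")),
    data.frame(species = "C.albicans", merged_name = "Bem1a",
               member = c("Bem1a_1", "Bem1a_2")),
    data.frame(species = "C.albicans", merged_name = "Rvs167",
               member = c("Rvs167_1", "Rvs167_2")),
    data.frame(species = "A.gossypii", merged_name = "Bem1a",
               member = c("Bem1a_1", "Bem1a_2")),
    data.frame(species = "S.pombe", merged_name = "Hof1",
               member = c("Hof1_1", "Hof1_2", "Hof1_3"))
  )
}

#' Average within-species paralog columns
#'
#' Each merge rule replaces its member domain columns by their arithmetic
#' mean under the merged name, so closely related paralogs contribute a
#' single column to the binding-fraction denominator. Rules for other
#' species are ignored.
#'
#' @param matrix a [BindingMatrix-class].
#' @param rules data.frame (`species`, `merged_name`, `member`), e.g.
#'   [defaultMergeRules()].
#' @return A [BindingMatrix-class] with merged columns (order preserved:
#'   the merged column takes its first member's place).
#' @export
mergeParalogs <- function(matrix, rules) {
  sub <- rules[rules$species == matrix@species, , drop = FALSE]
  if (!nrow(sub)) return(matrix)
  m <- matrix@intensities
  for (merged in unique(sub$merged_name)) {
    members <- sub$member[sub$merged_name == merged]
    if (length(members) < 2L)
      stop("merge rule '", merged, "' needs at least 2 members")
    missing <- setdiff(members, colnames(m))
    if (length(missing))
      stop("merge member(s) not found for '", merged, "': ",
           paste(missing, collapse = ", "))
    avg <- rowMeans(m[, members, drop = FALSE])
    first <- match(members[1L], colnames(m))
    m[, first] <- avg
    colnames(m)[first] <- merged
    m <- m[, !colnames(m) %in% members[-1L], drop = FALSE]
  }
  BindingMatrix(matrix@species, m, matrix@peptides)
}

#' Partition peptides by total-intensity signal floor
#'
#' A peptide is retained only when its summed intensity over all domains
#' of the species reaches `minSum` (default 1000 units, inclusive);
#' weaker rows are excluded so small denominators cannot inflate binding
#' fractions.
#'
#' @param matrix a (merged) [BindingMatrix-class].
#' @param minSum minimum row sum (default 1000).
#' @return list with `retained` (a [BindingMatrix-class]) and `excluded`
#'   (data.frame `peptide`, `sum`, `reason`).
#' @export
sumFilter <- function(matrix, minSum = 1000) {
  sums <- rowSums(matrix@intensities)
  keep <- sums >= minSum
  excluded <- data.frame(peptide = rownames(matrix@intensities)[!keep],
                         sum = unname(sums[!keep]),
                         reason = rep(sprintf("intensity sum below %g", minSum),
                                      sum(!keep)))
  retained <- BindingMatrix(matrix@species,
                            matrix@intensities[keep, , drop = FALSE],
                            matrix@peptides[keep])
  list(retained = retained, excluded = excluded)
}

#' Binding fractions per peptide and domain
#'
#' For each retained peptide, the binding fraction to a domain is its
#' intensity there divided by its summed intensity over every domain
#' assayed in that species, so each peptide's fractions sum to one.
#'
#' @param matrix a merged [BindingMatrix-class].
#' @param minSum signal floor applied before the calculation (default
#'   1000); see [sumFilter()].
#' @return A [BindingFractionTable-class].
#' @export
bindingFraction <- function(matrix, minSum = 1000) {
  part <- sumFilter(matrix, minSum)
  m <- part$retained@intensities
  sums <- rowSums(m)
  if (any(sums <= 0))
    stop("zero-sum retained peptide row; raise minSum above 0")
  new("BindingFractionTable", species = matrix@species,
      fractions = m / sums, intensities = m, excluded = part$excluded)
}

#' Call specific domain-peptide interactions
#'
#' A peptide binds a domain specifically in a species when its binding
#' fraction there exceeds `cutoff` (strictly; the default 0.5 guarantees
#' at most one call per peptide and species, since fractions sum to one).
#'
#' @param table a [BindingFractionTable-class] or a list of them.
#' @param cutoff binding-fraction cutoff (default 0.5). Values below 0.5
#'   trigger a warning: per-peptide uniqueness is no longer guaranteed.
#' @return data.frame `species`, `peptide`, `domain`, `bf`.
#' @export
callSpecific <- function(table, cutoff = 0.5) {
  if (is.list(table))
    return(do.call(rbind, lapply(table, callSpecific, cutoff = cutoff)))
  if (cutoff < 0.5)
    warning("cutoff below 0.5: a peptide may be called specific for more ",
            "than one domain")
  f <- table@fractions
  hit <- which(f > cutoff, arr.ind = TRUE)
  out <- data.frame(species = rep(table@species, nrow(hit)),
                    peptide = rownames(f)[hit[, 1L]],
                    domain = colnames(f)[hit[, 2L]],
                    bf = f[hit])
  out[order(out$peptide, out$domain), , drop = FALSE]
}

# mean of a peptide-level statistic across the species tables where the
# domain was assayed and the peptide retained
.peptideMeans <- function(tables, domain, slot = c("fractions", "intensities")) {
  slot <- match.arg(slot)
  withData <- Filter(function(t) domain %in% colnames(slot(t, slot)), tables)
  if (!length(withData))
    stop("domain '", domain, "' absent from every species table")
  peps <- sort(unique(unlist(lapply(withData, function(t)
    rownames(slot(t, slot))))))
  vals <- vapply(peps, function(p) {
    v <- vapply(withData, function(t) {
      m <- slot(t, slot)
      if (p %in% rownames(m)) m[p, domain] else NA_real_
    }, numeric(1))
    mean(v, na.rm = TRUE)
  }, numeric(1))
  list(means = vals, withData = withData)
}

#' Per-domain binding-specificity summary
#'
#' Summarises one domain across species: the number of peptides specific
#' to it in at least one species (`n_specific_peptides`), the best peptide
#' (highest mean binding fraction across species with data; ties broken by
#' lexicographic peptide id), that mean (`bf_specific`), and a species
#' pair: in how many species the best peptide reaches a binding fraction
#' of at least 0.5, out of how many species both assayed the domain and
#' retained the best peptide.
#'
#' @param tables list of [BindingFractionTable-class], one per species.
#' @param domain domain name (post-merge).
#' @param cutoff specificity cutoff for the peptide count (default 0.5,
#'   strict, as in [callSpecific()]).
#' @return One-row data.frame: `domain`, `n_specific_peptides`,
#'   `best_peptide`, `bf_specific`, `n_species_specific`,
#'   `n_species_with_data`.
#' @export
summarizeDomain <- function(tables, domain, cutoff = 0.5) {
  pm <- .peptideMeans(tables, domain, "fractions")
  withData <- pm$withData
  nSpecific <- sum(vapply(names(pm$means), function(p) {
    any(vapply(withData, function(t) {
      f <- t@fractions
      p %in% rownames(f) && f[p, domain] > cutoff
    }, logical(1)))
  }, logical(1)))
  ord <- order(-pm$means, names(pm$means))
  best <- names(pm$means)[ord[1L]]
  bestBF <- vapply(withData, function(t) {
    f <- t@fractions
    if (best %in% rownames(f)) f[best, domain] else NA_real_
  }, numeric(1))
  data.frame(domain = domain,
             n_specific_peptides = nSpecific,
             best_peptide = best,
             bf_specific = mean(bestBF, na.rm = TRUE),
             n_species_specific = sum(bestBF >= 0.5, na.rm = TRUE),
             n_species_with_data = sum(!is.na(bestBF)))
}

#' Summarise every domain of a species set
#'
#' @param tables list of [BindingFractionTable-class].
#' @param cutoff see [summarizeDomain()].
#' @return data.frame, one row per domain occurring in any species.
#' @export
summarizeAllDomains <- function(tables, cutoff = 0.5) {
  domains <- sort(unique(unlist(lapply(tables, function(t)
    colnames(t@fractions)))))
  do.call(rbind, lapply(domains, function(d)
    summarizeDomain(tables, d, cutoff)))
}

#' Rank a domain's peptides by binding fraction or raw intensity
#'
#' Ranks descending by the chosen statistic averaged across the species
#' with data, ties broken by peptide id. Fraction- and intensity-based
#' ranks can disagree: a peptide bound promiscuously at high intensity
#' ranks high by intensity but low by fraction.
#'
#' @param tables list of [BindingFractionTable-class].
#' @param domain domain name.
#' @param by `"binding_fraction"` or `"intensity"`.
#' @return data.frame `peptide`, `statistic`, `rank`.
#' @export
rankPeptides <- function(tables, domain,
                         by = c("binding_fraction", "intensity")) {
  by <- match.arg(by)
  pm <- .peptideMeans(tables, domain,
                      if (by == "intensity") "intensities" else "fractions")
  ord <- order(-pm$means, names(pm$means))
  data.frame(peptide = names(pm$means)[ord],
             statistic = unname(pm$means[ord]),
             rank = seq_along(ord))
}
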