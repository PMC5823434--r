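## Synthetic families and binding matrices with planted ground truth.
## Every pipeline stage can be exercised end-to-end with known answers.

#' FamilySpec: parameters of a synthetic domain family
#'
#' Positions fall into three classes. Housekeeping positions keep one
#' equivalency group family-wide (conserved in both paralog and ortholog
#' alignments). Specificity positions draw an independent group per family
#' member, held within each member's orthologs (divergent across paralogs,
#' conserved within orthologs -- high SC). Variable positions churn in
#' both alignments. The default class map plants specificity on surface II
#' and housekeeping on surface I.
#'
#' @slot nParalogs family size (default 28).
#' @slot nOrthologs rows per ortholog alignment, including the reference
#'   (default 29).
#' @slot nPositions canonical positions (default 60).
#' @slot classMap character per position in
#'   `{housekeeping, specificity, variable}`.
#' @slot hkSwitch housekeeping group-switch probability, both alignments
#'   (default 0.02).
#' @slot specSwitch specificity group-switch probability within orthologs
#'   (default 0.05; paralog groups are drawn independently per member).
#' @slot varSwitch variable-position switch probability, both alignments
#'   (default 0.65).
#' @slot gapProb per-cell gap probability in non-reference ortholog rows
#'   (default 0.02).
#' @slot insertions data.frame (`region`, `count`, `conserved`) of
#'   ortholog-alignment insertions to plant; empty by default.
#' @slot seed RNG seed.
#' @export
setClass("FamilySpec",
  representation(nParalogs = "integer", nOrthologs = "integer",
                 nPositions = "integer", classMap = "character",
                 hkSwitch = "numeric", specSwitch = "numeric",
                 varSwitch = "numeric", gapProb = "numeric",
                 insertions = "data.frame", seed = "integer"))

setValidity("FamilySpec", function(object) {
  if (length(object@classMap) != object@nPositions)
    return("classMap must cover every position")
  if (!all(object@classMap %in% c("housekeeping", "specificity", "variable")))
    return("unknown position class")
  probs <- c(object@hkSwitch, object@specSwitch, object@varSwitch,
             object@gapProb)
  if (any(probs < 0 | probs > 1)) return("probabilities must lie in [0, 1]")
  if (nrow(object@insertions) &&
      !all(c("region", "count", "conserved") %in% names(object@insertions)))
    return("insertions needs columns region, count, conserved")
  TRUE
})

#' Construct a FamilySpec
#'
#' @param nParalogs,nOrthologs,nPositions,hkSwitch,specSwitch,varSwitch,gapProb,insertions,seed
#'   see [FamilySpec-class].
#' @param classMap per-position classes; default: housekeeping on SI,
#'   specificity on SII, variable elsewhere.
#' @return A [FamilySpec-class].
#' @export
familySpec <- function(nParalogs = 28L, nOrthologs = 29L, nPositions = 60L,
                       classMap = NULL, hkSwitch = 0.02, specSwitch = 0.05,
                       varSwitch = 0.65, gapProb = 0.02,
                       insertions = data.frame(region = character(0),
                                               count = integer(0),
                                               conserved = logical(0)),
                       seed = 0L) {
  if (is.null(classMap)) {
    classMap <- rep("variable", nPositions)
    surf <- defaultSurfaces()
    classMap[surf$SI[surf$SI <= nPositions]] <- "housekeeping"
    classMap[surf$SII[surf$SII <= nPositions]] <- "specificity"
  }
  new("FamilySpec", nParalogs = as.integer(nParalogs),
      nOrthologs = as.integer(nOrthologs),
      nPositions = as.integer(nPositions), classMap = classMap,
      hkSwitch = hkSwitch, specSwitch = specSwitch, varSwitch = varSwitch,
      gapProb = gapProb, insertions = insertions, seed = as.integer(seed))
}

# uniform residue within a group; groups indexed into scheme
.sampleResidue <- function(groupIdx, scheme) {
  g <- scheme[[groupIdx]]
  g[sample.int(length(g), 1L)]
}

.switchGroup <- function(groupIdx, k) {
  sample(setdiff(seq_len(k), groupIdx), 1L)
}

#' Generate a synthetic domain family
#'
#' Produces a paralog alignment (the family members' reference sequences,
#' emitted ungapped so canonical mapping is exact), one ortholog alignment
#' per member, and the planted position-class truth table. Deterministic
#' given the spec's seed (R's Mersenne-Twister RNG).
#'
#' @param spec a [FamilySpec-class].
#' @param scheme equivalency scheme.
#' @return list with `paralog` ([DomainAlignment-class]), `orthologs`
#'   (named list of [DomainAlignment-class]), `truth` (data.frame
#'   `position`, `class`) and `spec`.
#' @export
generateFamily <- function(spec = familySpec(),
                           scheme = defaultEquivalencyGroups()) {
  validObject(spec)
  validateScheme(scheme)
  set.seed(spec@seed)
  k <- length(scheme)
  nP <- spec@nParalogs; nO <- spec@nOrthologs; L <- spec@nPositions
  cls <- spec@classMap
  members <- sprintf("Dom%02d", seq_len(nP))

  baseGroup <- sample.int(k, L, replace = TRUE)   # hk + variable baseline
  # per-member group at each position
  memberGroup <- matrix(0L, nrow = nP, ncol = L)
  for (pos in seq_len(L)) {
    memberGroup[, pos] <- switch(cls[pos],
      housekeeping = ifelse(runif(nP) < spec@hkSwitch,
                            vapply(seq_len(nP), function(i)
                              .switchGroup(baseGroup[pos], k), integer(1)),
                            baseGroup[pos]),
      specificity = sample.int(k, nP, replace = TRUE),
      variable = ifelse(runif(nP) < spec@varSwitch,
                        sample.int(k, nP, replace = TRUE),
                        baseGroup[pos]))
  }
  refSeqs <- matrix("", nrow = nP, ncol = L)
  for (i in seq_len(nP)) for (pos in seq_len(L))
    refSeqs[i, pos] <- .sampleResidue(memberGroup[i, pos], scheme)

  paralog <- DomainAlignment(
    stats::setNames(apply(refSeqs, 1L, paste0, collapse = ""), members),
    species = rep("S.cerevisiae", nP), taxonGroup = rep(0L, nP),
    kind = "paralog")

  switchRate <- c(housekeeping = spec@hkSwitch,
                  specificity = spec@specSwitch,
                  variable = spec@varSwitch)
  orthologs <- stats::setNames(vector("list", nP), members)
  for (i in seq_len(nP)) {
    mat <- matrix("", nrow = nO, ncol = L)
    mat[1L, ] <- refSeqs[i, ]
    for (r in 2L:nO) {
      for (pos in seq_len(L)) {
        g <- memberGroup[i, pos]
        rate <- switchRate[[cls[pos]]]
        if (runif(1L) < rate) {
          g <- if (cls[pos] == "variable") sample.int(k, 1L)
               else .switchGroup(g, k)
        }
        mat[r, pos] <- .sampleResidue(g, scheme)
      }
      gap <- runif(L) < spec@gapProb
      mat[r, gap] <- "-"
    }
    mat <- .plantInsertions(mat, spec@insertions, scheme, k)
    ids <- c(sprintf("%s_S.cerevisiae_0", members[i]),
             sprintf("%s_sp%02d_%d", members[i], 2L:nO, (2L:nO - 2L) %% 8L))
    orthologs[[i]] <- DomainAlignment(
      stats::setNames(apply(mat, 1L, paste0, collapse = ""), ids),
      kind = "ortholog")
  }
  list(paralog = paralog, orthologs = orthologs,
       truth = data.frame(position = seq_len(L), class = cls), spec = spec)
}

# splice insertion columns into an ortholog alignment matrix: reference row
# gets gaps, other rows residues (one fixed group when conserved, a random
# group per cell otherwise); anchored at canonical loop centres
.plantInsertions <- function(mat, insertions, scheme, k) {
  if (!nrow(insertions)) return(mat)
  anchors <- c("N-terminus" = 0L, "RT-loop" = 15L, "N-Src loop" = 32L,
               "distal loop" = 45L, "C-terminus" = ncol(mat))
  # insert right-to-left so earlier anchors stay valid
  spec <- insertions[order(-anchors[insertions$region]), , drop = FALSE]
  for (r in seq_len(nrow(spec))) {
    anchor <- anchors[[spec$region[r]]]
    for (j in seq_len(spec$count[r])) {
      col <- character(nrow(mat))
      col[1L] <- "-"
      if (spec$conserved[r]) {
        g <- sample.int(k, 1L)
        col[-1L] <- vapply(seq_len(nrow(mat) - 1L),
                           function(x) .sampleResidue(g, scheme), character(1))
      } else {
        col[-1L] <- vapply(seq_len(nrow(mat) - 1L), function(x)
          .sampleResidue(sample.int(k, 1L), scheme), character(1))
      }
      at <- anchor + j - 1L
      mat <- cbind(mat[, seq_len(at), drop = FALSE], col,
                   if (at < ncol(mat)) mat[, (at + 1L):ncol(mat), drop = FALSE])
    }
  }
  unname(mat)
}

#' BindingSpec: parameters of synthetic SPOT binding matrices
#'
#' Emulates a peptide-array experiment over several species: a shared
#' peptide panel, a log-normal intensity noise floor, a subset of peptides
#' planted as specific binders of one domain each (the same target in
#' every species, at a binding-fraction level above the calling cutoff),
#' and a few low-signal peptides whose intensity sums fall below the
#' signal floor.
#'
#' @slot speciesNames species to simulate (default 4 fungal species).
#' @slot nPeptides peptide panel size (default 300).
#' @slot domains domain names shared by all species (default 24).
#' @slot nSpecific number of planted specific peptides (default 150).
#' @slot targetBF planted binding-fraction level (default 0.7).
#' @slot noiseMeanlog,noiseSdlog log-normal background intensity
#'   parameters (defaults `log(60)` and 1).
#' @slot nLowSignal peptides planted below the signal floor (default 10).
#' @slot seed RNG seed.
#' @export
setClass("BindingSpec",
  representation(speciesNames = "character", nPeptides = "integer",
                 domains = "character", nSpecific = "integer",
                 targetBF = "numeric", noiseMeanlog = "numeric",
                 noiseSdlog = "numeric", nLowSignal = "integer",
                 seed = "integer"))

setValidity("BindingSpec", function(object) {
  if (object@nSpecific + object@nLowSignal > object@nPeptides)
    return("planted peptides exceed the panel size")
  if (object@targetBF <= 0 || object@targetBF >= 1)
    return("targetBF must lie in (0, 1)")
  TRUE
})

#' Construct a BindingSpec
#' @param speciesNames,nPeptides,domains,nSpecific,targetBF,noiseMeanlog,noiseSdlog,nLowSignal,seed
#'   see [BindingSpec-class].
#' @return A [BindingSpec-class].
#' @export
bindingSpec <- function(speciesNames = c("S.cerevisiae", "C.albicans",
                                         "A.gossypii", "S.pombe"),
                        nPeptides = 300L,
                        domains = sprintf("Dom%02d", 1:24),
                        nSpecific = 150L, targetBF = 0.7,
                        noiseMeanlog = log(60), noiseSdlog = 1,
                        nLowSignal = 10L, seed = 0L) {
  new("BindingSpec", speciesNames = speciesNames,
      nPeptides = as.integer(nPeptides), domains = domains,
      nSpecific = as.integer(nSpecific), targetBF = targetBF,
      noiseMeanlog = noiseMeanlog, noiseSdlog = noiseSdlog,
      nLowSignal = as.integer(nLowSignal), seed = as.integer(seed))
}

#' Generate synthetic binding matrices with planted specific peptides
#'
#' Each planted peptide gets, in every species, an intensity to its target
#' domain chosen so that its binding fraction lands near `targetBF`
#' (+/- 5% jitter) over the log-normal noise floor; low-signal peptides
#' are scaled so their intensity sums fall below 1000 units. Deterministic
#' given the seed.
#'
#' @param spec a [BindingSpec-class].
#' @return list with `matrices` (named list of [BindingMatrix-class], one
#'   per species), `truth` (data.frame `peptide`, `domain`, `target_bf`)
#'   and `low_signal` (peptide ids planted below the signal floor).
#' @export
generateBinding <- function(spec = bindingSpec()) {
  validObject(spec)
  if (spec@targetBF <= 0.5)
    warning("planted target binding fraction <= 0.5 will not be callable ",
            "at the default cutoff")
  set.seed(spec@seed)
  nPep <- spec@nPeptides
  peps <- sprintf("pep%03d", seq_len(nPep))
  seqs <- stats::setNames(vapply(seq_len(nPep), function(i)
    paste0(sample(STANDARD_AA, 15L, replace = TRUE), collapse = ""),
    character(1)), peps)

  planted <- sample(peps, spec@nSpecific)
  targets <- stats::setNames(sample(spec@domains, spec@nSpecific,
                                    replace = TRUE), planted)
  lowSignal <- sample(setdiff(peps, planted), spec@nLowSignal)

  nDom <- length(spec@domains)
  matrices <- stats::setNames(vector("list", length(spec@speciesNames)),
                              spec@speciesNames)
  for (sp in spec@speciesNames) {
    m <- matrix(rlnorm(nPep * nDom, spec@noiseMeanlog, spec@noiseSdlog),
                nrow = nPep, dimnames = list(peps, spec@domains))
    for (p in planted) {
      d <- targets[[p]]
      others <- sum(m[p, colnames(m) != d])
      bf <- spec@targetBF * runif(1L, 0.95, 1.05)
      m[p, d] <- bf / (1 - bf) * others
    }
    for (p in lowSignal) {
      m[p, ] <- m[p, ] * runif(1L, 200, 900) / sum(m[p, ])
    }
    matrices[[sp]] <- BindingMatrix(sp, m, seqs)
  }
  list(matrices = matrices,
       truth = data.frame(peptide = planted, domain = unname(targets),
                          target_bf = spec@targetBF),
       low_signal = lowSignal)
}
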