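# Shared fixture builders; everything is generated in code at test time.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# independent entropy oracle: straight -sum(p log p) over table() counts,
# sharing no code with positionalEntropy()
oracleEntropy <- function(column, scheme = defaultEquivalencyGroups()) {
  groupOf <- function(ch) {
    for (nm in names(scheme)) if (ch %in% scheme[[nm]]) return(nm)
    NA_character_
  }
  g <- vapply(toupper(column), groupOf, character(1))
  g <- g[!is.na(g)]
  p <- as.numeric(table(g)) / length(g)
  exp(-sum(p * log(p)))
}

# rectangular toy alignment from raw sequence strings
toyAlignment <- function(seqs, ids = sprintf("row%d_%d", seq_along(seqs),
                                             seq_along(seqs)),
                         kind = "paralog") {
  DomainAlignment(stats::setNames(seqs, ids), kind = kind)
}

# n identical ungapped sequences of width w drawn from one group letter
uniformAlignment <- function(n = 5, w = 60, letter = "A") {
  toyAlignment(rep(strrep(letter, w), n))
}

writeFastaLines <- function(ids, seqs, path) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

# minimal binding matrix: intensities given as a named-dimnames matrix
toyBindingMatrix <- function(m, species = "S.cerevisiae") {
  peps <- stats::setNames(strrep("A", 15)[rep(1, nrow(m))], rownames(m))
  BindingMatrix(species, m, peps)
}
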