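test_that("uniform k-group columns give entropy k and conserved columns give 1", {
  firstLetters <- vapply(defaultEquivalencyGroups(), `[`, character(1), 1L)
  for (k in 1:6) {
    col <- rep(firstLetters[1:k], each = 12)
    expect_equal(positionalEntropy(col), k, tolerance = 1e-12)
  }
  expect_equal(positionalEntropy(rep("W", 29)), 1.0)   # single group
})

test_that("entropy matches an independent -sum(p log p) oracle to 1e-12", {
  set.seed(7)
  for (i in 1:1000) {
    col <- sample(AA20, 29, replace = TRUE)
    got <- positionalEntropy(col)
    want <- oracleEntropy(col)
    expect_lt(abs(got - want) / want, 1e-12)
  }
})

test_that("skewed group mixtures reproduce hand-computed values", {
  # counts 2:1 over two groups
  expect_equal(positionalEntropy(c("A", "A", "K"), gapThreshold = 0),
               exp(-(2/3 * log(2/3) + 1/3 * log(1/3))))
  expect_equal(positionalEntropy(c("A", "A", "K"), gapThreshold = 0),
               1.8899, tolerance = 1e-4)
  # 15:14 split of 29 rows over two groups
  col <- c(rep("A", 15), rep("K", 14))
  expect_equal(positionalEntropy(col),
               exp(-(15/29 * log(15/29) + 14/29 * log(14/29))))
  expect_equal(positionalEntropy(col), 1.9988, tolerance = 1e-4)
})

test_that("the 0.64 gap threshold admits 19 of 29 rows but not 18", {
  colOf <- function(nRes) c(rep("A", nRes), rep("-", 29 - nRes))
  expect_true(is.na(positionalEntropy(colOf(18))))     # 18/29 < 0.64
  expect_false(is.na(positionalEntropy(colOf(19))))    # 19/29 >= 0.64
  defined <- vapply(1:29, function(n) !is.na(positionalEntropy(colOf(n))),
                    logical(1))
  expect_equal(min(which(defined)), 19L)
  expect_true(is.na(positionalEntropy(rep("-", 29)))) # all gaps
})

test_that("ambiguity letters are excluded from fractions and count as gaps", {
  expect_equal(positionalEntropy(c(rep("A", 19), rep("X", 10))), 1.0)
  expect_true(is.na(positionalEntropy(c(rep("A", 18), rep("X", 11)))))
})

test_that("entropy lies in [1, k] and hits k only at equal frequencies", {
  set.seed(11)
  for (i in 1:200) {
    col <- sample(AA20, 29, replace = TRUE)
    e <- positionalEntropy(col)
    expect_gte(e, 1); expect_lte(e, 6 + 1e-12)
  }
  # merging two equal-size single-group columns gives exactly 2
  expect_equal(positionalEntropy(c(rep("A", 10), rep("D", 10))), 2,
               tolerance = 1e-12)
})

test_that("alignment profiles are row-permutation invariant and labelled", {
  set.seed(3)
  seqs <- vapply(1:20, function(i)
    paste0(sample(c(AA20, "-"), 40, replace = TRUE), collapse = ""),
    character(1))
  aln <- toyAlignment(seqs)
  prof <- profileAlignment(aln)
  shuffled <- DomainAlignment(sample(aln@seqs), kind = "paralog")
  prof2 <- profileAlignment(shuffled)
  expect_equal(prof$entropy, prof2$entropy)
  expect_equal(prof$nongap_fraction, prof2$nongap_fraction)

  ident <- uniformAlignment(10, 12)
  expect_true(all(profileAlignment(ident)$entropy == 1))
  allGap <- toyAlignment(c("A-", "C-", "D-"))
  p <- profileAlignment(allGap)
  expect_true(is.na(p$entropy[2]))
  expect_equal(p$nongap_fraction[2], 0)
})

test_that("SC is the paralog/ortholog entropy ratio with NA propagation", {
  mkProf <- function(entropies) {
    data.frame(label = as.character(seq_along(entropies)),
               entropy = entropies,
               nongap_fraction = 1)
  }
  pe <- rep(1, 60); oe <- rep(1, 60)
  pe[14] <- 4.5; oe[14] <- 1.2      # the worked Abp1-style position
  pe[20] <- 1.0; oe[20] <- 2.0
  pe[30] <- NA                      # paralog side fails the gap threshold
  prof <- scProfile(mkProf(pe), mkProf(oe), "Abp1")
  pos <- scPositions(prof)
  expect_equal(pos$sc[14], 3.75)
  # published tables divide unrounded entropies and print one decimal; the
  # ratio of the printed entropies must land within rounding slack of that
  expect_lte(abs(pos$sc[14] - 3.7), 0.06)
  expect_equal(pos$sc_display[14], round(pos$sc[14], 1))
  expect_equal(pos$sc[20], 0.5)
  expect_equal(pos$sc[1], 1.0)
  expect_true(is.na(pos$sc[30]))
  expect_s4_class(prof, "ConservationProfile")
})

test_that("region averages skip undefined SC and drive the 1.7 flag", {
  mkProf <- function(sc) {
    pos <- data.frame(position = 1:60, paralog_entropy = sc,
                      ortholog_entropy = rep(1, 60), sc = sc,
                      sc_display = round(sc, 1), nongap_fraction = 1)
    new("ConservationProfile", domainName = "toy", positions = pos,
        insertions = data.frame(label = character(0),
                                ortholog_entropy = numeric(0),
                                nongap_fraction = numeric(0)),
        gapThreshold = 0.64)
  }
  sc <- rep(2, 60)
  expect_equal(averageRegionSC(mkProf(sc), defaultSurfaces()$SII), 2.0)

  sc2 <- rep(NA_real_, 60); sc2[1:3] <- c(1, 2, 3)
  expect_equal(averageRegionSC(mkProf(sc2), 1:4), 2.0)  # NA excluded
  expect_true(is.na(averageRegionSC(mkProf(sc2), 10:12)))
  expect_error(averageRegionSC(mkProf(sc), integer(0)), "empty")

  atCut <- mkProf(rep(1.7, 60))
  s <- summarizeConservation(atCut)
  expect_true(s$high_sc_SII)        # >= 1.7 counts as high
  below <- summarizeConservation(mkProf(rep(1.69, 60)))
  expect_false(below$high_sc_SII)
})

test_that("family position averages pool defined SC across domains", {
  mk <- function(name, sc32) {
    pos <- data.frame(position = 1:60, paralog_entropy = 1,
                      ortholog_entropy = 1, sc = 1,
                      sc_display = 1, nongap_fraction = 1)
    pos$sc[32] <- sc32
    new("ConservationProfile", domainName = name, positions = pos,
        insertions = data.frame(), gapThreshold = 0.64)
  }
  one <- familyPositionAverage(list(a = mk("a", 2)))
  expect_equal(unname(one["32"]), 2)
  two <- familyPositionAverage(list(a = mk("a", 2), b = mk("b", 4)))
  expect_equal(unname(two["32"]), 3)
  m <- familySCMatrix(list(a = mk("a", 2), b = mk("b", 4)))
  expect_equal(dim(m), c(2L, 60L))
})

test_that("conserved insertions are counted per region at the 3.3 cutoff", {
  mkIns <- function(labels, entropies) {
    new("ConservationProfile", domainName = "toy",
        positions = data.frame(position = 1:60, paralog_entropy = 1,
                               ortholog_entropy = 1, sc = 1,
                               sc_display = 1, nongap_fraction = 1),
        insertions = data.frame(label = labels,
                                ortholog_entropy = entropies,
                                nongap_fraction = rep(1, length(labels))),
        gapThreshold = 0.64)
  }
  none <- mkIns(character(0), numeric(0))
  expect_true(all(conservedInsertionCount(none) == 0L))

  # two RT-loop insertions, entropies 1.5 and 3.4 -> only one conserved
  rt <- mkIns(c("15a", "15b"), c(1.5, 3.4))
  cnt <- conservedInsertionCount(rt)
  expect_equal(unname(cnt["RT-loop"]), 1L)

  # boundary: 3.3 itself counts
  expect_equal(unname(conservedInsertionCount(
    mkIns("15a", 3.3))["RT-loop"]), 1L)

  expect_error(conservedInsertionCount(
    rt, regions = c("15a" = "RT-loop", "99z" = "RT-loop")), "unknown")
  expect_error(conservedInsertionCount(
    rt, regions = c("15a" = "RT-loop")), "cover")
})

test_that("fully conserved planted RT-loop insertions are both counted", {
  spec <- familySpec(nParalogs = 4, nOrthologs = 20, gapProb = 0,
                     insertions = data.frame(region = "RT-loop", count = 2,
                                             conserved = TRUE),
                     seed = 5)
  fam <- generateFamily(spec)
  o <- fam$orthologs[[1]]
  map <- buildCanonicalMap(o, alignmentIds(o)[1], c(1, 60))
  expect_true(all(c("15a", "15b") %in% mapLabels(map)))
  pmap <- buildCanonicalMap(fam$paralog, "Dom01", c(1, 60))
  prof <- scProfile(profileAlignment(fam$paralog, pmap),
                    profileAlignment(o, map), "Dom01")
  cnt <- conservedInsertionCount(prof)
  expect_equal(unname(cnt["RT-loop"]), 2L)
})
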