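yeastPanel <- function() {
  doms <- c("Abp1", "Bbc1", "Bem1a", "Bem1b", "Boi1", "Boi2", "Bud14",
            "Bzz1a", "Bzz1b", "Cdc25", "Cyk2", "Cyk3", "Fus1", "Hse1",
            "Lsb1", "Lsb2", "Lsb3", "Lsb4", "Myo3", "Myo5", "Nbp2",
            "Pex13", "Rvs167", "Sdc25", "Sho1", "Sla1a", "Sla1b", "Sla1c")
  set.seed(1)
  m <- matrix(runif(10 * 28, 10, 100), nrow = 10,
              dimnames = list(sprintf("pep%02d", 1:10), doms))
  toyBindingMatrix(m)
}

test_that("default merge rules average the four yeast pairs: 28 -> 24 domains", {
  bm <- yeastPanel()
  merged <- mergeParalogs(bm, defaultMergeRules())
  expect_equal(ncol(bindingIntensities(merged)), 24L)
  expect_true(all(c("Lsb1/Lsb2", "Lsb3/Lsb4", "Myo3/Myo5", "Boi1/Boi2")
                  %in% bindingDomains(merged)))
  expect_false(any(c("Lsb1", "Myo5") %in% bindingDomains(merged)))
  # merged column is the arithmetic mean of its members
  expect_equal(bindingIntensities(merged)[, "Myo3/Myo5"],
               rowMeans(bindingIntensities(bm)[, c("Myo3", "Myo5")]))
})

test_that("merging pairs 100/300 gives 200; missing members are named errors", {
  m <- matrix(c(100, 300, 50), nrow = 1,
              dimnames = list("p1", c("A1", "A2", "B")))
  m <- rbind(m, m); rownames(m) <- c("p1", "p2")
  bm <- toyBindingMatrix(m)
  rules <- data.frame(species = "S.cerevisiae", merged_name = "A",
                      member = c("A1", "A2"))
  merged <- mergeParalogs(bm, rules)
  expect_equal(unname(bindingIntensities(merged)["p1", "A"]), 200)
  # no applicable rules -> unchanged
  expect_identical(bindingIntensities(
    mergeParalogs(bm, rules[0, ])), bindingIntensities(bm))
  badRules <- data.frame(species = "S.cerevisiae", merged_name = "A",
                         member = c("A1", "Axx"))
  expect_error(mergeParalogs(bm, badRules), "Axx")
})

test_that("the 1000-unit sum filter is inclusive at the boundary", {
  m <- rbind(low = rep(999 / 3, 3), edge = rep(1000 / 3, 3),
             zero = rep(0, 3), high = rep(1000, 3))
  colnames(m) <- c("D1", "D2", "D3")
  bm <- toyBindingMatrix(m)
  part <- sumFilter(bm)
  expect_setequal(rownames(bindingIntensities(part$retained)),
                  c("edge", "high"))
  expect_setequal(part$excluded$peptide, c("low", "zero"))
  expect_equal(part$excluded$sum[part$excluded$peptide == "low"], 999)
})

test_that("binding fractions normalise each retained row to sum 1", {
  m <- rbind(single = c(2000, 0, 0),
             uniform = rep(1000, 3),
             mixed = c(600, 400, 0) * 2)
  colnames(m) <- c("D1", "D2", "D3")
  bft <- bindingFraction(toyBindingMatrix(m))
  f <- bindingFractions(bft)
  expect_equal(unname(f["single", ]), c(1, 0, 0))
  expect_equal(unname(f["uniform", ]), rep(1 / 3, 3))
  expect_equal(unname(f["mixed", ]), c(0.6, 0.4, 0))
  expect_true(all(abs(rowSums(f) - 1) < 1e-9))
})

test_that("fractions, calls and summaries are scale invariant", {
  set.seed(8)
  m <- matrix(rlnorm(50 * 8, log(80), 1), nrow = 50,
              dimnames = list(sprintf("p%02d", 1:50), paste0("D", 1:8)))
  m[1, 1] <- 20 * sum(m[1, -1])
  bm1 <- toyBindingMatrix(m)
  bm2 <- toyBindingMatrix(m * 7.3)
  b1 <- bindingFraction(bm1, minSum = 1000)
  b2 <- bindingFraction(bm2, minSum = 1000 * 7.3)  # floor in scaled units
  expect_equal(bindingFractions(b1), bindingFractions(b2))
  expect_equal(callSpecific(b1)[, c("peptide", "domain")],
               callSpecific(b2)[, c("peptide", "domain")])
  expect_equal(summarizeDomain(list(b1), "D1")$bf_specific,
               summarizeDomain(list(b2), "D1")$bf_specific)
})

test_that("merging identical paralog columns leaves other domains' BF unchanged", {
  set.seed(4)
  m <- matrix(rlnorm(20 * 5, log(400), 0.5), nrow = 20,
              dimnames = list(sprintf("p%02d", 1:20),
                              c("A1", "A2", "B", "C", "D")))
  m[, "A2"] <- m[, "A1"]
  bm <- toyBindingMatrix(m)
  rules <- data.frame(species = "S.cerevisiae", merged_name = "A",
                      member = c("A1", "A2"))
  fBefore <- bindingFractions(bindingFraction(bm, minSum = 0.001))
  fAfter <- bindingFractions(bindingFraction(mergeParalogs(bm, rules),
                                             minSum = 0.001))
  for (d in c("B", "C", "D")) {
    # denominators shrink by the duplicated column; relative BF among the
    # remaining domains is preserved
    ratioBefore <- fBefore[, d] / rowSums(fBefore[, c("B", "C", "D")])
    ratioAfter <- fAfter[, d] / rowSums(fAfter[, c("B", "C", "D")])
    expect_equal(ratioBefore, ratioAfter)
  }
})

test_that("specific calls are strict at 0.5 and unique per peptide/species", {
  m <- rbind(exact = c(500, 500), above = c(600, 400),
             uniform = c(500.0001, 499.9999))
  colnames(m) <- c("D1", "D2")
  bft <- bindingFraction(toyBindingMatrix(m))
  calls <- callSpecific(bft)
  expect_false("exact" %in% calls$peptide)     # 0.5 is not > 0.5
  expect_true("above" %in% calls$peptide)
  expect_lte(max(table(calls$peptide)), 1L)
  expect_warning(callSpecific(bft, cutoff = 0.3), "0.5")
})

test_that("domain summaries count specific peptides and species support", {
  mk <- function(species, m) {
    peps <- stats::setNames(rep(strrep("A", 15), nrow(m)), rownames(m))
    bindingFraction(BindingMatrix(species, m, peps), minSum = 1)
  }
  m1 <- rbind(p1 = c(900, 50, 50), p2 = c(100, 800, 100),
              p3 = c(400, 300, 300))
  colnames(m1) <- c("X", "Y", "Z")
  t1 <- mk("sp1", m1)
  s <- summarizeDomain(list(t1), "X")
  expect_equal(s$n_specific_peptides, 1L)
  expect_equal(s$best_peptide, "p1")
  expect_equal(s$bf_specific, 0.9)
  expect_equal(s$n_species_specific, 1L)
  expect_equal(s$n_species_with_data, 1L)

  # domain with no specific peptide anywhere
  sZ <- summarizeDomain(list(t1), "Z")
  expect_equal(sZ$n_specific_peptides, 0L)
  expect_lt(sZ$bf_specific, 0.5)
  expect_equal(sZ$n_species_specific, 0L)

  expect_error(summarizeDomain(list(t1), "Q"), "absent")

  # missing species data: absent column drops that species from the counts
  m2 <- m1[, c("Y", "Z")]
  t2 <- mk("sp2", m2)
  s2 <- summarizeDomain(list(t1, t2), "X")
  expect_equal(s2$n_species_with_data, 1L)
})

test_that("fraction and intensity ranks can disagree", {
  # A: high fraction, modest intensity; B: low fraction, high intensity
  m <- rbind(A = c(1600, 200, 200), B = c(5000, 6000, 6000),
             C = c(400, 400, 400))
  colnames(m) <- c("T", "U", "V")
  bft <- bindingFraction(toyBindingMatrix(m))
  byBF <- rankPeptides(list(bft), "T", by = "binding_fraction")
  byBI <- rankPeptides(list(bft), "T", by = "intensity")
  expect_equal(byBF$peptide[1], "A")
  expect_equal(byBI$peptide[1], "B")
  # single peptide ranks first either way; ties fall back to id order
  oneM <- rbind(A = c(700, 300), B = c(700, 300), Z = c(300, 700)) * 2
  colnames(oneM) <- c("T", "U")
  one <- bindingFraction(toyBindingMatrix(oneM), minSum = 1)
  r <- rankPeptides(list(one), colnames(bindingFractions(one))[1])
  expect_equal(r$peptide, c("A", "B", "Z"))
})

test_that("planted specific peptides are recovered with few false calls", {
  gen <- generateBinding(bindingSpec(seed = 6))
  tables <- lapply(gen$matrices, bindingFraction)
  calls <- callSpecific(tables)
  truth <- gen$truth
  key <- function(df) paste(df$peptide, df$domain)
  recovered <- vapply(names(tables), function(sp) {
    mean(key(truth) %in% key(calls[calls$species == sp, ]))
  }, numeric(1))
  expect_true(all(recovered >= 0.95))
  falseCalls <- calls[!key(calls) %in% key(truth), ]
  expect_lte(nrow(falseCalls), 0.05 * nrow(calls))
  # planted low-signal peptides are excluded by the sum filter
  for (t in tables)
    expect_true(all(gen$low_signal %in% excludedPeptides(t)$peptide))
})
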