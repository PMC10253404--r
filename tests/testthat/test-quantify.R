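mkPep <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(peptide_id = r[[1]], peptide_sequence = "PEPK",
               protein_accession = r[[2]], sample_id = r[[3]],
               intensity = as.numeric(r[[4]]), stringsAsFactors = FALSE)))
}

test_that("protein abundance is the sum of unique peptide intensities", {
  design <- tinyDesign()
  s1 <- design$sample_id[1]; s2 <- design$sample_id[2]
  pep <- mkPep(list("p1", "P1", s1, 100), list("p2", "P1", s1, 200),
               list("p3", "P1;P2", s1, 999), # shared: contributes to neither
               list("p4", "P2", s2, 50))
  ce <- aggregateAbundance(pep, design)
  ab <- abundance(ce)
  expect_equal(ab["P1", s1], 300)
  expect_true(is.na(ab["P2", s1]))   # missing, not zero
  expect_equal(ab["P2", s2], 50)
  expect_equal(peptideCounts(ce)["P1", s1], 2L)
  expect_equal(peptideCounts(ce)["P2", s1], 0L)
  # the shared peptide is excluded everywhere
  expect_false("P1;P2" %in% rownames(ab))
  expect_equal(ab["P1", s1], 300) # unchanged by the shared peptide
})

test_that("aggregation is permutation-invariant and validates accessions", {
  design <- tinyDesign()
  s1 <- design$sample_id[1]
  pep <- mkPep(list("p1", "P1", s1, 10), list("p2", "P2", s1, 20),
               list("p3", "P1", s1, 5))
  shuffled <- pep[c(3, 1, 2), ]
  expect_equal(abundance(aggregateAbundance(pep, design)),
               abundance(aggregateAbundance(shuffled, design)))
  expect_error(aggregateAbundance(pep, design, catalog = c("P1")), "P2")
  expect_error(aggregateAbundance(transform(pep, intensity = -1), design),
               "non-negative")
})

test_that("normalization equalizes column totals and preserves ratios", {
  design <- tinyDesign()
  ab <- matrix(c(800, 200, NA,
                 1500, 500, NA,
                 10, 20, 30,
                 100, 100, 100),
               nrow = 3, dimnames = list(c("P1", "P2", "P3"),
                                         design$sample_id))
  ce <- ceFromMatrix(ab, design)
  norm <- normalizeAbundance(ce)
  nab <- abundance(norm)
  totals <- colSums(nab, na.rm = TRUE)
  expect_equal(max(abs(totals - mean(colSums(ab, na.rm = TRUE)))), 0,
               tolerance = 1e-9)
  # within-sample ratios preserved
  expect_equal(nab["P1", 1] / nab["P2", 1], ab["P1", 1] / ab["P2", 1])
  expect_true(isNormalized(norm))

  # idempotence
  twice <- normalizeAbundance(norm)
  expect_equal(abundance(twice), nab, tolerance = 1e-12)

  # explicit two-sample example: totals 1000 and 2000 -> both 1500
  d2 <- captureDesign(probes = "Q8", nReplicates = 1)
  ab2 <- matrix(c(1000, 2000), 1, dimnames = list("P1", d2$sample_id))
  n2 <- abundance(normalizeAbundance(ceFromMatrix(ab2, d2)))
  expect_equal(unname(n2[1, ]), c(1500, 1500))
})

test_that("normalization rejects all-missing samples", {
  design <- tinyDesign()
  ab <- matrix(c(1, NA, 1, NA, 1, NA, 1, NA), 2,
               dimnames = list(c("P1", "P2"), design$sample_id))
  ab[, 2] <- NA
  expect_error(normalizeAbundance(ceFromMatrix(ab, design)),
               design$sample_id[2])
})

test_that("minimum-peptide filter uses the maximum per-sample count", {
  design <- tinyDesign()
  s <- design$sample_id
  pep <- rbind(
    mkPep(list("a1", "ONE", s[1], 10)),                      # 1 peptide only
    mkPep(list("b1", "BURST", s[2], 10), list("b2", "BURST", s[2], 10),
          list("b3", "BURST", s[2], 10)),                    # 3 in one sample
    mkPep(list("c1", "TWO", s[1], 10), list("c2", "TWO", s[1], 10))
  )
  ce <- aggregateAbundance(pep, design)
  expect_setequal(rownames(filterMinPeptides(ce, 2)), c("BURST", "TWO"))
  expect_setequal(rownames(filterMinPeptides(ce, 1)), rownames(ce))
  expect_error(filterMinPeptides(ce, 0), ">= 1")
})

test_that("group ratios handle absence as flags, never as infinities", {
  design <- tinyDesign()
  cap <- design$sample_id[design$probe == "Q8"]
  ctl <- design$sample_id[design$probe == "none"]
  ab <- matrix(c(400, NA,  10,
                 400, NA,  10,
                 100, 5,   NA,
                 100, 5,   NA),
               nrow = 3, dimnames = list(c("RATIO4", "ABSNUM", "ABSDEN"),
                                         c(cap, ctl)))
  ce <- ceFromMatrix(ab, design)
  rat <- groupRatio(ce, cap, ctl)
  expect_equal(rat$r[rat$accession == "RATIO4"], 4)
  expect_equal(rat$flag[rat$accession == "ABSNUM"], "absent_in_numerator")
  expect_equal(rat$flag[rat$accession == "ABSDEN"], "absent_in_denominator")
  expect_true(all(is.na(rat$r[rat$flag != "ok"])))

  # reversed contrast gives reciprocal ratios for doubly-observed proteins
  rev <- groupRatio(ce, ctl, cap)
  both <- rat$flag == "ok" & rev$flag == "ok"
  expect_equal(rat$r[both] * rev$r[both], rep(1, sum(both)))

  expect_error(groupRatio(ce, cap, cap), "disjoint")
})

test_that("ANOVA p-values match the sum-of-squares oracle", {
  design <- captureDesign(probes = "Q8", nReplicates = 3)
  cap <- design$sample_id[design$probe == "Q8"]
  ctl <- design$sample_id[design$probe == "none"]
  # log2 abundances {10,12,11} vs {5,6,7}: hand-derived F = 37.5, and
  # p = pf(37.5, 1, 4, lower = FALSE) = 0.0036022326
  ab <- matrix(2^c(10, 12, 11, 5, 6, 7), 1,
               dimnames = list("P1", c(cap, ctl)))
  p <- anovaPvalue(ceFromMatrix(ab, design), list(cap, ctl))
  expect_equal(unname(p), 0.0036022326, tolerance = 1e-8)
  expect_equal(unname(p), anovaOracle(list(c(10, 12, 11), c(5, 6, 7))),
               tolerance = 1e-12)

  # randomized tables against the oracle
  set.seed(101)
  for (i in 1:25) {
    vals <- rnorm(6, mean = 10)
    abi <- matrix(2^vals, 1, dimnames = list("P1", c(cap, ctl)))
    pi <- anovaPvalue(ceFromMatrix(abi, design), list(cap, ctl))
    expect_equal(unname(pi), anovaOracle(list(vals[1:3], vals[4:6])),
                 tolerance = 1e-10)
  }
})

test_that("two-group ANOVA equals the pooled-variance t-test (F = t^2)", {
  design <- captureDesign(probes = "Q8", nReplicates = 3)
  cap <- design$sample_id[design$probe == "Q8"]
  ctl <- design$sample_id[design$probe == "none"]
  set.seed(77)
  for (i in 1:10) {
    vals <- rnorm(6, 8, 2)
    abi <- matrix(2^vals, 1, dimnames = list("P1", c(cap, ctl)))
    pA <- anovaPvalue(ceFromMatrix(abi, design), list(cap, ctl))
    pT <- t.test(vals[1:3], vals[4:6], var.equal = TRUE)$p.value
    expect_equal(unname(pA), pT, tolerance = 1e-12)
  }
})

test_that("degenerate and under-observed proteins yield undefined p", {
  design <- captureDesign(probes = "Q8", nReplicates = 3)
  cap <- design$sample_id[design$probe == "Q8"]
  ctl <- design$sample_id[design$probe == "none"]
  ab <- matrix(c(8, 8, 8, 2, 2, 2,      # zero variance in both groups
                 8, 9, NA, 2, NA, NA),  # control group has 1 observation
               nrow = 2, byrow = TRUE,
               dimnames = list(c("CONST", "SPARSE"), c(cap, ctl)))
  p <- anovaPvalue(ceFromMatrix(ab, design), list(cap, ctl))
  expect_true(is.na(p[["CONST"]]))
  expect_true(is.na(p[["SPARSE"]]))
  expect_error(anovaPvalue(ceFromMatrix(ab, design), list(cap)), "two")
})
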