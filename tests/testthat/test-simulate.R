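test_that("ground truth respects binder and redundancy rates and is seed-deterministic", {
  cfg <- simulationConfig(nProteins = 100, binderFraction = 0.1,
                          redundancyRate = 0.2, seed = 7)
  truth <- generateGroundTruth(cfg)
  cat100 <- truthCatalog(truth)
  expect_equal(sum(cat100$is_binder), 10)
  expect_equal(nrow(duplicateMap(truth)), 20)
  expect_false(anyDuplicated(duplicateMap(truth)$duplicate_accession) > 0)
  expect_true(all(duplicateMap(truth)$canonical_accession %in% cat100$accession))

  truth2 <- generateGroundTruth(cfg)
  expect_identical(truthCatalog(truth2), cat100)
  expect_identical(querySequence(truth2), querySequence(truth))

  truth3 <- generateGroundTruth(simulationConfig(nProteins = 100, seed = 8))
  expect_false(identical(truthCatalog(truth3)$sequence, cat100$sequence))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(simulationConfig(binderFraction = 1.5), "binderFraction")
  expect_error(simulationConfig(enrichmentFold = 1), "enrichmentFold")
  expect_error(simulationConfig(nReplicates = 1), "nReplicates")
  expect_error(simulationConfig(intensityScale = 0), "intensityScale")
  expect_error(simulationConfig(methodNEfficiency = 0), "methodNEfficiency")
})

test_that("similarity tiers exist among binders and non-binders", {
  truth <- generateGroundTruth(simulationConfig(nProteins = 80, seed = 3))
  cat80 <- truthCatalog(truth)
  for (tier in c(0.9, 0.6, 0.3)) {
    expect_equal(sum(cat80$is_binder & cat80$identity_to_query %in% tier), 2)
    expect_equal(sum(!cat80$is_binder & cat80$identity_to_query %in% tier), 2)
  }
})

test_that("peptide report reflects the capture design multiplicatively", {
  cfg <- simulationConfig(nProteins = 40, probeAffinity = c(Q8 = 1),
                          cvReplicate = 1e-9, detectionMidpoint = -Inf,
                          seed = 21)
  truth <- generateGroundTruth(cfg)
  design <- captureDesign(probes = "Q8", nReplicates = 2)
  rep <- simulatePeptideReport(truth, design, cfg)

  # no missingness when the detection midpoint is -Inf
  expect_equal(nrow(rep),
               length(unique(rep$peptide_id)) * nrow(design))

  # with near-zero replicate noise, binder capture/control ratio is exactly
  # the enrichment fold x affinity; non-binder ratio is 1
  wide <- reshape(rep[, c("peptide_id", "protein_accession", "sample_id", "intensity")],
                  idvar = c("peptide_id", "protein_accession"),
                  timevar = "sample_id", direction = "wide")
  capCol <- paste0("intensity.", design$sample_id[design$probe == "Q8"][1])
  ctlCol <- paste0("intensity.", design$sample_id[design$probe == "none"][1])
  ratio <- wide[[capCol]] / wide[[ctlCol]]
  isB <- truthCatalog(truth)$is_binder[
    match(wide$protein_accession, truthCatalog(truth)$accession)]
  expect_equal(ratio[isB], rep(16, sum(isB)), tolerance = 1e-6)
  expect_equal(ratio[!isB], rep(1, sum(!isB)), tolerance = 1e-6)
})

test_that("report errors on probes without configured affinity", {
  truth <- generateGroundTruth(simulationConfig(nProteins = 10, seed = 1))
  design <- captureDesign(probes = "ZZ9")
  expect_error(simulatePeptideReport(truth, design), "ZZ9")
})

test_that("mean realized binder log2 ratio matches the analytic expectation", {
  # affinity 1 probe, no censoring: E[log2(capture/control)] = log2(16)
  ratios <- vapply(1:10, function(seed) {
    cfg <- simulationConfig(nProteins = 120, probeAffinity = c(Q8 = 1),
                            detectionMidpoint = -Inf, seed = seed)
    truth <- generateGroundTruth(cfg)
    design <- captureDesign(probes = "Q8")
    ce <- aggregateAbundance(simulatePeptideReport(truth, design, cfg), design)
    rat <- groupRatio(ce, design$sample_id[design$probe == "Q8"],
                      design$sample_id[design$probe == "none"])
    binders <- truthCatalog(truth)$accession[truthCatalog(truth)$is_binder]
    mean(log2(rat$r[rat$accession %in% binders]))
  }, numeric(1))
  expect_equal(mean(ratios), log2(16), tolerance = 0.05)
})

test_that("missingness is monotone non-increasing in intensity", {
  cfg <- simulationConfig(nProteins = 200, seed = 5)
  truth <- generateGroundTruth(cfg)
  design <- captureDesign(probes = "Q8")
  full <- simulatePeptideReport(truth, design,
                                simulationConfig(nProteins = 200, seed = 5,
                                                 detectionMidpoint = -Inf))
  kept <- simulatePeptideReport(truth, design, cfg)
  obs <- paste(kept$peptide_id, kept$sample_id) # survivors
  full$detected <- paste(full$peptide_id, full$sample_id) %in% obs
  # empirical detection rate must rise with intensity decile
  dec <- cut(log(full$intensity), quantile(log(full$intensity), 0:10 / 10),
             include.lowest = TRUE, labels = FALSE)
  rate <- tapply(full$detected, dec, mean)
  expect_true(all(diff(rate) >= -0.02)) # non-decreasing up to sampling noise
  expect_gt(rate[10], rate[1])
})

test_that("fixture bundle round-trips and FASTA honours the redundant variant", {
  cfg <- simulationConfig(nProteins = 50, redundancyRate = 0.2, seed = 9)
  truth <- generateGroundTruth(cfg)
  design <- captureDesign(probes = c("Q8", "Q6"))
  rep <- simulatePeptideReport(truth, design, cfg)
  dir <- withr::local_tempdir()
  paths <- writeFixtureBundle(truth, rep, design, dir)

  back <- readPeptideReport(paths[["report"]])
  expect_equal(back[, names(rep)], rep, tolerance = 1e-12)
  expect_equal(readDesign(paths[["design"]]), design)
  hm <- readHomologueMap(paths[["homologues"]])
  expect_true(all(truthCatalog(truth)$accession %in% hm$local_accession))

  fa <- readProteinFasta(paths[["fasta"]])
  faRed <- readProteinFasta(paths[["fasta_redundant"]])
  expect_length(fa, 50)
  expect_length(faRed, 60) # n x (1 + redundancy_rate)
  expect_identical(unname(faRed[duplicateMap(truth)$duplicate_accession[1]]),
                   unname(fa[duplicateMap(truth)$canonical_accession[1]]))
})

test_that("an empty truth writes valid header-only files", {
  cfg <- simulationConfig(nProteins = 0, seed = 2)
  truth <- generateGroundTruth(cfg)
  design <- captureDesign(probes = "Q8")
  rep <- simulatePeptideReport(truth, design, cfg)
  expect_equal(nrow(rep), 0)
  dir <- withr::local_tempdir()
  paths <- writeFixtureBundle(truth, rep, design, dir)
  expect_warning(back <- readPeptideReport(paths[["report"]]), "empty")
  expect_equal(nrow(back), 0)
  expect_named(readTsvForTest(paths[["truth"]]),
               c("accession", "is_binder", "category", "sequence",
                 "identity_to_query", "affinity_Q8", "affinity_Q6",
                 "affinity_K8"))
})

test_that("redundant reports mark duplicated proteins as shared peptides", {
  cfg <- simulationConfig(nProteins = 30, redundancyRate = 0.5, seed = 4)
  truth <- generateGroundTruth(cfg)
  design <- captureDesign(probes = "Q8")
  rep <- simulatePeptideReport(truth, design, cfg, redundant = TRUE)
  shared <- grepl(";", rep$protein_accession)
  expect_gt(sum(shared), 0)
  accPairs <- unique(rep$protein_accession[shared])
  first <- strsplit(accPairs[1], ";")[[1]]
  expect_equal(duplicateMap(truth)$duplicate_accession[
    match(first[1], duplicateMap(truth)$canonical_accession)], first[2])
})
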