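mkAnn <- function(acc, desc, go = "", ipr = "") {
  data.frame(accession = acc, description = desc, go_terms = go,
             ipr_terms = ipr, stringsAsFactors = FALSE)
}

test_that("keyword screen categorizes with A > B > C priority", {
  ann <- rbind(
    mkAnn("P1", "probable methyltransferase 3"),
    mkAnn("P2", "some protein", go = "GO:0016491|oxidoreductase activity"),
    mkAnn("P3", "bifunctional methyltransferase/monooxygenase"), # A beats B
    mkAnn("P4", "UDP-glycosyltransferase 73C"),
    mkAnn("P5", "uncharacterized protein"),
    mkAnn("P6", ""))
  res <- categorizeCandidates(ann)
  got <- setNames(as.character(res$category), res$accession)
  expect_identical(got[["P1"]], "B_methyltransferase")
  expect_identical(got[["P2"]], "A_oxidase")
  expect_identical(got[["P3"]], "A_oxidase")
  expect_identical(got[["P4"]], "C_glycosyltransferase")
  expect_identical(got[["P5"]], "D_other")
  expect_identical(got[["P6"]], "D_other")
  expect_false(res$characterized[res$accession == "P5"])
  expect_true(res$characterized[res$accession == "P1"])

  # order-independent
  res2 <- categorizeCandidates(ann[sample(nrow(ann)), ])
  expect_identical(setNames(as.character(res2$category), res2$accession)[names(got)],
                   got)
  expect_error(categorizeCandidates(ann, keywords = list(A_oxidase = character())),
               "non-empty")
})

test_that("heatmap table merges assays in the reference namespace", {
  mkStat <- function(acc, cls, r, nCap = 3, nCtl = 0, p = 0.001) {
    data.frame(accession = acc, contrast = "x", r = r, flag = "ok", p = p,
               log2_r = log2(r), neg_log10_p = -log10(p),
               n_detected_capture = nCap, n_detected_control = nCtl,
               capture_class = factor(cls, levels = probeCapture:::captureClassLevels,
                                      ordered = TRUE),
               stringsAsFactors = FALSE)
  }
  hm <- buildHeatmapTable(
    list("Rudbeckia.Q8.O" = rbind(
           mkStat("L1", "highly_significant_enriched", 20),
           mkStat("L2", "highly_significant_absent_control", NA),
           mkStat("L3", "detected", 1.2)),
         "Rudbeckia.Q6.O" = rbind(
           mkStat("L1", "highly_significant_enriched", 18),
           mkStat("L2", "detected", 1.1))),
    annotations = mkAnn("L1", "cytochrome P450 monooxygenase"),
    homologueMap = data.frame(local_accession = c("L1", "L2", "L3"),
                              reference_accession = c("R1", "R2", "R3")))
  expect_setequal(hm$accession, c("R1", "R2", "R3"))
  # one row per (reference accession, assay) with any detection
  expect_equal(nrow(hm), 5)
  # captured by both quercetin probes -> not exclusive
  expect_false(any(hm$exclusive_quercetin[hm$accession == "R1"]))
  # highly significant under Q8 only -> exclusive flag
  expect_true(all(hm$exclusive_quercetin[hm$accession == "R2"]))
  expect_identical(unique(hm$category[hm$accession == "R1"]), "A_oxidase")
})

test_that("heatmap warns on unmappable accessions and keeps local ids", {
  st <- data.frame(accession = "LX", contrast = "x", r = 5, flag = "ok",
                   p = 0.01, log2_r = log2(5), neg_log10_p = 2,
                   n_detected_capture = 3, n_detected_control = 3,
                   capture_class = "significant", stringsAsFactors = FALSE)
  expect_warning(
    hm <- buildHeatmapTable(list("Sp.Q8.O" = st),
                            homologueMap = data.frame(local_accession = "other",
                                                      reference_accession = "R")),
    "LX")
  expect_identical(hm$accession, "LX")
})

test_that("redundant local accessions collapse onto the better cell", {
  mk <- function(acc, p, r) data.frame(
    accession = acc, contrast = "x", r = r, flag = "ok", p = p,
    log2_r = log2(r), neg_log10_p = -log10(p),
    n_detected_capture = 3, n_detected_control = 3,
    capture_class = "significant", stringsAsFactors = FALSE)
  hm <- buildHeatmapTable(
    list("Sp.Q8.O" = rbind(mk("L1", 0.04, 3), mk("L1alt", 0.002, 9))),
    homologueMap = data.frame(local_accession = c("L1", "L1alt"),
                              reference_accession = c("R1", "R1")))
  expect_equal(nrow(hm), 1)
  expect_equal(hm$r, 9) # the lower-p cell won
})

test_that("cross-species coherence requires capture in both proteomes", {
  mkStat <- function(acc, cls) data.frame(
    accession = acc, contrast = "x", r = 10, flag = "ok", p = 0.001,
    log2_r = log2(10), neg_log10_p = 3, n_detected_capture = 3,
    n_detected_control = 0, capture_class = cls, stringsAsFactors = FALSE)
  sp1 <- list(a = mkStat(c("A1", "A2"), "highly_significant_absent_control"))
  sp2 <- list(a = mkStat("B1", "highly_significant_enriched"),
              b = mkStat("B3", "detected"))
  m1 <- data.frame(local_accession = c("A1", "A2"),
                   reference_accession = c("R1", "R2"))
  m2 <- data.frame(local_accession = c("B1", "B3"),
                   reference_accession = c("R1", "R3"))
  confirmed <- crossSpeciesCoherence(sp1, sp2, m1, m2)
  expect_identical(confirmed, "R1") # R2 in sp1 only; R3 not highly significant
  hs1 <- unique(unlist(lapply(sp1, highlySignificant)))
  expect_true(all(confirmed %in% probeCapture:::mapToReference(hs1, m1)))
})

test_that("GO enrichment p-values match the exhaustive hypergeometric oracle", {
  # 5/10 targets vs 10/100 background: frozen oracle value 6.7162774826505e-4
  background <- sprintf("B%03d", 1:100)
  target <- background[1:10]
  withTerm <- c(background[1:5], background[11:15]) # 5 in target, 10 total
  ann <- mkAnn(background, "protein",
               go = ifelse(background %in% withTerm,
                           "GO:0016491|oxidoreductase activity", ""))
  res <- goEnrichment(target, background, ann)
  expect_equal(res$p[res$term == "GO:0016491"], 6.7162774826505e-4,
               tolerance = 1e-10)
  expect_equal(res$count_target[res$term == "GO:0016491"], 5)
  expect_equal(res$count_background[res$term == "GO:0016491"], 10)

  set.seed(59)
  for (i in 1:20) {
    N <- sample(30:100, 1); n <- sample(5:20, 1); K <- sample(3:25, 1)
    bg <- sprintf("x%03d", 1:N)
    tg <- sample(bg, n)
    carriers <- sample(bg, K)
    k <- length(intersect(tg, carriers))
    if (k == 0) next
    ann2 <- mkAnn(bg, "p", go = ifelse(bg %in% carriers, "GO:0000001|term", ""))
    got <- goEnrichment(tg, bg, ann2)
    expect_equal(got$p[got$term == "GO:0000001"], hyperOracle(k, K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("GO enrichment handles degenerate inputs", {
  bg <- sprintf("g%02d", 1:20)
  ann <- mkAnn(bg, "p", go = "GO:0000002|everywhere")
  res <- goEnrichment(bg, bg, ann) # target = background: p must be 1
  expect_equal(res$p, 1)
  expect_error(goEnrichment(c(bg, "alien"), bg, ann), "subset")
  # BH adjustment is monotone and bounded
  tg <- bg[1:8]
  ann3 <- rbind(mkAnn(bg[1:10], "p", go = "GO:0000003|a"),
                mkAnn(bg[11:20], "p", go = "GO:0000004|b"))
  res3 <- goEnrichment(tg, bg, ann3)
  expect_true(all(res3$padj >= res3$p - 1e-15 & res3$padj <= 1))
})

test_that("binder-specific terms rank first in a synthetic recovery run", {
  truth <- generateGroundTruth(simulationConfig(nProteins = 150, seed = 23))
  cat150 <- truthCatalog(truth)
  # give every binder one marker term; background proteins a generic one
  ann <- mkAnn(cat150$accession, "protein",
               go = ifelse(cat150$is_binder,
                           "GO:0099999|probe binding;GO:0005524|ATP binding",
                           "GO:0005524|ATP binding"))
  target <- cat150$accession[cat150$is_binder]
  res <- goEnrichment(target, cat150$accession, ann)
  expect_identical(res$term[1], "GO:0099999")
  expect_lt(res$padj[1], 1e-6)
})
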