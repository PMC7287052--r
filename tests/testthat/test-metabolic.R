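test_that("upregulationProfile computes strict z > 0 fractions", {
    zm <- mkMatrix(c(0.5, -0.5, 1.2, -2,
                     0, 0, 0, 0), c("HK2", "LDHA"), sprintf("s%d", 1:4))
    strata <- setNames(rep("high", 4), colnames(zm))
    pr <- upregulationProfile(zm, panels = list(glycolysis = c("HK2",
                                                               "LDHA")),
                              strata = strata)
    expect_equal(pr$frac[pr$gene == "HK2"], 0.5)
    # all-zero gene is never "up" (strict inequality)
    expect_equal(pr$frac[pr$gene == "LDHA"], 0)
})

test_that("upregulationProfile drops absent genes with a warning", {
    set.seed(41)
    zm <- matrix(rnorm(2 * 40), 2, 40,
                 dimnames = list(c("HK2", "LDHA"), sprintf("s%d", 1:40)))
    strata <- setNames(rep(c("high", "low"), 20), colnames(zm))
    expect_warning(
        pr <- upregulationProfile(zm,
                                  panels = list(glycolysis = c("HK2", "LDHA",
                                                               "GONE")),
                                  strata = strata),
        "dropping")
    expect_setequal(unique(pr$gene), c("HK2", "LDHA"))
    expect_identical(attr(pr, "missing_genes"), "GONE")
})

test_that("null genes have upregulation fractions near one half", {
    set.seed(42)
    zm <- matrix(rnorm(20 * 400), 20, 400,
                 dimnames = list(sprintf("G%02d", 1:20),
                                 sprintf("s%d", 1:400)))
    strata <- setNames(rep("all", 400), colnames(zm))
    pr <- upregulationProfile(zm, panels = list(p = rownames(zm)),
                              strata = strata, exclude = character())
    expect_equal(mean(pr$frac), 0.5, tolerance = 0.05)
})

test_that("compareGeneUpregulation reuses the exact 2x2 machinery", {
    pr <- data.frame(gene = "HK2", panel = "glycolysis",
                     stratum = c("high", "low"), n = c(50, 60),
                     n_up = c(40, 12), frac = c(0.8, 0.2))
    r <- compareGeneUpregulation(pr, "HK2")
    expect_equal(r$p,
                 fisherExact2x2(rbind(c(40, 12), c(10, 48)))$p,
                 tolerance = 1e-12)
    expect_true(r$significant)
    # identical strata: p = 1
    pr2 <- pr; pr2$n_up <- c(25, 30)
    expect_equal(compareGeneUpregulation(pr2, "HK2")$p, 1)
})

test_that("comparePanelMeans matches the hand-computed Welch formula", {
    x <- c(0.8, 0.7, 0.9); y <- c(0.2, 0.4, 0.3)
    pr <- data.frame(gene = rep(c("A", "B", "C"), 2), panel = "p",
                     stratum = rep(c("high", "low"), each = 3),
                     n = 10, n_up = 5, frac = c(x, y))
    r <- comparePanelMeans(pr, "p")
    tHand <- (mean(x) - mean(y)) /
        sqrt(var(x) / length(x) + var(y) / length(y))
    dfHand <- (var(x) / 3 + var(y) / 3)^2 /
        ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
    expect_equal(r$t, tHand, tolerance = 1e-9)
    expect_equal(r$df, dfHand, tolerance = 1e-9)
    expect_equal(r$p, 2 * pt(-abs(tHand), dfHand), tolerance = 1e-9)
    # symmetry: swapping strata negates t and preserves p
    r2 <- comparePanelMeans(pr, "p", strata = c("low", "high"))
    expect_equal(r2$t, -r$t, tolerance = 1e-12)
    expect_equal(r2$p, r$p, tolerance = 1e-12)
    # identical vectors: t = 0, p = 1
    prEq <- pr; prEq$frac <- rep(c(0.5, 0.5, 0.5), 2)
    rEq <- comparePanelMeans(prEq, "p")
    expect_equal(rEq$t, 0)
    expect_equal(rEq$p, 1)
    expect_error(comparePanelMeans(pr[c(1, 4), ], "p"), ">= 2 genes")
})

test_that("relativePhenotype normalizes shares and is scale invariant", {
    pr <- data.frame(gene = c("A", "B", "C", "D"),
                     panel = rep(c("glycolysis", "oxphos"), each = 2),
                     stratum = "high", n = 10, n_up = 5,
                     frac = c(0.6, 0.6, 0.2, 0.2))
    ph <- relativePhenotype(pr)
    expect_equal(ph$glycolysis_share, 0.75)
    expect_equal(ph$oxphos_share, 0.25)
    expect_equal(ph$glycolysis_share + ph$oxphos_share, 1, tolerance = 1e-9)
    pr2 <- pr; pr2$frac <- pr$frac / 3
    expect_equal(relativePhenotype(pr2)$glycolysis_share, 0.75,
                 tolerance = 1e-12)
    pr3 <- pr; pr3$frac <- 0
    expect_error(relativePhenotype(pr3), "zero")
    # symmetric case
    pr4 <- pr; pr4$frac <- 0.5
    expect_equal(relativePhenotype(pr4)$glycolysis_share, 0.5)
})

test_that("planted regulator coupling drives stratum-wise gene significance", {
    co <- simulateCohort(cohortConfig(nSamples = 800, metabCoupling = 0.8,
                                      seed = 44))
    z <- zScore(cohortExpression(co))
    st <- stratifyExpression(z, "EP300", kappa = 1)
    pr <- upregulationProfile(z, strata = st)
    glyGenes <- metabolicPanels()$glycolysis
    sig <- vapply(glyGenes, function(g) {
        r <- compareGeneUpregulation(pr, g)
        r$p < 0.05 && r$table["up", "high"] / sum(r$table[, "high"]) >
            r$table["up", "low"] / sum(r$table[, "low"])
    }, logical(1L))
    expect_gte(sum(sig), 20L)
    # panel-level: glycolysis dominates the high stratum, OXPHOS the low
    ph <- relativePhenotype(pr)
    expect_gt(ph$glycolysis_share[ph$stratum == "high"], 0.5)
    expect_gt(ph$oxphos_share[ph$stratum == "low"], 0.5)
})

test_that("wordcloud export is a deterministic pass-through", {
    pr <- data.frame(gene = c("B", "A", "C"), panel = "glycolysis",
                     stratum = "high", n = 10, n_up = c(1, 2, 3),
                     frac = c(0.1, 0.2, 0.3))
    f1 <- tempfile(); f2 <- tempfile()
    out <- exportWordcloudWeights(pr, "high", f1)
    exportWordcloudWeights(pr, "high", f2)
    expect_equal(nrow(out), 3L)
    expect_identical(out$gene, c("A", "B", "C"))     # stable ordering
    expect_equal(out$weight, c(0.2, 0.1, 0.3))       # exact pass-through
    expect_identical(readLines(f1), readLines(f2))   # byte-identical
})
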