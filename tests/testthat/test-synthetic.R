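test_that("simulateCohort is deterministic under a fixed seed", {
    c1 <- simulateCohort(cohortConfig(nSamples = 200, seed = 7))
    c2 <- simulateCohort(cohortConfig(nSamples = 200, seed = 7))
    expect_identical(SummarizedExperiment::assay(cohortExpression(c1)),
                     SummarizedExperiment::assay(cohortExpression(c2)))
    expect_identical(mutationRecords(cohortMutations(c1)),
                     mutationRecords(cohortMutations(c2)))
    expect_identical(cohortClinical(c1), cohortClinical(c2))
    c3 <- simulateCohort(cohortConfig(nSamples = 200, seed = 8))
    expect_false(identical(
        SummarizedExperiment::assay(cohortExpression(c1)),
        SummarizedExperiment::assay(cohortExpression(c3))))
})

test_that("cohortConfig validates proportions, rates and coupling", {
    expect_error(cohortConfig(proportions = c(activated = 0.5,
                                              suppressed = 0.5,
                                              absent = 0.5,
                                              unclassified = -0.5)),
                 "\\[0, 1\\]")
    expect_error(cohortConfig(proportions = c(activated = 0.3,
                                              suppressed = 0.3,
                                              absent = 0.3,
                                              unclassified = 0.2)),
                 "sum to 1")
    expect_error(cohortConfig(mutBaseRate = 1.5), "rates")
    expect_error(cohortConfig(metabCoupling = 1), "metabCoupling")
})

test_that("realized subtype counts stay within multinomial bounds", {
    cfg <- cohortConfig(nSamples = 600, seed = 61)
    co <- simulateCohort(cfg)
    tab <- table(factor(cohortTruth(co)$subtype,
                        levels = names(cfg$proportions)))
    for (lv in names(cfg$proportions)) {
        p <- cfg$proportions[[lv]]
        expect_lt(abs(tab[[lv]] - 600 * p), 4 * sqrt(600 * p * (1 - p)) + 1)
    }
})

test_that("planted mutation rates are recovered within binomial error", {
    cfg <- cohortConfig(nSamples = 800,
                        proportions = c(activated = 0.25, suppressed = 0.25,
                                        absent = 0.25, unclassified = 0.25),
                        mutBaseRate = 0.05, mutEnrichedRate = 0.5,
                        seed = 62)
    co <- simulateCohort(cfg)
    tr <- cohortTruth(co)
    inAct <- tr$subtype == "activated"
    rateAct <- mean(tr$planted_mutated[inAct])
    # 99% binomial CI around the planted rate
    expect_lt(abs(rateAct - 0.5), 2.58 * sqrt(0.25 / sum(inAct)))
    rateBg <- mean(tr$planted_mutated[!inAct])
    expect_lt(abs(rateBg - 0.05),
              2.58 * sqrt(0.05 * 0.95 / sum(!inAct)))
    # truth flags agree with the mutation records
    rec <- mutationRecords(cohortMutations(co))
    expect_setequal(rec$sample_id[rec$gene == "EP300"],
                    tr$sample_id[tr$planted_mutated])
})

test_that("regulator-program coupling matches the generative correlation", {
    co <- simulateCohort(cohortConfig(nSamples = 1000, metabCoupling = 0.8,
                                      seed = 63))
    x <- SummarizedExperiment::assay(cohortExpression(co))
    reg <- x["EP300", ]
    glyGenes <- setdiff(TIMEsig:::.canonical(metabolicPanels()$glycolysis),
                        "EP300")
    corGly <- vapply(glyGenes, function(g) cor(reg, x[g, ]), numeric(1L))
    expect_true(all(abs(corGly - 0.8) < 0.05))
    corOx <- vapply(metabolicPanels()$oxphos,
                    function(g) cor(reg, x[g, ]), numeric(1L))
    expect_true(all(abs(corOx + 0.8) < 0.05))
})

test_that("a fully unclassified null cohort yields no subtype calls", {
    co <- simulateCohort(cohortConfig(
        nSamples = 400, immuneShift = 0,
        proportions = c(activated = 0, suppressed = 0, absent = 0,
                        unclassified = 1), seed = 64))
    a <- assignSubtypes(zScore(cohortExpression(co)))
    expect_lte(mean(a$subtype != "unclassified"), 0.01)
})

test_that("classification accuracy is monotone in the planted shift", {
    accAt <- function(delta) {
        mean(vapply(1:5, function(s) {
            co <- simulateCohort(cohortConfig(nSamples = 600,
                                              immuneShift = delta,
                                              seed = 600 + s))
            a <- assignSubtypes(zScore(cohortExpression(co)))
            tr <- cohortTruth(co)
            planted <- tr$subtype != "unclassified"
            mean(as.character(a$subtype[planted]) == tr$subtype[planted])
        }, numeric(1L)))
    }
    accs <- vapply(c(0.5, 1, 2, 3), accAt, numeric(1L))
    # non-decreasing up to Monte-Carlo noise
    expect_true(all(diff(accs) > -0.02))
    expect_gte(accs[4], 0.9)
})

test_that("simulatePerturbation is deterministic and validated", {
    p1 <- simulatePerturbation(seed = 9)
    p2 <- simulatePerturbation(seed = 9)
    expect_identical(perturbationData(p1), perturbationData(p2))
    expect_error(simulatePerturbation(nRepsTreated = 1), ">= 2 replicates")
    d <- perturbationData(p1)
    expect_equal(length(unique(d$replicate[d$condition == "control"])), 10L)
    expect_equal(length(unique(d$replicate[d$condition == "treated"])), 4L)
    expect_equal(length(unique(d$gene)), 52L + 116L)
})

test_that("null perturbation p-values are approximately uniform", {
    ps <- vapply(1:60, function(s) {
        pe <- simulatePerturbation(cellLines = "CL1",
                                   panels = metabolicPanels(),
                                   deltaGlyc = 0, deltaOx = 0,
                                   nRepsControl = 4, nRepsTreated = 3,
                                   seed = 700 + s)
        treatmentShift(pe, "CL1", metabolicPanels()$glycolysis)$p
    }, numeric(1L))
    # Kolmogorov-Smirnov against U(0,1)
    expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
    expect_gt(mean(ps), 0.3)
})
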