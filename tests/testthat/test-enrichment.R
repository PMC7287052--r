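test_that("filterGenes counts records and patients separately", {
    # 2 records in one patient + 1 in another: count 3, patients 2
    mut <- MutationTable(c("s1", "s1", "s2"), rep("G", 3),
                         rep("Missense_Mutation", 3),
                         profiledSamples = c("s1", "s2", "s3", "s4"))
    st <- filterGenes(mut, minCount = 1)
    expect_equal(st$mutation_count, 3L)
    expect_equal(st$mutated_patient_count, 2L)
    expect_equal(st$patient_frequency, 0.5)
    expect_equal(st$count_frequency, 0.75)
})

test_that("filterGenes applies the record-count threshold and ordering", {
    mut <- MutationTable(
        sample_id = c(sprintf("s%02d", 1:10), sprintf("s%02d", 1:9),
                      sprintf("s%02d", 1:10)),
        gene = c(rep("AAA", 10), rep("ZZZ", 9), rep("BBB", 10)),
        variant_class = "Missense_Mutation",
        profiledSamples = sprintf("s%02d", 1:20))
    st <- filterGenes(mut, minCount = 10)
    expect_identical(st$gene, c("AAA", "BBB"))  # ZZZ below threshold
    # frequency arithmetic at the published scale: 10 of 512 is 1.95%
    mut512 <- MutationTable(sprintf("t%03d", 1:10), rep("G", 10),
                            "Missense_Mutation",
                            profiledSamples = sprintf("t%03d", 1:512))
    expect_equal(round(100 * filterGenes(mut512)$count_frequency, 2), 1.95)
})

test_that("enrichmentScreen recovers a planted subtype-enriched gene", {
    co <- simulateCohort(cohortConfig(
        nSamples = 300,
        proportions = c(activated = 0.2, suppressed = 0.2, absent = 0.2,
                        unclassified = 0.4),
        mutBaseRate = 0.05, mutEnrichedRate = 0.5, seed = 31))
    a <- assignSubtypes(zScore(cohortExpression(co)))
    scr <- enrichmentScreen(a, cohortMutations(co), minCount = 5)
    row <- scr[scr$gene == "EP300", ]
    expect_lt(row$omnibus_p, 0.001)
    expect_identical(row$direction, "activated")
    expect_true(row$significant)
    expect_true(all(scr$omnibus_p > 0 & scr$omnibus_p <= 1))
    expect_true(all(scr$q_value >= scr$omnibus_p - 1e-12))
    # contingency counts cover exactly the classified, profiled samples
    ncls <- sum(a$subtype != "unclassified")
    expect_equal(unique(rowSums(
        scr[, c("mutated_activated", "wildtype_activated",
                "mutated_suppressed", "wildtype_suppressed",
                "mutated_absent", "wildtype_absent")])), ncls)
})

test_that("enrichmentScreen is invariant to sample order", {
    co <- simulateCohort(cohortConfig(nSamples = 200, seed = 32))
    a <- assignSubtypes(zScore(cohortExpression(co)))
    scr1 <- enrichmentScreen(a, cohortMutations(co), genes = "EP300")
    a2 <- a[rev(seq_len(nrow(a))), ]
    scr2 <- enrichmentScreen(a2, cohortMutations(co), genes = "EP300")
    expect_equal(scr1$omnibus_p, scr2$omnibus_p, tolerance = 1e-12)
})

test_that("enrichment monotonicity: stronger planting lowers the median p", {
    meds <- vapply(c(0.05, 0.2, 0.5), function(rate) {
        ps <- vapply(1:15, function(s) {
            co <- simulateCohort(cohortConfig(
                nSamples = 300,
                proportions = c(activated = 0.2, suppressed = 0.2,
                                absent = 0.2, unclassified = 0.4),
                mutBaseRate = 0.05, mutEnrichedRate = rate,
                nNeutralMutGenes = 2, seed = 100 + s))
            scr <- enrichmentScreen(truthAssignment(co),
                                    cohortMutations(co), genes = "EP300")
            scr$omnibus_p
        }, numeric(1L))
        median(ps)
    }, numeric(1L))
    expect_true(all(diff(meds) <= 0))
})

test_that("degenerate screens behave", {
    ids <- sprintf("s%d", 1:30)
    a <- mkAssignment(ids, rep(c("activated", "suppressed", "absent"), 10))
    mut <- MutationTable("s1", "G", "Missense_Mutation",
                         profiledSamples = ids)
    # gene mutated in zero classified samples -> p = 1, no direction
    scr <- enrichmentScreen(a, MutationTable(profiledSamples = ids),
                            genes = "NOTMUT")
    expect_equal(scr$omnibus_p, 1)
    expect_true(is.na(scr$direction))
    # fewer than two nonempty subtypes is an error
    a1 <- mkAssignment(ids, rep("activated", 30))
    expect_error(enrichmentScreen(a1, mut, genes = "G"), "two non-empty")
})

test_that("HPV stratification runs the screen within each stratum", {
    co <- simulateCohort(cohortConfig(nSamples = 400, seed = 33))
    a <- truthAssignment(co)
    scr <- enrichmentScreen(a, cohortMutations(co), genes = "EP300",
                            clinical = cohortClinical(co),
                            hpvStratify = TRUE)
    expect_setequal(unique(scr$stratum),
                    c("all", "hpv_positive", "hpv_negative"))
    expect_error(enrichmentScreen(a, cohortMutations(co), genes = "EP300",
                                  hpvStratify = TRUE),
                 "clinical")
})

test_that("cytactAssociation builds the 2x2 on up/down samples only", {
    ids <- sprintf("s%d", 1:48)
    cyt <- data.frame(sample_id = ids,
                      cytact = factor(rep(c("up", "down", "neither"), 16),
                                      levels = c("up", "down", "neither")))
    mutated <- setNames(ids %in% ids[1:9], ids)  # mutated mostly CytAct-up
    r <- cytactAssociation(mutated, cyt)
    expect_equal(sum(r$table), 32)  # neither excluded
    expect_equal(r$p, fisherExact2x2(r$table)$p)
    # planted association: mutants all up (8/8) vs background
    cyt2 <- data.frame(sample_id = sprintf("x%d", 1:48),
                       cytact = factor(rep(c("up", "down"), c(18, 30)),
                                       levels = c("up", "down", "neither")))
    mut2 <- setNames(sprintf("x%d", 1:48) %in% sprintf("x%d", 1:8),
                     sprintf("x%d", 1:48))
    expect_lt(cytactAssociation(mut2, cyt2)$p, 0.01)
    # single mutated sample: runs without crashing, uninformative p
    mut3 <- setNames(sprintf("x%d", 1:48) == "x1", sprintf("x%d", 1:48))
    expect_gt(cytactAssociation(mut3, cyt2)$p, 0.1)
    # all-neither is an error
    cyt3 <- data.frame(sample_id = ids,
                       cytact = factor("neither",
                                       levels = c("up", "down", "neither")))
    expect_error(cytactAssociation(mutated, cyt3), "up or down")
})

test_that("domainTabulation computes per-domain CytAct percentages", {
    domains <- c(rep("TAZ1", 8), rep("KAT", 4), NA, "weird")
    up <- c(rep(TRUE, 3), rep(FALSE, 5), TRUE, rep(FALSE, 3), TRUE, TRUE)
    tab <- domainTabulation(domains, up, knownDomains = c("TAZ1", "KAT"))
    taz <- tab[tab$domain == "TAZ1", ]
    expect_equal(taz$n_mutations, 8L)
    expect_equal(taz$n_cytact_up, 3L)
    expect_equal(taz$pct_cytact_up, 37.5)
    expect_equal(tab$n_mutations[tab$domain == "other"], 2L)
    # self-consistency of percentages
    expect_true(all(abs(tab$pct_cytact_up -
                        100 * tab$n_cytact_up / tab$n_mutations) <= 0.05))
    # zero-mutation domains are simply absent
    expect_false("IBID" %in% tab$domain)
})
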