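#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the analyzed head-and-neck cohort: 530 samples of which
#' 20/35/100 carry the three planted TIME subtypes and 375 are unclassified;
#' an immune-panel shift of 3 sd; a planted mutation gene enriched in the
#' activated subtype (50\% vs a 5\% background rate) plus 20 neutral mutated
#' genes; a regulator gene coupled +0.8 to the glycolysis program and -0.8 to
#' the OXPHOS program; exponential survival with a halved hazard for the
#' activated subtype; and HPV-positivity rates of 45/15/6/15\% by subtype.
#'
#' @param nSamples cohort size.
#' @param proportions probabilities of (activated, suppressed, absent,
#'   unclassified), summing to 1.
#' @param immuneShift planted immune-panel effect size, in sd units.
#' @param nBackgroundGenes number of unshifted standard-normal genes.
#' @param plantedMutGene symbol of the subtype-enriched mutated gene.
#' @param mutBaseRate,mutEnrichedRate per-sample mutation probabilities
#'   outside / inside the enriched subtype.
#' @param enrichedSubtype subtype carrying the enrichment.
#' @param nNeutralMutGenes neutral mutated genes at the base rate.
#' @param regulatorGene symbol of the metabolically coupled regulator.
#' @param metabCoupling correlation magnitude rho between the regulator and
#'   each glycolysis gene (+rho) / OXPHOS gene (-rho); |rho| < 1.
#' @param hazards named exponential hazards per subtype (per day).
#' @param dfsHazardFactor disease-free-survival hazard multiplier.
#' @param hpvRates named per-subtype HPV-positivity probabilities.
#' @param seed integer RNG seed; one seed drives the whole generator.
#' @return validated configuration list (class \code{CohortConfig}).
#' @export
cohortConfig <- function(nSamples = 530,
                         proportions = c(activated = 20, suppressed = 35,
                                         absent = 100,
                                         unclassified = 375) / 530,
                         immuneShift = 3,
                         nBackgroundGenes = 50,
                         plantedMutGene = "EP300",
                         mutBaseRate = 0.05,
                         mutEnrichedRate = 0.5,
                         enrichedSubtype = "activated",
                         nNeutralMutGenes = 20,
                         regulatorGene = "EP300",
                         metabCoupling = 0.8,
                         hazards = c(activated = 5e-4, suppressed = 1e-3,
                                     absent = 1e-3, unclassified = 1e-3),
                         dfsHazardFactor = 1.5,
                         hpvRates = c(activated = 0.45, suppressed = 0.15,
                                      absent = 0.06, unclassified = 0.15),
                         seed = 1L) {
    lev <- c("activated", "suppressed", "absent", "unclassified")
    if (!identical(names(proportions), lev))
        stop("proportions must be named ", paste(lev, collapse = ", "))
    if (any(proportions < 0) || any(proportions > 1))
        stop("proportions must lie in [0, 1]")
    if (abs(sum(proportions) - 1) > 1e-9)
        stop("proportions must sum to 1")
    for (r in c(mutBaseRate, mutEnrichedRate))
        if (r < 0 || r > 1) stop("mutation rates must lie in [0, 1]")
    if (abs(metabCoupling) >= 1) stop("|metabCoupling| must be < 1")
    if (!enrichedSubtype %in% lev) stop("unknown enrichedSubtype")
    if (!all(lev %in% names(hazards)) || any(hazards <= 0))
        stop("hazards must be positive and named per subtype")
    if (nSamples < 2L) stop("nSamples must be >= 2")
    structure(list(nSamples = as.integer(nSamples),
                   proportions = proportions, immuneShift = immuneShift,
                   nBackgroundGenes = as.integer(nBackgroundGenes),
                   plantedMutGene = plantedMutGene,
                   mutBaseRate = mutBaseRate,
                   mutEnrichedRate = mutEnrichedRate,
                   enrichedSubtype = enrichedSubtype,
                   nNeutralMutGenes = as.integer(nNeutralMutGenes),
                   regulatorGene = regulatorGene,
                   metabCoupling = metabCoupling,
                   hazards = hazards[lev],
                   dfsHazardFactor = dfsHazardFactor,
                   hpvRates = hpvRates[lev],
                   seed = as.integer(seed)),
              class = "CohortConfig")
}

#' Simulate a cohort with planted truth
#'
#' Expression is generated directly on the z-like scale (standard-normal
#' background), since every downstream rule operates on z-scores. Immune
#' panel genes are shifted by +/- \code{immuneShift} according to the planted
#' subtype: activated samples have all eight markers up; suppressed samples
#' have CD68/S100A9 up and the cytotoxic genes down; absent samples have all
#' markers down. Unclassified samples violate every panel by construction:
#' one cytotoxic gene is forced to +(0.5 + |N(0,1)|) -- breaking the
#' suppressed and absent rules -- and a second, distinct activated-panel gene
#' is forced to -(0.5 + |N(0,1)|) -- breaking the activated rule. The two
#' forced values have opposite signs so per-gene cohort means stay near zero
#' and the violations survive re-standardization.
#'
#' The planted mutation gene is mutated with \code{mutEnrichedRate} in the
#' enriched subtype and \code{mutBaseRate} elsewhere; neutral genes are
#' mutated at the base rate everywhere. The regulator gene r ~ N(0,1) drives
#' glycolysis genes rho*r + sqrt(1-rho^2)*noise and OXPHOS genes
#' -rho*r + sqrt(1-rho^2)*noise. Survival is exponential with per-subtype
#' hazards under independent Uniform(0, 3/max hazard) censoring. A fixed
#' seed gives byte-identical output.
#'
#' @param cfg a \code{\link{cohortConfig}}.
#' @return a \linkS4class{SyntheticCohort}.
#' @export
simulateCohort <- function(cfg = cohortConfig()) {
    stopifnot(inherits(cfg, "CohortConfig"))
    set.seed(cfg$seed)
    n <- cfg$nSamples
    lev <- c("activated", "suppressed", "absent", "unclassified")
    subtype <- sample(lev, n, replace = TRUE, prob = cfg$proportions)
    ids <- sprintf("S%05d", seq_len(n))

    immune <- immuneMarkerGenes()
    cytotoxic <- c("CD8A", "GZMB", "PRF1")
    actPanel <- c("PTPRC", cytotoxic)
    panels <- metabolicPanels()
    glyGenes <- .canonical(panels$glycolysis)     # GLUT1 stored as SLC2A1
    oxGenes <- panels$oxphos
    bg <- if (cfg$nBackgroundGenes > 0L)
        sprintf("BG%03d", seq_len(cfg$nBackgroundGenes)) else character()
    genes <- unique(c(immune, cfg$regulatorGene, glyGenes, oxGenes, bg))

    x <- matrix(rnorm(length(genes) * n), length(genes), n,
                dimnames = list(genes, ids))

    d <- cfg$immuneShift
    act <- subtype == "activated"
    sup <- subtype == "suppressed"
    abs_ <- subtype == "absent"
    unc <- subtype == "unclassified"
    x[immune, act] <- x[immune, act] + d
    x[c("CD68", "S100A9"), sup] <- x[c("CD68", "S100A9"), sup] + d
    x[cytotoxic, sup] <- x[cytotoxic, sup] - d
    x[immune, abs_] <- x[immune, abs_] - d
    nu <- sum(unc)
    if (nu > 0L) {
        gUp <- sample(cytotoxic, nu, replace = TRUE)
        gDown <- vapply(gUp, function(g)
            sample(setdiff(actPanel, g), 1L), character(1L))
        cols <- which(unc)
        x[cbind(match(gUp, genes), cols)] <- 0.5 + abs(rnorm(nu))
        x[cbind(match(gDown, genes), cols)] <- -(0.5 + abs(rnorm(nu)))
    }

    rho <- cfg$metabCoupling
    reg <- rnorm(n)
    x[cfg$regulatorGene, ] <- reg
    noiseSd <- sqrt(1 - rho^2)
    for (g in setdiff(glyGenes, cfg$regulatorGene))
        x[g, ] <- rho * reg + noiseSd * rnorm(n)
    for (g in setdiff(oxGenes, cfg$regulatorGene))
        x[g, ] <- -rho * reg + noiseSd * rnorm(n)

    mutGenes <- c(cfg$plantedMutGene,
                  sprintf("NEUT%02d", seq_len(cfg$nNeutralMutGenes)))
    recs <- NULL
    planted <- logical(n)
    for (g in mutGenes) {
        p <- if (g == cfg$plantedMutGene)
            ifelse(subtype == cfg$enrichedSubtype, cfg$mutEnrichedRate,
                   cfg$mutBaseRate)
        else cfg$mutBaseRate
        hit <- rbinom(n, 1L, p) == 1L
        if (g == cfg$plantedMutGene) planted <- hit
        if (any(hit))
            recs <- rbind(recs, data.frame(
                sample_id = ids[hit], gene = g,
                variant_class = sample(nonsynVariantClasses(), sum(hit),
                                       replace = TRUE),
                stringsAsFactors = FALSE))
    }
    if (is.null(recs))
        recs <- data.frame(sample_id = character(), gene = character(),
                           variant_class = character())
    mut <- new("MutationTable", records = recs, profiledSamples = ids)

    haz <- cfg$hazards[subtype]
    cmax <- 3 / max(cfg$hazards)
    osT <- rexp(n, haz); osC <- runif(n, 0, cmax)
    dfsT <- rexp(n, haz * cfg$dfsHazardFactor); dfsC <- runif(n, 0, cmax)
    clinical <- data.frame(
        sample_id = ids,
        hpv_status = ifelse(runif(n) < cfg$hpvRates[subtype],
                            "positive", "negative"),
        anatomical_site = sample(c("oropharynx", "oral_cavity", "larynx",
                                   "hypopharynx"), n, replace = TRUE,
                                 prob = c(0.16, 0.60, 0.22, 0.02)),
        stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                       prob = c(0.04, 0.19, 0.21, 0.56)),
        os_time = pmin(osT, osC), os_event = as.integer(osT <= osC),
        dfs_time = pmin(dfsT, dfsC), dfs_event = as.integer(dfsT <= dfsC),
        stringsAsFactors = FALSE)

    new("SyntheticCohort",
        expression = SummarizedExperiment::SummarizedExperiment(
            assays = list(exprs = x)),
        mutations = mut,
        clinical = clinical,
        truth = data.frame(sample_id = ids, subtype = subtype,
                           planted_mutated = planted,
                           stringsAsFactors = FALSE),
        config = unclass(cfg))
}

#' Write a synthetic cohort to disk
#'
#' Writes \code{expression.tsv}, \code{mutations.tsv} (plus
#' \code{samples.txt} sidecar), \code{clinical.tsv}, \code{truth.tsv} and a
#' \code{config.json} echo, all in the package's reader formats.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeExpression(cohortExpression(cohort),
                    file.path(dir, "expression.tsv"))
    writeMutations(cohortMutations(cohort), file.path(dir, "mutations.tsv"),
                   file.path(dir, "samples.txt"))
    writeClinical(cohortClinical(cohort), file.path(dir, "clinical.tsv"))
    write.table(cohortTruth(cohort), file.path(dir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cfg <- cohort@config
    cfg$proportions <- as.list(cfg$proportions)
    cfg$hazards <- as.list(cfg$hazards)
    cfg$hpvRates <- as.list(cfg$hpvRates)
    jsonlite::write_json(cfg, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' Simulate a paired control/treated perturbation experiment
#'
#' Emulates a perturbational expression resource: per cell line, each gene
#' gets a standard-normal baseline (optionally shifted per panel to plant
#' baseline phenotypes); control replicates add N(0, sigma) noise around the
#' baseline; treated replicates are shifted by \code{-deltaGlyc} on
#' glycolysis genes and \code{+deltaOx} on OXPHOS genes before noise. The
#' default replicate design mirrors the emulated resource: 10 control and 4
#' treated replicates.
#'
#' @param cellLines cell line identifiers.
#' @param panels named list with \code{glycolysis} and \code{oxphos} gene
#'   vectors (default: the extended 52/116-gene programs).
#' @param nRepsControl,nRepsTreated replicates per arm (>= 2).
#' @param deltaGlyc treatment shift subtracted from glycolysis genes.
#' @param deltaOx treatment shift added to OXPHOS genes.
#' @param sigma replicate noise sd.
#' @param baselineShifts optional named list: cell line -> named numeric
#'   vector of per-panel baseline shifts, e.g.
#'   \code{list(A375 = c(oxphos = 1))}.
#' @param seed integer RNG seed.
#' @return a \linkS4class{PerturbationExperiment}.
#' @export
simulatePerturbation <- function(cellLines = "CL1",
                                 panels = extendedMetabolicPanels(),
                                 nRepsControl = 10, nRepsTreated = 4,
                                 deltaGlyc = 1, deltaOx = 0, sigma = 0.2,
                                 baselineShifts = NULL, seed = 1L) {
    if (nRepsControl < 2L || nRepsTreated < 2L)
        stop("need >= 2 replicates per arm")
    set.seed(seed)
    genes <- unique(unlist(panels))
    shift <- numeric(length(genes))
    shift[genes %in% panels$glycolysis] <- -deltaGlyc
    shift[genes %in% panels$oxphos] <- deltaOx
    rows <- NULL
    for (cl in cellLines) {
        base <- rnorm(length(genes))
        if (!is.null(baselineShifts[[cl]])) {
            bs <- baselineShifts[[cl]]
            for (pn in names(bs))
                base[genes %in% panels[[pn]]] <-
                    base[genes %in% panels[[pn]]] + bs[[pn]]
        }
        for (r in seq_len(nRepsControl))
            rows <- rbind(rows, data.frame(
                cell_line = cl, condition = "control",
                replicate = sprintf("c%02d", r), gene = genes,
                value = base + rnorm(length(genes), 0, sigma),
                stringsAsFactors = FALSE))
        for (r in seq_len(nRepsTreated))
            rows <- rbind(rows, data.frame(
                cell_line = cl, condition = "treated",
                replicate = sprintf("t%02d", r), gene = genes,
                value = base + shift + rnorm(length(genes), 0, sigma),
                stringsAsFactors = FALSE))
    }
    new("PerturbationExperiment", data = rows,
        metadata = list(deltaGlyc = deltaGlyc, deltaOx = deltaOx,
                        sigma = sigma, seed = seed))
}
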