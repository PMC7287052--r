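#' Pipeline configuration
#'
#' Exactly one of \code{inputs} (paths to expression/mutations/clinical
#' files) or \code{simulation} (a \code{\link{cohortConfig}}) must be given.
#' All significance thresholds live here with their standard defaults
#' (alpha = 0.05, panel threshold tau = 0, stratum cut kappa = 1,
#' minCount = 10); nothing is hard-coded downstream.
#'
#' @param inputs named list with \code{expression}, \code{mutations},
#'   \code{clinical} file paths (optional \code{sampleList}).
#' @param simulation a \code{\link{cohortConfig}}.
#' @param outputDir output directory.
#' @param alpha significance level.
#' @param tau subtype-panel z threshold.
#' @param kappa expression-stratum z cut.
#' @param minCount mutation-record filter.
#' @param regulatorGene gene whose expression strata drive the metabolic
#'   phenotyping.
#' @param rules \linkS4class{SubtypeRuleSet} override.
#' @param panels metabolic panel override.
#' @param perturbation optional named list of
#'   \code{\link{simulatePerturbation}} arguments.
#' @param seed integer seed for all stochastic stages.
#' @return validated configuration list (class \code{PipelineConfig}).
#' @export
pipelineConfig <- function(inputs = NULL, simulation = NULL,
                           outputDir = tempfile("timesig_run_"),
                           alpha = 0.05, tau = 0, kappa = 1, minCount = 10,
                           regulatorGene = "EP300", rules = NULL,
                           panels = NULL, perturbation = NULL, seed = 1L) {
    if (is.null(inputs) == is.null(simulation))
        stop("exactly one of 'inputs' or 'simulation' must be supplied")
    for (v in c(alpha, tau, kappa, minCount))
        if (!is.finite(v)) stop("thresholds must be finite")
    structure(list(inputs = inputs, simulation = simulation,
                   outputDir = outputDir, alpha = alpha, tau = tau,
                   kappa = kappa, minCount = minCount,
                   regulatorGene = regulatorGene, rules = rules,
                   panels = panels, perturbation = perturbation,
                   seed = as.integer(seed)),
              class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the \code{\link{pipelineConfig}}
#'   arguments, with \code{simulation} given as \code{\link{cohortConfig}}
#'   arguments.
#' @return a \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$simulation)) {
        if (!is.null(y$simulation$proportions))
            y$simulation$proportions <- unlist(y$simulation$proportions)
        if (!is.null(y$simulation$hazards))
            y$simulation$hazards <- unlist(y$simulation$hazards)
        if (!is.null(y$simulation$hpvRates))
            y$simulation$hpvRates <- unlist(y$simulation$hpvRates)
        y$simulation <- do.call(cohortConfig, y$simulation)
    }
    do.call(pipelineConfig, y)
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the published workflow end to end: z-score the expression
#' matrix, assign TIME subtypes, compare activated vs pooled-rest survival
#' (OS and DFS), screen filtered mutated genes for subtype enrichment, call
#' cytolytic activity, stratify samples by the regulator gene, profile
#' glycolysis/OXPHOS upregulation with panel-level tests and relative
#' phenotypes, and (optionally) simulate and test a paired perturbation
#' experiment. Writes tab-delimited stage outputs plus a machine-readable
#' \code{summary.json} into \code{outputDir}; with a fixed seed the summary
#' is identical across runs. Thresholds actually used are logged via
#' \code{message}.
#'
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return invisibly, the summary list.
#' @export
runPipeline <- function(cfg) {
    stopifnot(inherits(cfg, "PipelineConfig"))
    dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
    message(sprintf("thresholds: alpha=%g tau=%g kappa=%g minCount=%d seed=%d",
                    cfg$alpha, cfg$tau, cfg$kappa, cfg$minCount, cfg$seed))
    if (!is.null(cfg$simulation)) {
        cohort <- .stage("simulate", simulateCohort(cfg$simulation))
        expr <- cohortExpression(cohort)
        mut <- cohortMutations(cohort)
        clinical <- cohortClinical(cohort)
        writeCohort(cohort, file.path(cfg$outputDir, "cohort"))
    } else {
        expr <- .stage("load", readExpression(cfg$inputs$expression))
        mut <- .stage("load", readMutations(
            cfg$inputs$mutations, sampleListPath = cfg$inputs$sampleList))
        clinical <- .stage("load", readClinical(cfg$inputs$clinical))
    }

    z <- .stage("zscore", zScore(expr))
    rules <- if (is.null(cfg$rules)) defaultRuleSet(threshold = cfg$tau)
             else cfg$rules
    assignment <- .stage("classify", assignSubtypes(z, rules))
    write.table(assignment, file.path(cfg$outputDir, "subtypes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    counts <- table(assignment$subtype)

    surv <- list()
    for (ep in c("OS", "DFS")) {
        res <- .stage("survive",
                      compareActivatedVsRest(assignment, clinical, ep))
        write.table(res$curves,
                    file.path(cfg$outputDir,
                              sprintf("km_%s.tsv", tolower(ep))),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        surv[[ep]] <- list(statistic = res$test$statistic, p = res$test$p,
                           n = as.list(res$test$n))
    }

    screen <- .stage("enrich", enrichmentScreen(
        assignment, mut, alpha = cfg$alpha, clinical = clinical,
        hpvStratify = FALSE, minCount = cfg$minCount))
    write.table(screen, file.path(cfg$outputDir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    sig <- screen[screen$significant & screen$stratum == "all", ]

    cytact <- .stage("classify", callCytAct(z))
    write.table(cytact, file.path(cfg$outputDir, "cytact.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    strata <- .stage("metabolize",
                     stratifyExpression(z, cfg$regulatorGene, cfg$kappa))
    panels <- if (is.null(cfg$panels)) metabolicPanels() else cfg$panels
    profile <- .stage("metabolize",
                      suppressWarnings(upregulationProfile(z, panels,
                                                           strata)))
    write.table(profile, file.path(cfg$outputDir, "metabolic_profile.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    panelTests <- lapply(names(panels), function(pn) {
        r <- comparePanelMeans(profile, pn)
        list(panel = pn, mean = as.list(r$mean), t = r$t, p = r$p)
    })
    names(panelTests) <- names(panels)
    phen <- relativePhenotype(profile)
    write.table(phen, file.path(cfg$outputDir, "relative_phenotype.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (lv in unique(profile$stratum))
        exportWordcloudWeights(profile, lv,
                               file.path(cfg$outputDir,
                                         sprintf("wordcloud_%s.tsv", lv)))

    summary <- list(
        seed = cfg$seed,
        thresholds = list(alpha = cfg$alpha, tau = cfg$tau,
                          kappa = cfg$kappa, minCount = cfg$minCount),
        n_samples = ncol(expr),
        subtype_counts = as.list(setNames(as.integer(counts),
                                          names(counts))),
        survival = surv,
        n_genes_screened = length(unique(screen$gene)),
        significant_genes = as.list(sig$gene),
        cytact_counts = as.list(setNames(
            as.integer(table(cytact$cytact)),
            names(table(cytact$cytact)))),
        panel_tests = panelTests,
        relative_phenotype = lapply(seq_len(nrow(phen)), function(i)
            as.list(phen[i, ])))

    if (!is.null(cfg$perturbation)) {
        args <- cfg$perturbation
        if (is.null(args$seed)) args$seed <- cfg$seed
        pexp <- .stage("perturb", do.call(simulatePerturbation, args))
        writePerturbation(pexp, file.path(cfg$outputDir,
                                          "perturbation.tsv"))
        ppanels <- if (is.null(args$panels)) extendedMetabolicPanels()
                   else args$panels
        shifts <- NULL
        for (cl in unique(perturbationData(pexp)$cell_line))
            for (pn in names(ppanels)) {
                s <- .stage("perturb",
                            treatmentShift(pexp, cl, ppanels[[pn]], pn))
                shifts <- rbind(shifts, data.frame(
                    cell_line = cl, panel = pn, t = s$t, p = s$p,
                    direction = s$direction,
                    mean_difference = s$mean_difference))
            }
        write.table(shifts, file.path(cfg$outputDir, "treatment_shifts.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        summary$perturbation <- lapply(seq_len(nrow(shifts)), function(i)
            as.list(shifts[i, ]))
    }

    jsonlite::write_json(summary, file.path(cfg$outputDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(summary)
}
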