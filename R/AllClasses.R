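#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors metadata
#' @importFrom stats rnorm rbinom rexp runif pchisq p.adjust sd setNames
#' @importFrom utils read.delim write.table head
NULL

#' ZScoreExperiment: per-gene standardized expression
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"zscore"}
#' holds per-gene z-scores: for every gene with nonzero variance in the
#' source matrix, \code{(x - mean)/sd} computed across all samples of the
#' cohort. Genes that were constant in the source are set to an all-zero row
#' and recorded in the \code{degenerateGenes} slot, so a constant gene is
#' never called "up" or "down" by any panel rule.
#'
#' Objects are created by \code{\link{zScore}}, not by \code{new()}.
#'
#' @slot degenerateGenes character vector of zero-variance gene symbols.
#' @seealso \code{\link{zScore}}, \code{\link{assignSubtypes}}
#' @export
setClass("ZScoreExperiment",
         contains = "SummarizedExperiment",
         representation(degenerateGenes = "character"))

setValidity("ZScoreExperiment", function(object) {
    if (!"zscore" %in% SummarizedExperiment::assayNames(object))
        return("assay 'zscore' missing")
    z <- SummarizedExperiment::assay(object, "zscore")
    if (anyNA(z)) return("z-score matrix contains missing values")
    bad <- setdiff(object@degenerateGenes, rownames(z))
    if (length(bad))
        return(paste0("degenerate genes not in matrix: ",
                      paste(bad, collapse = ", ")))
    if (length(object@degenerateGenes)) {
        dz <- z[object@degenerateGenes, , drop = FALSE]
        if (any(dz != 0)) return("degenerate gene rows must be all zero")
    }
    live <- setdiff(rownames(z), object@degenerateGenes)
    if (length(live) && ncol(z) > 1L) {
        zl <- z[live, , drop = FALSE]
        m <- rowMeans(zl)
        ss <- rowSums((zl - m)^2)
        # unit sd under either the population (ddof = 0) or sample (ddof = 1)
        # convention, whichever the object was built with
        sdOff <- pmin(abs(sqrt(ss / ncol(zl)) - 1),
                      abs(sqrt(ss / (ncol(zl) - 1L)) - 1))
        if (max(abs(m)) > 1e-6 || max(sdOff) > 1e-6)
            return("non-degenerate rows must have mean 0 and sd 1")
    }
    TRUE
})

#' MutationTable: non-synonymous mutation records
#'
#' Holds one record per (sample, gene, variant class) mutation call together
#' with the set of samples that were mutation-profiled at all. The profiled
#' set may exceed the samples carrying any record: a profiled sample with no
#' records is wildtype everywhere, and frequencies are always computed over
#' the profiled set.
#'
#' @slot records data.frame with columns \code{sample_id}, \code{gene},
#'   \code{variant_class}.
#' @slot profiledSamples character vector of profiled sample identifiers.
#' @seealso \code{\link{readMutations}}, \code{\link{filterGenes}}
#' @export
setClass("MutationTable",
         representation(records = "data.frame",
                        profiledSamples = "character"))

setValidity("MutationTable", function(object) {
    need <- c("sample_id", "gene", "variant_class")
    if (!all(need %in% names(object@records)))
        return(paste0("records must have columns ",
                      paste(need, collapse = ", ")))
    if (anyDuplicated(object@profiledSamples))
        return("profiledSamples must be unique")
    orphan <- setdiff(object@records$sample_id, object@profiledSamples)
    if (length(orphan))
        return(paste0("records for unprofiled samples: ",
                      paste(head(orphan, 5L), collapse = ", ")))
    TRUE
})

#' DirectionalGenePanel: a set of genes with required z-score directions
#'
#' Encodes one classification rule: every \code{"up"} gene must exceed the
#' threshold and every \code{"down"} gene must fall below it (strict
#' inequalities; a z-score exactly at the threshold satisfies neither
#' direction).
#'
#' @slot name panel name.
#' @slot genes gene symbols (unique within the panel).
#' @slot directions \code{"up"} or \code{"down"} per gene.
#' @slot threshold z-score cut point (default 0 for panels built by
#'   \code{\link{DirectionalGenePanel}}).
#' @seealso \code{\link{panelSatisfied}}, \code{\link{defaultRuleSet}}
#' @export
setClass("DirectionalGenePanel",
         representation(name = "character", genes = "character",
                        directions = "character", threshold = "numeric"))

setValidity("DirectionalGenePanel", function(object) {
    if (length(object@genes) < 1L) return("panel needs at least one gene")
    if (length(object@genes) != length(object@directions))
        return("genes and directions differ in length")
    if (anyDuplicated(object@genes)) return("panel genes must be unique")
    if (!all(object@directions %in% c("up", "down")))
        return("directions must be 'up' or 'down'")
    if (length(object@threshold) != 1L || !is.finite(object@threshold))
        return("threshold must be a single finite number")
    TRUE
})

#' SubtypeRuleSet: the three TIME subtype panels
#'
#' Bundles the activated, suppressed and absent panels used by
#' \code{\link{assignSubtypes}}. A sample receives a subtype label iff it
#' satisfies exactly one of the three panels.
#'
#' @slot activated,suppressed,absent \linkS4class{DirectionalGenePanel}.
#' @seealso \code{\link{defaultRuleSet}}
#' @export
setClass("SubtypeRuleSet",
         representation(activated = "DirectionalGenePanel",
                        suppressed = "DirectionalGenePanel",
                        absent = "DirectionalGenePanel"))

#' SyntheticCohort: simulated cohort with planted truth
#'
#' Container returned by \code{\link{simulateCohort}}: expression (on the
#' z-like generation scale), mutation records, clinical table, the per-sample
#' planted truth, and the generating configuration.
#'
#' @slot expression \linkS4class{SummarizedExperiment} (assay
#'   \code{"exprs"}).
#' @slot mutations \linkS4class{MutationTable}.
#' @slot clinical data.frame of clinical covariates and survival endpoints.
#' @slot truth data.frame with \code{sample_id}, \code{subtype},
#'   \code{planted_mutated}.
#' @slot config echoed generator configuration (list).
#' @export
setClass("SyntheticCohort",
         representation(expression = "SummarizedExperiment",
                        mutations = "MutationTable",
                        clinical = "data.frame",
                        truth = "data.frame",
                        config = "list"))

setValidity("SyntheticCohort", function(object) {
    ids <- colnames(object@expression)
    if (!identical(sort(ids), sort(object@truth$sample_id)))
        return("truth rows must align 1:1 with expression samples")
    if (!identical(sort(ids), sort(object@clinical$sample_id)))
        return("clinical rows must align 1:1 with expression samples")
    TRUE
})

#' PerturbationExperiment: paired control/treated replicate expression
#'
#' Long-format expression of one or more cell lines measured under a control
#' condition and after treatment, with at least two replicates per condition
#' per cell line and an identical gene set across all replicates of a line.
#'
#' @slot data data.frame with columns \code{cell_line}, \code{condition}
#'   (\code{"control"}/\code{"treated"}), \code{replicate}, \code{gene},
#'   \code{value}.
#' @slot metadata free-form list (treatment name, dose, duration, ...).
#' @seealso \code{\link{simulatePerturbation}}, \code{\link{treatmentShift}}
#' @export
setClass("PerturbationExperiment",
         representation(data = "data.frame", metadata = "list"))

setValidity("PerturbationExperiment", function(object) {
    need <- c("cell_line", "condition", "replicate", "gene", "value")
    if (!all(need %in% names(object@data)))
        return(paste0("data must have columns ", paste(need, collapse = ", ")))
    if (!all(object@data$condition %in% c("control", "treated")))
        return("condition must be 'control' or 'treated'")
    for (cl in unique(object@data$cell_line)) {
        d <- object@data[object@data$cell_line == cl, ]
        for (cond in unique(d$condition)) {
            dc <- d[d$condition == cond, ]
            if (length(unique(dc$replicate)) < 2L)
                return(sprintf("cell line %s needs >= 2 %s replicates",
                               cl, cond))
            gsets <- split(dc$gene, dc$replicate)
            ref <- sort(gsets[[1L]])
            if (!all(vapply(gsets, function(g) identical(sort(g), ref),
                            logical(1L))))
                return(sprintf("gene sets differ across %s replicates of %s",
                               cond, cl))
        }
    }
    TRUE
})
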