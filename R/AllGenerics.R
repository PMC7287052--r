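#' Per-gene z-score transform
#'
#' Standardizes each gene across the full analyzed cohort:
#' \code{(x - mean)/sd}, with the standard deviation computed over all
#' samples (population sd, \code{ddof = 0}, by default). Zero-variance genes
#' map to an all-zero row and are recorded as degenerate rather than raising
#' an error, so constant genes never satisfy an "up" or "down" rule.
#' Applying \code{zScore} to a \linkS4class{ZScoreExperiment} re-standardizes
#' and is idempotent up to numerical tolerance for non-degenerate genes.
#'
#' @param x numeric matrix (genes x samples, dimnames required), a
#'   \linkS4class{SummarizedExperiment} (first assay used), or a
#'   \linkS4class{ZScoreExperiment}.
#' @param ... passed to methods.
#' @param ddof delta degrees of freedom for the sd denominator
#'   \code{n - ddof}; \code{0} (population sd, the default) or \code{1}.
#' @return a \linkS4class{ZScoreExperiment}.
#' @examples
#' m <- matrix(c(1, 2, 3, 5, 5, 5), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
#' z <- zScore(m)
#' zMatrix(z)["A", ]        # -1.2247, 0, 1.2247
#' degenerateGenes(z)       # "B"
#' @export
setGeneric("zScore", function(x, ...) standardGeneric("zScore"))

#' @describeIn ZScoreExperiment genes with zero variance in the source
#'   matrix (all-zero z rows).
#' @param x a ZScoreExperiment.
#' @export
setGeneric("degenerateGenes", function(x) standardGeneric("degenerateGenes"))

#' @describeIn ZScoreExperiment the z-score matrix (genes x samples).
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))

#' @describeIn MutationTable the record data.frame.
#' @param x a MutationTable.
#' @export
setGeneric("mutationRecords", function(x) standardGeneric("mutationRecords"))

#' @describeIn MutationTable the profiled sample identifiers.
#' @export
setGeneric("profiledSamples", function(x) standardGeneric("profiledSamples"))

#' @describeIn DirectionalGenePanel gene symbols of the panel.
#' @param x a DirectionalGenePanel.
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))

#' @describeIn DirectionalGenePanel required direction per gene (named).
#' @export
setGeneric("panelDirections",
           function(x) standardGeneric("panelDirections"))

#' @describeIn DirectionalGenePanel z-score threshold of the panel.
#' @export
setGeneric("panelThreshold", function(x) standardGeneric("panelThreshold"))

#' @describeIn SyntheticCohort expression as a SummarizedExperiment.
#' @param x a SyntheticCohort.
#' @export
setGeneric("cohortExpression",
           function(x) standardGeneric("cohortExpression"))

#' @describeIn SyntheticCohort mutation records as a MutationTable.
#' @export
setGeneric("cohortMutations",
           function(x) standardGeneric("cohortMutations"))

#' @describeIn SyntheticCohort clinical table.
#' @export
setGeneric("cohortClinical", function(x) standardGeneric("cohortClinical"))

#' @describeIn SyntheticCohort planted per-sample truth.
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @describeIn PerturbationExperiment long-format data.frame.
#' @param x a PerturbationExperiment.
#' @export
setGeneric("perturbationData",
           function(x) standardGeneric("perturbationData"))
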