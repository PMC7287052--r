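#' @rdname ZScoreExperiment-class
#' @aliases degenerateGenes,ZScoreExperiment-method
#' @export
setMethod("degenerateGenes", "ZScoreExperiment",
          function(x) x@degenerateGenes)

#' @rdname ZScoreExperiment-class
#' @aliases zMatrix,ZScoreExperiment-method
#' @export
setMethod("zMatrix", "ZScoreExperiment",
          function(x) SummarizedExperiment::assay(x, "zscore"))

setMethod("show", "ZScoreExperiment", function(object) {
    callNextMethod()
    cat(sprintf("degenerate genes: %d\n",
                length(object@degenerateGenes)))
})

#' Construct a MutationTable
#'
#' @param sample_id,gene,variant_class equal-length character vectors, one
#'   element per mutation record.
#' @param profiledSamples samples with mutation profiling; defaults to the
#'   samples appearing in the records.
#' @return a \linkS4class{MutationTable}.
#' @examples
#' MutationTable(c("s1", "s1", "s2"), c("TP53", "EP300", "TP53"),
#'               rep("Missense_Mutation", 3),
#'               profiledSamples = c("s1", "s2", "s3"))
#' @export
MutationTable <- function(sample_id = character(), gene = character(),
                          variant_class = character(),
                          profiledSamples = unique(as.character(sample_id))) {
    new("MutationTable",
        records = data.frame(sample_id = as.character(sample_id),
                             gene = as.character(gene),
                             variant_class = as.character(variant_class),
                             stringsAsFactors = FALSE),
        profiledSamples = as.character(profiledSamples))
}

#' @rdname MutationTable-class
#' @aliases mutationRecords,MutationTable-method
#' @export
setMethod("mutationRecords", "MutationTable", function(x) x@records)

#' @rdname MutationTable-class
#' @aliases profiledSamples,MutationTable-method
#' @export
setMethod("profiledSamples", "MutationTable", function(x) x@profiledSamples)

setMethod("show", "MutationTable", function(object) {
    cat(sprintf(paste0("MutationTable: %d records, %d genes, ",
                       "%d mutated of %d profiled samples\n"),
                nrow(object@records), length(unique(object@records$gene)),
                length(unique(object@records$sample_id)),
                length(object@profiledSamples)))
})

#' Construct a DirectionalGenePanel
#'
#' @param name panel name.
#' @param up,down gene symbols required above / below the threshold.
#' @param threshold z-score cut point (strict inequalities on both sides).
#' @return a \linkS4class{DirectionalGenePanel}.
#' @examples
#' DirectionalGenePanel("cytact", up = c("GZMB", "PRF1"))
#' @export
DirectionalGenePanel <- function(name, up = character(), down = character(),
                                 threshold = 0) {
    new("DirectionalGenePanel", name = name,
        genes = c(up, down),
        directions = c(rep("up", length(up)), rep("down", length(down))),
        threshold = threshold)
}

#' @rdname DirectionalGenePanel-class
#' @aliases panelGenes,DirectionalGenePanel-method
#' @export
setMethod("panelGenes", "DirectionalGenePanel", function(x) x@genes)

#' @rdname DirectionalGenePanel-class
#' @aliases panelDirections,DirectionalGenePanel-method
#' @export
setMethod("panelDirections", "DirectionalGenePanel",
          function(x) setNames(x@directions, x@genes))

#' @rdname DirectionalGenePanel-class
#' @aliases panelThreshold,DirectionalGenePanel-method
#' @export
setMethod("panelThreshold", "DirectionalGenePanel", function(x) x@threshold)

setMethod("show", "DirectionalGenePanel", function(object) {
    cat(sprintf("DirectionalGenePanel '%s' (tau = %g)\n",
                object@name, object@threshold))
    cat("  up:  ", paste(object@genes[object@directions == "up"],
                         collapse = ", "), "\n")
    cat("  down:", paste(object@genes[object@directions == "down"],
                         collapse = ", "), "\n")
})

setMethod("show", "SubtypeRuleSet", function(object) {
    cat("SubtypeRuleSet\n")
    for (p in c("activated", "suppressed", "absent")) show(slot(object, p))
})

#' @rdname SyntheticCohort-class
#' @aliases cohortExpression,SyntheticCohort-method
#' @export
setMethod("cohortExpression", "SyntheticCohort", function(x) x@expression)

#' @rdname SyntheticCohort-class
#' @aliases cohortMutations,SyntheticCohort-method
#' @export
setMethod("cohortMutations", "SyntheticCohort", function(x) x@mutations)

#' @rdname SyntheticCohort-class
#' @aliases cohortClinical,SyntheticCohort-method
#' @export
setMethod("cohortClinical", "SyntheticCohort", function(x) x@clinical)

#' @rdname SyntheticCohort-class
#' @aliases cohortTruth,SyntheticCohort-method
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)

setMethod("show", "SyntheticCohort", function(object) {
    tab <- table(object@truth$subtype)
    cat(sprintf("SyntheticCohort: %d samples, %d genes (seed %s)\n",
                ncol(object@expression), nrow(object@expression),
                format(object@config$seed)))
    cat("  planted subtypes:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

#' @rdname PerturbationExperiment-class
#' @aliases perturbationData,PerturbationExperiment-method
#' @export
setMethod("perturbationData", "PerturbationExperiment", function(x) x@data)

setMethod("show", "PerturbationExperiment", function(object) {
    d <- object@data
    cat(sprintf(paste0("PerturbationExperiment: %d cell line(s), ",
                       "%d genes, %d rows\n"),
                length(unique(d$cell_line)), length(unique(d$gene)),
                nrow(d)))
})
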