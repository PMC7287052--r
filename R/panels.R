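#' Default TIME subtype rule set
#'
#' Reconstructed from the marker list used for immunohistochemistry-anchored
#' TIME typing (CD45/PTPRC, CD8A, FOXP3, CD79A, CD68, granzyme B, perforin,
#' S100A9):
#' \itemize{
#'   \item activated: cytotoxic T-cell response genes up
#'     (PTPRC, CD8A, GZMB, PRF1);
#'   \item suppressed: cytotoxic genes down (CD8A, GZMB, PRF1) and the
#'     macrophage/MDSC markers CD68 and S100A9 up;
#'   \item absent: all eight immune markers down.
#' }
#' FOXP3 and CD79A are deliberately left out of the activated conjunction,
#' which is defined by cytotoxic response genes; pass
#' \code{allMarkersActivated = TRUE} to require all eight. The panels are a
#' reconstruction of the published figure rule and are fully overridable via
#' \code{\link{DirectionalGenePanel}} / \code{\link{readPanel}}.
#'
#' @param threshold z-score cut point shared by all three panels.
#' @param allMarkersActivated require all eight markers up for "activated".
#' @return a \linkS4class{SubtypeRuleSet}.
#' @export
defaultRuleSet <- function(threshold = 0, allMarkersActivated = FALSE) {
    act_up <- if (allMarkersActivated)
        c("PTPRC", "CD8A", "FOXP3", "CD79A", "CD68", "GZMB", "PRF1", "S100A9")
    else c("PTPRC", "CD8A", "GZMB", "PRF1")
    new("SubtypeRuleSet",
        activated = DirectionalGenePanel("activated", up = act_up,
                                         threshold = threshold),
        suppressed = DirectionalGenePanel(
            "suppressed", up = c("CD68", "S100A9"),
            down = c("CD8A", "GZMB", "PRF1"), threshold = threshold),
        absent = DirectionalGenePanel(
            "absent",
            down = c("PTPRC", "CD8A", "FOXP3", "CD79A", "CD68", "GZMB",
                     "PRF1", "S100A9"),
            threshold = threshold))
}

#' Immune marker genes of the default rule set
#' @return character vector of the eight marker symbols.
#' @export
immuneMarkerGenes <- function() {
    c("PTPRC", "CD8A", "FOXP3", "CD79A", "CD68", "GZMB", "PRF1", "S100A9")
}

#' Glycolysis and OXPHOS gene panels
#'
#' The shipped metabolic programs: 24 glycolysis enzymes/transporters
#' (glucose and pyruvate/lactate metabolism, including GLUT1 = SLC2A1, LDHA
#' and LDHB) and 31 mitochondrial respiratory-chain (complex I-V) proteins.
#' Symbols are stored as published; \code{\link{defaultAliasMap}} reconciles
#' GLUT1 with SLC2A1 at matrix-lookup time.
#'
#' @return named list with character vectors \code{glycolysis} (24) and
#'   \code{oxphos} (31).
#' @export
metabolicPanels <- function() {
    list(
        glycolysis = c("ALDOA", "ALDOB", "ALDOC", "BPGM", "ENO1", "ENO2",
                       "ENO3", "GALM", "GCK", "GPI", "HK2", "HK3", "PFKL",
                       "PGAM2", "PGK1", "PGK2", "PGM1", "PGM2", "PGM3",
                       "PKLR", "TPI1", "GLUT1", "LDHA", "LDHB"),
        oxphos = c("ATP12A", "ATP5A1", "ATP5F1", "ATP5G3", "ATP5J", "ATP5O",
                   "ATP6V1C2", "LHPP", "OXA1L", "PPA1", "COX4I1", "COX5B",
                   "COX6B1", "COX7A2", "COX8A", "BCS1L", "UQCRC1", "UQCRH",
                   "SDHA", "SDHC", "NDUFA1", "NDUFA2", "NDUFA5", "NDUFA8",
                   "NDUFB2", "NDUFB5", "NDUFB8", "NDUFC2", "NDUFS3",
                   "NDUFS6", "NDUFV1"))
}

#' Extend a gene panel with additional genes
#'
#' Concatenates and deduplicates after alias resolution (duplicates are
#' merged with a warning), preserving base-list order first. Used to widen
#' the 24-gene glycolysis and 31-gene OXPHOS programs with externally
#' supplied gene lists for perturbation-profiling platforms.
#'
#' @param base,extra character vectors of gene symbols.
#' @param aliasMap alias map used to detect duplicates across symbol
#'   variants.
#' @return character vector; length reported via attribute \code{"n"}.
#' @examples
#' length(panelExtension(metabolicPanels()$glycolysis,
#'                       c("GAPDH", "PKM", "ALDOA")))  # 26 (one overlap)
#' @export
panelExtension <- function(base, extra, aliasMap = defaultAliasMap()) {
    canonBase <- .canonical(base, aliasMap)
    canonExtra <- .canonical(extra, aliasMap)
    dupWithin <- duplicated(canonExtra)
    overlap <- (canonExtra %in% canonBase) & !dupWithin
    if (any(overlap) || any(dupWithin))
        warning(sprintf("merged %d duplicate gene(s) during panel extension",
                        sum(overlap) + sum(dupWithin)), call. = FALSE)
    out <- c(base, extra[!(canonExtra %in% canonBase) & !dupWithin])
    attr(out, "n") <- length(out)
    out
}

#' Read / write a DirectionalGenePanel as YAML
#'
#' Serialization format:
#' \code{{name, threshold, entries: [{gene, direction}]}}.
#'
#' @param path file path.
#' @return \code{readPanel}: a \linkS4class{DirectionalGenePanel}.
#' @export
readPanel <- function(path) {
    y <- yaml::read_yaml(path)
    genes <- vapply(y$entries, `[[`, character(1L), "gene")
    dirs <- vapply(y$entries, `[[`, character(1L), "direction")
    new("DirectionalGenePanel", name = y$name, genes = genes,
        directions = dirs,
        threshold = if (is.null(y$threshold)) 0 else y$threshold)
}

#' @rdname readPanel
#' @param panel a \linkS4class{DirectionalGenePanel}.
#' @return \code{writePanel}: invisibly, \code{path}.
#' @export
writePanel <- function(panel, path) {
    yaml::write_yaml(
        list(name = panel@name, threshold = panel@threshold,
             entries = mapply(function(g, d) list(gene = g, direction = d),
                              panel@genes, panel@directions,
                              SIMPLIFY = FALSE, USE.NAMES = FALSE)),
        path)
    invisible(path)
}

#' Extended metabolic panels shipped for perturbation profiling
#'
#' Merges the base 24/31-gene programs with the packaged synthetic extension
#' lists (see \code{inst/extdata}), yielding 52 glycolysis-associated and 116
#' OXPHOS-associated genes. The extension lists are synthetic stand-ins for
#' platform-specific gene lists and are labelled as such in their filenames.
#'
#' @return named list with \code{glycolysis} (52) and \code{oxphos} (116).
#' @export
extendedMetabolicPanels <- function() {
    base <- metabolicPanels()
    glyExt <- readLines(system.file(
        "extdata", "glycolysis_extension_synthetic.txt", package = "TIMEsig"))
    oxExt <- readLines(system.file(
        "extdata", "oxphos_extension_synthetic.txt", package = "TIMEsig"))
    list(glycolysis = suppressWarnings(
             panelExtension(base$glycolysis, glyExt)),
         oxphos = suppressWarnings(panelExtension(base$oxphos, oxExt)))
}
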