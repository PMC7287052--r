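# replicate-mean expression per gene for one cell line and condition
.replicateMeans <- function(d, cellLine, condition, genes = NULL) {
    dc <- d[d$cell_line == cellLine & d$condition == condition, ]
    if (nrow(dc) == 0L)
        stop("no ", condition, " replicates for cell line ", cellLine)
    m <- tapply(dc$value, dc$gene, mean)
    if (!is.null(genes)) m <- m[genes]
    m
}

#' Baseline panel-level characterization across cell lines
#'
#' Averages the control replicates per gene within each cell line, z-scores
#' every gene across cell lines, and summarizes each (cell line, panel) as
#' the mean z over panel genes plus a Welch t-test of the line's panel-gene
#' z-values against the same genes pooled over all other lines. Lines whose
#' panel genes are globally invariant give t = 0, p = 1.
#'
#' @param exp \linkS4class{PerturbationExperiment} with >= 2 cell lines.
#' @param panels named list of gene vectors.
#' @param aliasMap gene alias map.
#' @return data.frame with \code{cell_line}, \code{panel}, \code{mean_z},
#'   \code{t}, \code{p}, \code{n_genes}.
#' @export
baselinePanelLevel <- function(exp, panels = metabolicPanels(),
                               aliasMap = defaultAliasMap()) {
    d <- perturbationData(exp)
    lines <- sort(unique(d$cell_line))
    if (length(lines) < 2L) stop("baseline characterization needs >= 2 lines")
    genes <- sort(unique(d$gene))
    base <- vapply(lines, function(cl)
        .replicateMeans(d, cl, "control", genes), numeric(length(genes)))
    rownames(base) <- genes
    m <- rowMeans(base)
    s <- sqrt(rowSums((base - m)^2) / ncol(base))
    zb <- (base - m) / ifelse(s == 0, 1, s)
    zb[s == 0, ] <- 0
    out <- NULL
    for (pn in names(panels)) {
        idx <- .matchGenes(panels[[pn]], genes, aliasMap, required = FALSE)
        idx <- idx[!is.na(idx)]
        if (length(idx) < 2L)
            stop("panel ", pn, " has < 2 genes measured in the experiment")
        for (cl in lines) {
            x <- zb[idx, cl]
            y <- as.vector(zb[idx, setdiff(lines, cl)])
            if (sd(x) == 0 && sd(y) == 0) {
                tt <- list(statistic = 0, p.value = 1)
            } else tt <- stats::t.test(x, y)
            out <- rbind(out, data.frame(
                cell_line = cl, panel = pn, mean_z = mean(x),
                t = unname(tt$statistic), p = tt$p.value,
                n_genes = length(idx), stringsAsFactors = FALSE))
        }
    }
    rownames(out) <- NULL
    out
}

#' Paired panel shift after treatment
#'
#' For one cell line and panel: per gene, the replicate-mean expression under
#' control and under treatment, then a paired two-sided t-test across the
#' panel genes on the (treated - control) differences. The pairing unit is
#' the gene -- replicate counts may differ between arms -- so this equals the
#' one-sample t-test of the difference vector against zero. A zero difference
#' vector gives t = 0, p = 1.
#'
#' @param exp \linkS4class{PerturbationExperiment}.
#' @param cellLine cell line identifier.
#' @param panel character vector of panel genes.
#' @param panelName label carried into the result.
#' @param aliasMap gene alias map.
#' @return list with \code{cell_line}, \code{panel}, \code{per_gene}
#'   (data.frame gene/mean_control/mean_treated/difference), \code{t},
#'   \code{df}, \code{p}, \code{direction} (\code{"down"}, \code{"up"} or
#'   \code{"none"}) and \code{mean_difference}.
#' @export
treatmentShift <- function(exp, cellLine, panel, panelName = "panel",
                           aliasMap = defaultAliasMap()) {
    d <- perturbationData(exp)
    genes <- unique(d$gene[d$cell_line == cellLine])
    idx <- .matchGenes(panel, genes, aliasMap, required = FALSE)
    use <- genes[idx[!is.na(idx)]]
    if (length(use) < 2L)
        stop("panel coverage < 2 genes for cell line ", cellLine)
    ctrl <- .replicateMeans(d, cellLine, "control", use)
    trt <- .replicateMeans(d, cellLine, "treated", use)
    diffs <- trt - ctrl
    if (all(diffs == 0)) {
        t <- 0; df <- length(diffs) - 1L; p <- 1
    } else {
        tt <- stats::t.test(trt, ctrl, paired = TRUE)
        t <- unname(tt$statistic); df <- unname(tt$parameter)
        p <- tt$p.value
    }
    md <- mean(diffs)
    list(cell_line = cellLine, panel = panelName,
         per_gene = data.frame(gene = use, mean_control = unname(ctrl),
                               mean_treated = unname(trt),
                               difference = unname(diffs),
                               stringsAsFactors = FALSE),
         t = t, df = df, p = p,
         direction = if (md < 0) "down" else if (md > 0) "up" else "none",
         mean_difference = md)
}

#' Read / write perturbation experiment tables
#'
#' Long tab-delimited format with columns \code{cell_line},
#' \code{condition}, \code{replicate}, \code{gene}, \code{value}.
#'
#' @param path file path.
#' @return \code{readPerturbation}: a
#'   \linkS4class{PerturbationExperiment}.
#' @export
readPerturbation <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    new("PerturbationExperiment", data = df, metadata = list())
}

#' @rdname readPerturbation
#' @param exp a \linkS4class{PerturbationExperiment}.
#' @return \code{writePerturbation}: invisibly, \code{path}.
#' @export
writePerturbation <- function(exp, path) {
    write.table(perturbationData(exp), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
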