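.strataVector <- function(strata) {
    if (is.data.frame(strata)) {
        if (!all(c("sample_id", "stratum") %in% names(strata)))
            stop("strata data.frame needs sample_id and stratum columns")
        setNames(as.character(strata$stratum), strata$sample_id)
    } else if (!is.null(names(strata))) {
        setNames(as.character(strata), names(strata))
    } else stop("strata must be a data.frame or a named vector")
}

#' Per-gene upregulation frequencies within expression strata
#'
#' For every panel gene and every stratum, the fraction of stratum samples
#' with z strictly above zero ("upregulated"; degenerate all-zero genes are
#' never up). Strata are usually the high/low groups from
#' \code{\link{stratifyExpression}} but any sample partition works (e.g. a
#' mutated/wildtype split). Panel genes absent from the matrix are dropped
#' with a warning and recorded in the \code{"missing_genes"} attribute.
#'
#' @param z \linkS4class{ZScoreExperiment} or z-score matrix.
#' @param panels named list of gene vectors (default
#'   \code{\link{metabolicPanels}}).
#' @param strata data.frame from \code{\link{stratifyExpression}} or a named
#'   sample -> stratum vector.
#' @param exclude stratum levels to ignore (default \code{"mid"}).
#' @param aliasMap gene alias map.
#' @return data.frame with \code{gene}, \code{panel}, \code{stratum},
#'   \code{n}, \code{n_up}, \code{frac}.
#' @export
upregulationProfile <- function(z, panels = metabolicPanels(), strata,
                                exclude = "mid",
                                aliasMap = defaultAliasMap()) {
    zm <- .zmat(z)
    sv <- .strataVector(strata)
    sv <- sv[names(sv) %in% colnames(zm)]
    sv <- sv[!sv %in% exclude]
    levs <- unique(sv)
    if (length(levs) < 1L) stop("no usable strata")
    missing <- character()
    out <- NULL
    for (pn in names(panels)) {
        idx <- .matchGenes(panels[[pn]], rownames(zm), aliasMap,
                           required = FALSE)
        if (anyNA(idx)) {
            missing <- c(missing, panels[[pn]][is.na(idx)])
            warning(sprintf("panel %s: dropping %d gene(s) absent from %s",
                            pn, sum(is.na(idx)), "the matrix"),
                    call. = FALSE)
        }
        gsym <- panels[[pn]][!is.na(idx)]
        idx <- idx[!is.na(idx)]
        for (lv in levs) {
            cols <- names(sv)[sv == lv]
            if (length(cols) == 0L) stop("empty stratum: ", lv)
            up <- rowSums(zm[idx, cols, drop = FALSE] > 0)
            out <- rbind(out, data.frame(
                gene = gsym, panel = pn, stratum = lv,
                n = length(cols), n_up = as.integer(up),
                frac = up / length(cols), stringsAsFactors = FALSE))
        }
    }
    rownames(out) <- NULL
    attr(out, "missing_genes") <- unique(missing)
    out
}

#' Compare one gene's upregulation frequency between two strata
#'
#' Fisher 2x2 on (up / not-up) x (stratum A / stratum B) counts from an
#' upregulation profile.
#'
#' @param profile data.frame from \code{\link{upregulationProfile}}.
#' @param gene gene symbol.
#' @param strata the two stratum labels to compare (default high vs low).
#' @param alpha significance level for the flag.
#' @return list with \code{table}, \code{odds_ratio}, \code{p},
#'   \code{significant}.
#' @export
compareGeneUpregulation <- function(profile, gene,
                                    strata = c("high", "low"),
                                    alpha = 0.05) {
    rows <- profile[profile$gene == gene & profile$stratum %in% strata, ]
    if (nrow(rows) != 2L)
        stop("gene must appear in exactly the two requested strata")
    rows <- rows[match(strata, rows$stratum), ]
    tab <- rbind(up = rows$n_up, not_up = rows$n - rows$n_up)
    colnames(tab) <- strata
    ft <- fisherExact2x2(tab)
    list(table = tab, odds_ratio = ft$odds_ratio, p = ft$p,
         significant = ft$p < alpha)
}

#' Compare a panel's mean upregulation frequency between strata
#'
#' Unpaired two-tailed t-test over the per-gene upregulation fractions of one
#' panel, between two strata (Welch by default; set \code{varEqual = TRUE}
#' for the pooled-variance variant). Identical fraction vectors give t = 0,
#' p = 1.
#'
#' @param profile data.frame from \code{\link{upregulationProfile}}.
#' @param panel panel name.
#' @param strata the two stratum labels to compare.
#' @param varEqual pooled-variance t-test instead of Welch.
#' @return list with \code{mean} (named, per stratum), \code{t}, \code{df},
#'   \code{p}, \code{n_genes}.
#' @export
comparePanelMeans <- function(profile, panel, strata = c("high", "low"),
                              varEqual = FALSE) {
    sub <- profile[profile$panel == panel, ]
    x <- sub$frac[sub$stratum == strata[1L]]
    y <- sub$frac[sub$stratum == strata[2L]]
    if (length(x) < 2L || length(y) < 2L)
        stop("panel needs >= 2 genes with defined fractions in each stratum")
    means <- setNames(c(mean(x), mean(y)), strata)
    if (sd(x) == 0 && sd(y) == 0 && means[1L] == means[2L])
        return(list(mean = means, t = 0, df = NA_real_, p = 1,
                    n_genes = c(length(x), length(y))))
    tt <- stats::t.test(x, y, var.equal = varEqual)
    list(mean = means, t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value,
         n_genes = c(length(x), length(y)))
}

#' Relative glycolysis/OXPHOS phenotype per stratum
#'
#' Normalizes the two panels' mean upregulation fractions to sum to one
#' within each stratum, giving a relative metabolic phenotype (glycolysis
#' share vs OXPHOS share). Errors when both panel means are zero in a
#' stratum.
#'
#' @param profile data.frame from \code{\link{upregulationProfile}} with
#'   panels \code{glycolysis} and \code{oxphos}.
#' @return data.frame with \code{stratum}, \code{glycolysis_share},
#'   \code{oxphos_share} (each pair summing to 1).
#' @export
relativePhenotype <- function(profile) {
    levs <- unique(profile$stratum)
    out <- NULL
    for (lv in levs) {
        mg <- mean(profile$frac[profile$panel == "glycolysis" &
                                profile$stratum == lv])
        mo <- mean(profile$frac[profile$panel == "oxphos" &
                                profile$stratum == lv])
        if (mg + mo == 0) stop("both panel means are zero in stratum ", lv)
        out <- rbind(out, data.frame(stratum = lv,
                                     glycolysis_share = mg / (mg + mo),
                                     oxphos_share = mo / (mg + mo)))
    }
    rownames(out) <- NULL
    out
}

#' Export frequency-weighted gene lists for word-cloud rendering
#'
#' Writes one row per gene with its panel and upregulation fraction as the
#' weight, in stable (panel, gene) order; rendering itself is out of scope.
#'
#' @param profile data.frame from \code{\link{upregulationProfile}}.
#' @param stratum stratum label to export.
#' @param path output file path (tab-delimited).
#' @return invisibly, the exported data.frame.
#' @export
exportWordcloudWeights <- function(profile, stratum, path) {
    sub <- profile[profile$stratum == stratum,
                   c("gene", "panel", "frac")]
    names(sub)[3L] <- "weight"
    sub <- sub[order(sub$panel, sub$gene), ]
    write.table(sub, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(sub)
}
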