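.zscoreMatrix <- function(x, ddof = 0) {
    if (!is.numeric(x) || is.null(rownames(x)) || is.null(colnames(x)))
        stop("x must be a numeric matrix with gene and sample dimnames")
    if (anyNA(x)) stop("matrix contains missing values; impute at load time")
    n <- ncol(x)
    if (n < 2L)
        stop("z-scores are undefined for a single-sample matrix")
    if (!ddof %in% c(0, 1)) stop("ddof must be 0 or 1")
    m <- rowMeans(x)
    xc <- x - m
    s <- sqrt(rowSums(xc^2) / (n - ddof))
    degenerate <- s == 0
    s[degenerate] <- 1      # rows are exactly zero already
    z <- xc / s
    z[degenerate, ] <- 0
    new("ZScoreExperiment",
        SummarizedExperiment::SummarizedExperiment(
            assays = list(zscore = z)),
        degenerateGenes = rownames(x)[degenerate])
}

#' @rdname zScore
#' @export
setMethod("zScore", "matrix", function(x, ddof = 0) .zscoreMatrix(x, ddof))

#' @rdname zScore
#' @export
setMethod("zScore", "SummarizedExperiment", function(x, ddof = 0) {
    .zscoreMatrix(SummarizedExperiment::assay(x, 1L), ddof)
})

#' @rdname zScore
#' @export
setMethod("zScore", "ZScoreExperiment", function(x, ddof = 0) {
    .zscoreMatrix(zMatrix(x), ddof)
})
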