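#' Default non-synonymous variant classes
#'
#' The cBioPortal-style variant classes retained by
#' \code{\link{readMutations}} by default.
#'
#' @return character vector of variant class names.
#' @export
nonsynVariantClasses <- function() {
    c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
      "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins", "Splice_Site",
      "Translation_Start_Site", "Nonstop_Mutation")
}

# classes recognized as valid MAF vocabulary even when filtered out
.knownVariantClasses <- function() {
    c(nonsynVariantClasses(),
      "Silent", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "Intron", "RNA",
      "IGR", "Targeted_Region")
}

#' Default gene-symbol alias map
#'
#' Protein names and legacy symbols used interchangeably with HGNC symbols in
#' immune/metabolic marker lists: CD45 (PTPRC), GLUT1 (SLC2A1), perforin
#' (PRF1, sometimes written PFN1 in this context) and granzyme (GZMB).
#' Matching is case-sensitive after alias resolution; both the panel symbol
#' and the matrix symbol are canonicalized before comparison, so a matrix may
#' carry either form.
#'
#' @return named character vector mapping alias to canonical symbol.
#' @export
defaultAliasMap <- function() {
    c(CD45 = "PTPRC", GLUT1 = "SLC2A1", PFN1 = "PRF1",
      Perforin = "PRF1", Granzyme = "GZMB")
}

# canonical form of gene symbols under an alias map
.canonical <- function(genes, aliasMap = defaultAliasMap()) {
    hit <- genes %in% names(aliasMap)
    genes[hit] <- unname(aliasMap[genes[hit]])
    genes
}

# match query genes against available rownames after alias resolution;
# errors naming the first missing gene unless required = FALSE
.matchGenes <- function(query, available, aliasMap = defaultAliasMap(),
                        required = TRUE) {
    idx <- match(.canonical(query, aliasMap), .canonical(available, aliasMap))
    if (required && anyNA(idx))
        stop("gene(s) not present in matrix: ",
             paste(query[is.na(idx)], collapse = ", "), call. = FALSE)
    idx
}

#' Read a gene x sample expression matrix
#'
#' Reads a tab-delimited matrix in the cBioPortal export dialect: first
#' column \code{Hugo_Symbol} (or any gene-symbol column first), an optional
#' second column \code{Entrez_Gene_Id} (skipped), then one column per sample.
#' Duplicate gene rows are resolved by keeping the row with the highest mean
#' (with a warning). Missing values are a hard error unless
#' \code{impute = "row_mean"}.
#'
#' @param path file path.
#' @param impute \code{"none"} (error on missing values) or
#'   \code{"row_mean"}.
#' @return \linkS4class{SummarizedExperiment} with assay \code{"exprs"}.
#' @seealso \code{\link{writeExpression}}, \code{\link{zScore}}
#' @export
readExpression <- function(path, impute = c("none", "row_mean")) {
    impute <- match.arg(impute)
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                     na.strings = c("NA", ""))
    if (ncol(df) < 2L) stop("expression file needs gene + sample columns")
    genes <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
    if (ncol(df) >= 1L && identical(names(df)[1L], "Entrez_Gene_Id"))
        df <- df[, -1L, drop = FALSE]
    raw <- read.delim(path, check.names = FALSE, colClasses = "character")
    raw <- raw[, names(df), drop = FALSE]
    mat <- matrix(NA_real_, nrow(df), ncol(df),
                  dimnames = list(NULL, names(df)))
    for (j in seq_len(ncol(df))) {
        v <- suppressWarnings(as.numeric(df[[j]]))
        bad <- which(is.na(v) & !is.na(df[[j]]))
        if (length(bad))
            stop(sprintf("unparseable numeric cell '%s' at gene %s, sample %s",
                         raw[bad[1L], j], genes[bad[1L]], names(df)[j]),
                 call. = FALSE)
        mat[, j] <- v
    }
    if (anyNA(mat)) {
        if (impute == "none")
            stop("missing values in expression matrix; ",
                 "use impute = 'row_mean' to fill from row means",
                 call. = FALSE)
        for (i in which(rowSums(is.na(mat)) > 0L)) {
            fill <- mean(mat[i, ], na.rm = TRUE)
            if (is.nan(fill))
                stop("gene ", genes[i], " has no observed values",
                     call. = FALSE)
            mat[i, is.na(mat[i, ])] <- fill
        }
    }
    if (anyDuplicated(genes)) {
        keep <- rep(TRUE, nrow(mat))
        means <- rowMeans(mat)
        for (g in unique(genes[duplicated(genes)])) {
            rows <- which(genes == g)
            keep[setdiff(rows, rows[which.max(means[rows])])] <- FALSE
        }
        warning(sprintf("%d duplicate gene row(s) dropped, keeping the row %s",
                        sum(!keep), "with highest mean"), call. = FALSE)
        mat <- mat[keep, , drop = FALSE]
        genes <- genes[keep]
    }
    rownames(mat) <- genes
    if (anyDuplicated(colnames(mat))) stop("duplicate sample identifiers")
    SummarizedExperiment::SummarizedExperiment(assays = list(exprs = mat))
}

#' Write an expression matrix
#'
#' Tab-delimited, first column \code{Hugo_Symbol}; bit-stable for fixed
#' input. Round-trips through \code{\link{readExpression}} to within 1e-9.
#'
#' @param x SummarizedExperiment (first assay written) or numeric matrix.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeExpression <- function(x, path) {
    mat <- if (is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, 1L) else x
    df <- data.frame(Hugo_Symbol = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a MAF-like mutation table
#'
#' Requires columns \code{Tumor_Sample_Barcode}, \code{Hugo_Symbol} and
#' \code{Variant_Classification}. Only records whose class is in
#' \code{nonsynClasses} are retained; records with a class outside the known
#' MAF vocabulary are dropped with a warning. The profiled sample set is the
#' sidecar list when given, else the union of all sample ids appearing in the
#' file (before filtering).
#'
#' @param path file path.
#' @param nonsynClasses variant classes to keep.
#' @param sampleListPath optional sidecar file, one profiled sample id per
#'   line.
#' @return a \linkS4class{MutationTable}.
#' @export
readMutations <- function(path, nonsynClasses = nonsynVariantClasses(),
                          sampleListPath = NULL) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("missing required column(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
    profiled <- if (is.null(sampleListPath))
        unique(as.character(df$Tumor_Sample_Barcode))
    else unique(readLines(sampleListPath))
    profiled <- profiled[nzchar(profiled)]
    unknown <- setdiff(unique(df$Variant_Classification),
                       .knownVariantClasses())
    if (length(unknown))
        warning("dropping records with unknown variant class(es): ",
                paste(unknown, collapse = ", "), call. = FALSE)
    keep <- df$Variant_Classification %in% nonsynClasses
    MutationTable(sample_id = df$Tumor_Sample_Barcode[keep],
                  gene = df$Hugo_Symbol[keep],
                  variant_class = df$Variant_Classification[keep],
                  profiledSamples = profiled)
}

#' Write a MutationTable in the MAF-subset format
#'
#' @param mut a \linkS4class{MutationTable}.
#' @param path output file path.
#' @param sampleListPath optional path for the profiled-sample sidecar.
#' @return invisibly, \code{path}.
#' @export
writeMutations <- function(mut, path, sampleListPath = NULL) {
    rec <- mutationRecords(mut)
    df <- data.frame(Tumor_Sample_Barcode = rec$sample_id,
                     Hugo_Symbol = rec$gene,
                     Variant_Classification = rec$variant_class)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(sampleListPath))
        writeLines(profiledSamples(mut), sampleListPath)
    invisible(path)
}

#' Read a clinical table
#'
#' Tab-delimited with a \code{sample_id} column plus any of
#' \code{hpv_status} (\code{positive}/\code{negative}/\code{unknown}),
#' \code{anatomical_site}, \code{stage}, \code{os_time}, \code{os_event},
#' \code{dfs_time}, \code{dfs_event}. A missing \code{hpv_status} column is
#' filled with \code{"unknown"} (with a warning); negative times and
#' non-binary events are hard errors.
#'
#' @param path file path.
#' @return data.frame keyed by unique \code{sample_id}.
#' @export
readClinical <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(df)) stop("clinical table needs sample_id")
    df$sample_id <- as.character(df$sample_id)
    if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical")
    if (!"hpv_status" %in% names(df)) {
        warning("no hpv_status column; coding all samples as unknown",
                call. = FALSE)
        df$hpv_status <- "unknown"
    }
    df$hpv_status[is.na(df$hpv_status) |
                  !df$hpv_status %in% c("positive", "negative")] <- "unknown"
    for (tc in intersect(c("os_time", "dfs_time"), names(df))) {
        if (any(df[[tc]] < 0, na.rm = TRUE))
            stop("negative ", tc, " in clinical table", call. = FALSE)
    }
    for (ec in intersect(c("os_event", "dfs_event"), names(df))) {
        if (!all(df[[ec]] %in% c(0, 1, NA)))
            stop(ec, " must be 0/1", call. = FALSE)
    }
    df
}

#' Write a clinical table
#'
#' @param clinical data.frame as returned by \code{\link{readClinical}}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeClinical <- function(clinical, path) {
    write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
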