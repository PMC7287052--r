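# shared fixture builders; everything is generated in code

# genes x samples matrix with dimnames
mkMatrix <- function(values, genes, samples) {
    matrix(values, nrow = length(genes), byrow = TRUE,
           dimnames = list(genes, samples))
}

# a ZScoreExperiment with prescribed z values (validated per-row:
# callers must supply standardized or all-zero rows); for arbitrary values
# use zScore() on a raw matrix instead
mkZ <- function(mat) zScore(mat)

# write a small expression file and return its path
writeExprFile <- function(mat, path = tempfile(fileext = ".tsv")) {
    df <- data.frame(Hugo_Symbol = rownames(mat), mat, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

writeMafFile <- function(sample, gene, class,
                         path = tempfile(fileext = ".maf")) {
    df <- data.frame(Hugo_Symbol = gene, Tumor_Sample_Barcode = sample,
                     Variant_Classification = class)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

# brute-force two-sided Fisher p for a 2x2 table by hypergeometric
# enumeration (independent oracle for the log-space implementation)
oracleFisher2x2 <- function(tab) {
    a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
    r1 <- a + b; c1 <- a + c_; n <- sum(tab)
    if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
    av <- max(0, c1 - (n - r1)):min(r1, c1)
    probs <- dhyper(av, c1, n - c1, r1)
    pobs <- dhyper(a, c1, n - c1, r1)
    min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# assignment data.frame from a label vector
mkAssignment <- function(ids, labels) {
    data.frame(sample_id = ids,
               subtype = factor(labels,
                                levels = c("activated", "suppressed",
                                           "absent", "unclassified")),
               stringsAsFactors = FALSE)
}

# truth labels of a cohort as an assignment table
truthAssignment <- function(cohort) {
    tr <- cohortTruth(cohort)
    mkAssignment(tr$sample_id, tr$subtype)
}
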