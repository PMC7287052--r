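.zmat <- function(z) {
    if (is(z, "ZScoreExperiment")) zMatrix(z)
    else if (is.matrix(z)) z
    else stop("expected a ZScoreExperiment or a z-score matrix")
}

# logical vector over samples: does each sample satisfy the panel?
.panelSatisfiedAll <- function(zm, panel, aliasMap = defaultAliasMap()) {
    idx <- .matchGenes(panel@genes, rownames(zm), aliasMap)
    tau <- panel@threshold
    up <- idx[panel@directions == "up"]
    dn <- idx[panel@directions == "down"]
    ok <- rep(TRUE, ncol(zm))
    if (length(up))
        ok <- ok & colSums(zm[up, , drop = FALSE] > tau) == length(up)
    if (length(dn))
        ok <- ok & colSums(zm[dn, , drop = FALSE] < tau) == length(dn)
    setNames(ok, colnames(zm))
}

#' Does a sample satisfy a directional gene panel?
#'
#' TRUE iff every "up" gene has z strictly above the panel threshold and
#' every "down" gene strictly below it. A z-score exactly at the threshold
#' satisfies neither direction, so boundary samples fail the panel.
#'
#' @param z \linkS4class{ZScoreExperiment} or z-score matrix.
#' @param sample sample identifier (must be a column).
#' @param panel \linkS4class{DirectionalGenePanel}.
#' @param aliasMap gene alias map (see \code{\link{defaultAliasMap}}).
#' @return logical scalar.
#' @export
panelSatisfied <- function(z, sample, panel, aliasMap = defaultAliasMap()) {
    zm <- .zmat(z)
    if (!sample %in% colnames(zm)) stop("unknown sample: ", sample)
    unname(.panelSatisfiedAll(zm, panel, aliasMap)[sample])
}

#' Assign TIME subtypes from a rule set
#'
#' A sample is labelled with a subtype iff it satisfies exactly one of the
#' three panels; samples satisfying zero panels (or, for custom rule sets,
#' more than one) are \code{"unclassified"} and excluded from downstream
#' subtype analyses. With the default rules no sample can satisfy two panels
#' because the panels place conflicting directions on the cytotoxic genes.
#'
#' @param z \linkS4class{ZScoreExperiment} or z-score matrix.
#' @param rules \linkS4class{SubtypeRuleSet}.
#' @param aliasMap gene alias map.
#' @return data.frame with \code{sample_id} and factor \code{subtype}
#'   (levels activated, suppressed, absent, unclassified).
#' @examples
#' cohort <- simulateCohort(cohortConfig(nSamples = 100, seed = 1))
#' z <- zScore(cohortExpression(cohort))
#' table(assignSubtypes(z)$subtype)
#' @export
assignSubtypes <- function(z, rules = defaultRuleSet(),
                           aliasMap = defaultAliasMap()) {
    zm <- .zmat(z)
    sat <- cbind(activated = .panelSatisfiedAll(zm, rules@activated, aliasMap),
                 suppressed = .panelSatisfiedAll(zm, rules@suppressed,
                                                 aliasMap),
                 absent = .panelSatisfiedAll(zm, rules@absent, aliasMap))
    n <- rowSums(sat)
    lab <- rep("unclassified", ncol(zm))
    one <- n == 1L
    lab[one] <- colnames(sat)[max.col(1 * sat[one, , drop = FALSE])]
    data.frame(sample_id = colnames(zm),
               subtype = factor(lab, levels = c("activated", "suppressed",
                                                "absent", "unclassified")),
               stringsAsFactors = FALSE)
}

#' Call cytolytic activity from granzyme/perforin co-regulation
#'
#' Cytolytic activity (CytAct) is \code{"up"} when both marker genes are
#' strictly above the threshold, \code{"down"} when both are strictly below
#' it, and \code{"neither"} otherwise (including discordant pairs and exact
#' ties). Under independent standard-normal genes, P(up) converges to 1/4.
#'
#' @param z \linkS4class{ZScoreExperiment} or z-score matrix.
#' @param genes the two marker genes (default granzyme B and perforin).
#' @param tau z-score threshold.
#' @param aliasMap gene alias map.
#' @return data.frame with \code{sample_id} and factor \code{cytact}
#'   (levels up, down, neither).
#' @export
callCytAct <- function(z, genes = c("GZMB", "PRF1"), tau = 0,
                       aliasMap = defaultAliasMap()) {
    zm <- .zmat(z)
    idx <- .matchGenes(genes, rownames(zm), aliasMap)
    zg <- zm[idx, , drop = FALSE]
    lab <- ifelse(colSums(zg > tau) == length(idx), "up",
           ifelse(colSums(zg < tau) == length(idx), "down", "neither"))
    data.frame(sample_id = colnames(zm),
               cytact = factor(lab, levels = c("up", "down", "neither")),
               stringsAsFactors = FALSE)
}

#' Stratify samples by one gene's z-score
#'
#' \code{"high"} iff z >= +kappa, \code{"low"} iff z <= -kappa, otherwise
#' \code{"mid"}; the boundaries are inclusive so ties at +/-kappa are
#' deterministic. With kappa = 1 and a standard-normal gene, about 15.9\% of
#' samples land in each extreme stratum.
#'
#' @param z \linkS4class{ZScoreExperiment} or z-score matrix.
#' @param gene the stratifying gene (e.g. a chromatin regulator whose
#'   expression level defines high/low expresser groups).
#' @param kappa z-score magnitude defining the strata (default 1).
#' @param aliasMap gene alias map.
#' @return data.frame with \code{sample_id} and factor \code{stratum}
#'   (levels high, low, mid); attributes \code{gene} and \code{kappa}.
#' @export
stratifyExpression <- function(z, gene, kappa = 1,
                               aliasMap = defaultAliasMap()) {
    zm <- .zmat(z)
    idx <- .matchGenes(gene, rownames(zm), aliasMap)
    zg <- zm[idx, ]
    lab <- ifelse(zg >= kappa, "high", ifelse(zg <= -kappa, "low", "mid"))
    out <- data.frame(sample_id = colnames(zm),
                      stratum = factor(lab, levels = c("high", "low", "mid")),
                      stringsAsFactors = FALSE)
    attr(out, "gene") <- gene
    attr(out, "kappa") <- kappa
    out
}

#' Subtype x covariate summary table
#'
#' Per-subtype counts and integer percentages for each categorical covariate
#' level, plus pairwise Fisher exact p-values between subtypes for each
#' level (level vs all other levels, 2x2). Subtypes with zero samples yield
#' an empty row and no test, with a warning.
#'
#' @param assignment data.frame from \code{\link{assignSubtypes}}.
#' @param clinical clinical data.frame with \code{sample_id}.
#' @param covariates clinical column names to summarize.
#' @param includeUnclassified also tabulate the unclassified samples.
#' @return list with data.frames \code{counts} (subtype, covariate, level,
#'   n, count, pct) and \code{tests} (covariate, level, group_a, group_b, p).
#' @export
subtypeSummary <- function(assignment, clinical,
                           covariates = c("hpv_status"),
                           includeUnclassified = FALSE) {
    df <- merge(assignment, clinical, by = "sample_id")
    lev <- c("activated", "suppressed", "absent")
    if (includeUnclassified) lev <- c(lev, "unclassified")
    counts <- NULL
    tests <- NULL
    for (cov in covariates) {
        if (!cov %in% names(df)) stop("covariate not in clinical: ", cov)
        for (st in lev) {
            sub <- df[df$subtype == st, ]
            if (nrow(sub) == 0L) {
                warning("subtype '", st, "' has no samples; skipping tests",
                        call. = FALSE)
                counts <- rbind(counts, data.frame(
                    subtype = st, covariate = cov, level = NA_character_,
                    n = 0L, count = 0L, pct = NA_real_))
                next
            }
            for (lv in sort(unique(as.character(df[[cov]])))) {
                k <- sum(sub[[cov]] == lv)
                counts <- rbind(counts, data.frame(
                    subtype = st, covariate = cov, level = lv,
                    n = nrow(sub), count = k,
                    pct = round(100 * k / nrow(sub))))
            }
        }
        present <- lev[vapply(lev, function(s) any(df$subtype == s),
                              logical(1L))]
        if (length(present) >= 2L) {
            pairs <- utils::combn(present, 2L)
            for (j in seq_len(ncol(pairs))) {
                a <- df[df$subtype == pairs[1L, j], cov]
                b <- df[df$subtype == pairs[2L, j], cov]
                for (lv in sort(unique(as.character(df[[cov]])))) {
                    tab <- rbind(c(sum(a == lv), sum(a != lv)),
                                 c(sum(b == lv), sum(b != lv)))
                    tests <- rbind(tests, data.frame(
                        covariate = cov, level = lv,
                        group_a = pairs[1L, j], group_b = pairs[2L, j],
                        p = fisherExact2x2(tab)$p))
                }
            }
        }
    }
    list(counts = counts, tests = tests)
}
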