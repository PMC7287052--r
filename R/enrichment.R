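#' Per-gene mutation statistics and the minimum-count filter
#'
#' Counts mutation records per gene (several records of one gene in one
#' patient all count) and distinct mutated patients, with frequencies over
#' the profiled sample set, and keeps genes with at least \code{minCount}
#' records. The record-level count drives the filter; patient-level status
#' drives all downstream contingency tables.
#'
#' @param mut \linkS4class{MutationTable}.
#' @param minCount minimum number of mutation records (default 10).
#' @return data.frame sorted by \code{mutation_count} descending (ties
#'   alphabetical) with columns \code{gene}, \code{mutation_count},
#'   \code{mutated_patient_count}, \code{patient_frequency},
#'   \code{count_frequency}.
#' @examples
#' mut <- MutationTable(sprintf("s%02d", 1:10), rep("TP53", 10),
#'                      rep("Missense_Mutation", 10),
#'                      profiledSamples = sprintf("s%02d", 1:512))
#' round(100 * filterGenes(mut)$count_frequency, 2)  # 1.95
#' @export
filterGenes <- function(mut, minCount = 10) {
    rec <- mutationRecords(mut)
    nprof <- length(profiledSamples(mut))
    if (nprof == 0L) stop("no profiled samples")
    if (nrow(rec) == 0L)
        return(data.frame(gene = character(), mutation_count = integer(),
                          mutated_patient_count = integer(),
                          patient_frequency = numeric(),
                          count_frequency = numeric()))
    cnt <- table(rec$gene)
    pat <- tapply(rec$sample_id, rec$gene,
                  function(s) length(unique(s)))
    out <- data.frame(gene = names(cnt),
                      mutation_count = as.integer(cnt),
                      mutated_patient_count = as.integer(pat[names(cnt)]),
                      stringsAsFactors = FALSE)
    out$patient_frequency <- out$mutated_patient_count / nprof
    out$count_frequency <- out$mutation_count / nprof
    out <- out[out$mutation_count >= minCount, , drop = FALSE]
    out <- out[order(-out$mutation_count, out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# patient-level mutation status for one gene over a sample set
.mutStatus <- function(mut, gene, samples) {
    rec <- mutationRecords(mut)
    setNames(samples %in% rec$sample_id[rec$gene == gene], samples)
}

.screenOneStratum <- function(mut, gene, bySubtype, alpha) {
    lev <- names(bySubtype)
    mutN <- integer(length(lev)); wtN <- integer(length(lev))
    for (k in seq_along(lev)) {
        st <- .mutStatus(mut, gene, bySubtype[[k]])
        mutN[k] <- sum(st); wtN[k] <- sum(!st)
    }
    tab <- rbind(mutated = mutN, wildtype = wtN)
    colnames(tab) <- lev
    omnibus <- fisherExact2x3(tab)
    pw <- vapply(seq_along(lev), function(k) {
        fisherExact2x2(cbind(c(mutN[k], wtN[k]),
                             c(sum(mutN[-k]), sum(wtN[-k]))))$p
    }, numeric(1L))
    frac <- mutN / pmax(1L, mutN + wtN)
    direction <- if (sum(mutN) == 0L) NA_character_ else lev[which.max(frac)]
    data.frame(gene = gene,
               mutated_activated = mutN[1L], wildtype_activated = wtN[1L],
               mutated_suppressed = mutN[2L], wildtype_suppressed = wtN[2L],
               mutated_absent = mutN[3L], wildtype_absent = wtN[3L],
               omnibus_p = omnibus,
               pairwise_p_activated = pw[1L], pairwise_p_suppressed = pw[2L],
               pairwise_p_absent = pw[3L],
               direction = direction,
               significant = omnibus < alpha,
               stringsAsFactors = FALSE)
}

#' Screen mutated genes for TIME-subtype enrichment
#'
#' For each gene, builds the patient-level mutated/wildtype x subtype
#' contingency table over the classified samples (unclassified excluded)
#' intersected with the profiled set, computes the omnibus Freeman-Halton
#' 2x3 p-value, pairwise 2x2 p-values (each subtype vs the pooled others),
#' the direction (subtype with the largest mutated fraction) and
#' Benjamini-Hochberg q-values. When a clinical table with HPV status is
#' supplied and \code{hpvStratify = TRUE}, the screen is additionally run
#' within the HPV-positive and HPV-negative strata.
#'
#' @param assignment data.frame from \code{\link{assignSubtypes}}.
#' @param mut \linkS4class{MutationTable}.
#' @param genes genes to screen; default: genes passing
#'   \code{\link{filterGenes}} at \code{minCount}.
#' @param alpha significance level for the \code{significant} flag (raw
#'   omnibus p; q-values are reported alongside).
#' @param clinical optional clinical data.frame (for HPV strata).
#' @param hpvStratify also screen within HPV-positive/negative samples.
#' @param minCount record-count filter used when \code{genes} is NULL.
#' @return data.frame, one row per gene per stratum (column \code{stratum}:
#'   \code{all}, \code{hpv_positive}, \code{hpv_negative}).
#' @export
enrichmentScreen <- function(assignment, mut, genes = NULL, alpha = 0.05,
                             clinical = NULL, hpvStratify = FALSE,
                             minCount = 10) {
    keep <- assignment$subtype != "unclassified" &
        assignment$sample_id %in% profiledSamples(mut)
    cls <- assignment[keep, , drop = FALSE]
    if (length(unique(droplevels(cls$subtype))) < 2L)
        stop("need at least two non-empty subtypes among classified samples")
    if (is.null(genes)) genes <- filterGenes(mut, minCount)$gene
    if (length(genes) == 0L) stop("no genes to screen")
    strata <- list(all = cls)
    if (hpvStratify) {
        if (is.null(clinical) || !"hpv_status" %in% names(clinical))
            stop("hpvStratify requires a clinical table with hpv_status")
        m <- merge(cls, clinical[, c("sample_id", "hpv_status")],
                   by = "sample_id")
        strata$hpv_positive <- m[m$hpv_status == "positive", ]
        strata$hpv_negative <- m[m$hpv_status == "negative", ]
    }
    out <- NULL
    for (sn in names(strata)) {
        cs <- strata[[sn]]
        if (nrow(cs) == 0L) next
        bySubtype <- lapply(c("activated", "suppressed", "absent"),
                            function(s) cs$sample_id[cs$subtype == s])
        names(bySubtype) <- c("activated", "suppressed", "absent")
        res <- do.call(rbind, lapply(genes, function(g)
            .screenOneStratum(mut, g, bySubtype, alpha)))
        res$q_value <- p.adjust(res$omnibus_p, method = "BH")
        res$stratum <- sn
        out <- rbind(out, res)
    }
    rownames(out) <- NULL
    out
}

#' Association of one gene's mutation status with cytolytic activity
#'
#' Fisher 2x2 of patient-level mutated/wildtype status against the CytAct
#' up/down call; samples called \code{"neither"} are excluded.
#'
#' @param mutStatus named logical vector (sample -> mutated) or data.frame
#'   with \code{sample_id} and logical \code{mutated}.
#' @param cytact data.frame from \code{\link{callCytAct}}.
#' @return list with the 2x2 \code{table} (mutated/wildtype x up/down),
#'   \code{odds_ratio} and \code{p}.
#' @export
cytactAssociation <- function(mutStatus, cytact) {
    if (is.data.frame(mutStatus))
        mutStatus <- setNames(mutStatus$mutated, mutStatus$sample_id)
    use <- cytact[cytact$cytact %in% c("up", "down"), ]
    if (nrow(use) == 0L)
        stop("no samples with an up or down cytolytic activity call")
    st <- mutStatus[use$sample_id]
    tab <- rbind(mutated = c(up = sum(st & use$cytact == "up"),
                             down = sum(st & use$cytact == "down")),
                 wildtype = c(sum(!st & use$cytact == "up"),
                              sum(!st & use$cytact == "down")))
    ft <- fisherExact2x2(tab)
    list(table = tab, odds_ratio = ft$odds_ratio, p = ft$p)
}

#' Tabulate mutations per protein domain with CytAct-up percentages
#'
#' Domain labels are supplied with the mutation records (no domain mapping is
#' performed); labels outside \code{knownDomains} (when given), empty or
#' missing labels are bucketed as \code{"other"}. Domains with zero mutations
#' are omitted.
#'
#' @param domains character vector, one protein-domain label per mutation
#'   record.
#' @param cytactUp logical vector, whether the carrying tumor had
#'   up-regulated cytolytic activity.
#' @param knownDomains optional domain vocabulary.
#' @return data.frame with \code{domain}, \code{n_mutations},
#'   \code{n_cytact_up}, \code{pct_cytact_up} (one decimal place).
#' @examples
#' domainTabulation(rep("TAZ1", 8), c(rep(TRUE, 3), rep(FALSE, 5)))
#' @export
domainTabulation <- function(domains, cytactUp, knownDomains = NULL) {
    stopifnot(length(domains) == length(cytactUp))
    domains <- as.character(domains)
    bad <- is.na(domains) | !nzchar(domains)
    if (!is.null(knownDomains)) bad <- bad | !domains %in% knownDomains
    domains[bad] <- "other"
    tot <- table(domains)
    up <- tapply(cytactUp, domains, sum)
    out <- data.frame(domain = names(tot),
                      n_mutations = as.integer(tot),
                      n_cytact_up = as.integer(up[names(tot)]),
                      stringsAsFactors = FALSE)
    out$pct_cytact_up <- round(100 * out$n_cytact_up / out$n_mutations, 1)
    rownames(out) <- NULL
    out
}
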