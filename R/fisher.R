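# Exact contingency tests, implemented in stable log-space.
#
# Both tests condition on the table margins and use the point-probability
# rule for two-sidedness: the p-value sums the hypergeometric probabilities
# of every margin-compatible table whose probability does not exceed the
# observed table's (with the customary 1 + 1e-7 relative slack against
# floating-point ties).

.relErr <- log1p(1e-7)

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric point probabilities at or
#' below the observed table's probability. The reported odds ratio is the
#' sample (cross-product) odds ratio; it is \code{NaN} when a margin is
#' empty, in which case p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list with \code{odds_ratio} and \code{p}.
#' @examples
#' fisherExact2x2(matrix(c(2, 0, 0, 2), 2))$p  # 1/3
#' @export
fisherExact2x2 <- function(tab) {
    tab <- as.matrix(tab)
    if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) || any(tab != round(tab)))
        stop("tab must be a 2x2 matrix of non-negative integers")
    a <- tab[1L, 1L]; b <- tab[1L, 2L]; c_ <- tab[2L, 1L]; d <- tab[2L, 2L]
    r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
    or <- (a * d) / (b * c_)
    if (r1 == 0L || r2 == 0L || c1 == 0L || c1 == n)
        return(list(odds_ratio = NaN, p = 1))
    av <- max(0L, c1 - r2):min(r1, c1)
    logp <- lchoose(r1, av) + lchoose(r2, c1 - av) - lchoose(n, c1)
    pobs <- logp[av == a]
    p <- min(1, sum(exp(logp[logp <= pobs + .relErr])))
    list(odds_ratio = or, p = p)
}

#' Freeman-Halton exact test on a 2x3 table
#'
#' Extension of Fisher's exact test to 2x3 tables: enumerates every table
#' with the observed margins and sums the probabilities of those no more
#' probable than the observed table. Enumeration is vectorized over the two
#' free cells of the first row, so margins in the hundreds remain fast.
#' A zero row margin gives p = 1.
#'
#' @param tab 2x3 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @examples
#' fisherExact2x3(rbind(c(1, 1, 1), c(9, 9, 9)))  # 1: observed is modal
#' @export
fisherExact2x3 <- function(tab) {
    tab <- as.matrix(tab)
    if (!all(dim(tab) == c(2L, 3L)) || any(tab < 0) || any(tab != round(tab)))
        stop("tab must be a 2x3 matrix of non-negative integers")
    r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ])
    cs <- colSums(tab); n <- r1 + r2
    if (r1 == 0L || r2 == 0L) return(1)
    av <- 0L:min(r1, cs[1L])
    bv <- 0L:min(r1, cs[2L])
    A <- matrix(av, length(av), length(bv))
    B <- matrix(bv, length(av), length(bv), byrow = TRUE)
    Cc <- r1 - A - B
    valid <- Cc >= 0L & Cc <= cs[3L]
    logp <- lchoose(cs[1L], A) + lchoose(cs[2L], B) + lchoose(cs[3L], Cc) -
        lchoose(n, r1)
    logp[!valid] <- -Inf
    pobs <- logp[av == tab[1L, 1L], bv == tab[1L, 2L]]
    min(1, sum(exp(logp[valid & logp <= pobs + .relErr])))
}
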