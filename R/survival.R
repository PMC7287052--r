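#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimator S(t) = prod over event times t_i <= t of
#' (1 - d_i/n_i), with Greenwood standard errors. Censoring at an event time
#' counts as at risk through that time (the standard convention). Fitting is
#' delegated to \code{survival::survfit}; the hand product-limit computation
#' serves as the test oracle.
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return data.frame with \code{time}, \code{n_risk}, \code{n_event},
#'   \code{survival}, \code{std_err} (Greenwood SE of S).
#' @examples
#' kmEstimate(c(1, 2, 3), c(1, 1, 0))$survival  # 2/3, 1/3, 1/3
#' @export
kmEstimate <- function(times, events) {
    if (length(times) == 0L) stop("empty survival input")
    if (any(times < 0)) stop("times must be non-negative")
    if (!all(events %in% c(0, 1))) stop("events must be 0/1")
    fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                             conf.type = "none")
    data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
               survival = fit$surv, std_err = fit$surv * fit$std.err)
}

#' Gehan-Wilcoxon (Gehan-Breslow) two-group survival test
#'
#' Weighted log-rank test with weights w_i = n_i (the total number at risk),
#' which emphasizes early event times -- the "Wilcoxon" test of
#' Kaplan-Meier software. At each distinct event time the observed events in
#' group A are compared with their hypergeometric expectation; the statistic
#' is (sum w_i (d_iA - e_iA))^2 / sum w_i^2 v_i, referred to a chi-square
#' with 1 df. \code{weights = "logrank"} sets w_i = 1, recovering the
#' standard log-rank test. With no events in either group, p = 1.
#'
#' @param timesA,eventsA,timesB,eventsB per-group times and 0/1 event
#'   indicators.
#' @param weights \code{"gehan"} (default) or \code{"logrank"}.
#' @return list with \code{statistic}, \code{p}, \code{n} (group sizes),
#'   \code{observed} and \code{expected} events in group A.
#' @export
gehanWilcoxonTest <- function(timesA, eventsA, timesB, eventsB,
                              weights = c("gehan", "logrank")) {
    weights <- match.arg(weights)
    if (length(timesA) == 0L || length(timesB) == 0L)
        stop("both groups must be nonempty")
    time <- c(timesA, timesB)
    event <- c(eventsA, eventsB)
    inA <- rep(c(TRUE, FALSE), c(length(timesA), length(timesB)))
    et <- sort(unique(time[event == 1]))
    if (length(et) == 0L)
        return(list(statistic = 0, p = 1,
                    n = c(length(timesA), length(timesB)),
                    observed = 0, expected = 0))
    U <- 0; V <- 0; obs <- 0; expc <- 0
    for (t in et) {
        atRisk <- time >= t
        n <- sum(atRisk)
        nA <- sum(atRisk & inA)
        d <- sum(event == 1 & time == t)
        dA <- sum(event == 1 & time == t & inA)
        e <- d * nA / n
        v <- if (n > 1L) d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
             else 0
        w <- if (weights == "gehan") n else 1
        U <- U + w * (dA - e)
        V <- V + w^2 * v
        obs <- obs + dA; expc <- expc + e
    }
    stat <- if (V > 0) U^2 / V else 0
    list(statistic = stat,
         p = if (V > 0) pchisq(stat, df = 1, lower.tail = FALSE) else 1,
         n = c(length(timesA), length(timesB)),
         observed = obs, expected = expc)
}

#' Survival of the immune-activated subtype vs the rest
#'
#' Kaplan-Meier curves and the Gehan-Wilcoxon test for the immune-activated
#' group against the pooled immune-suppressed + immune-absent group;
#' unclassified samples are excluded from both arms.
#'
#' @param assignment data.frame from \code{\link{assignSubtypes}}.
#' @param clinical clinical data.frame with \code{os_time}/\code{os_event}
#'   and/or \code{dfs_time}/\code{dfs_event}.
#' @param endpoint \code{"OS"} (overall survival) or \code{"DFS"}
#'   (disease-free survival).
#' @param weights passed to \code{\link{gehanWilcoxonTest}}.
#' @return list with \code{curves} (stacked KM data.frame with a
#'   \code{group} column), \code{test} and \code{n} (per-group sizes).
#' @export
compareActivatedVsRest <- function(assignment, clinical,
                                   endpoint = c("OS", "DFS"),
                                   weights = "gehan") {
    endpoint <- match.arg(endpoint)
    tc <- if (endpoint == "OS") "os_time" else "dfs_time"
    ec <- if (endpoint == "OS") "os_event" else "dfs_event"
    df <- merge(assignment, clinical, by = "sample_id")
    if (!all(c(tc, ec) %in% names(df)))
        stop("clinical table lacks ", tc, "/", ec)
    df <- df[df$subtype != "unclassified" &
             !is.na(df[[tc]]) & !is.na(df[[ec]]), ]
    a <- df[df$subtype == "activated", ]
    b <- df[df$subtype %in% c("suppressed", "absent"), ]
    if (nrow(a) == 0L || nrow(b) == 0L)
        stop("need >= 1 activated and >= 1 suppressed/absent sample with ",
             endpoint)
    curves <- rbind(cbind(kmEstimate(a[[tc]], a[[ec]]), group = "activated"),
                    cbind(kmEstimate(b[[tc]], b[[ec]]),
                          group = "suppressed_absent"))
    test <- gehanWilcoxonTest(a[[tc]], a[[ec]], b[[tc]], b[[ec]], weights)
    list(curves = curves, test = test,
         n = c(activated = nrow(a), rest = nrow(b)))
}
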