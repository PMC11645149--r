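# Signature-based patient stratification: step-threshold fitting,
# Kaplan-Meier estimation and log-rank testing.

#' Fit a one-step (two-level) threshold to a vector of scores
#'
#' StepMiner-style fit: over the sorted values, choose the split that
#' minimizes the total within-segment squared error of a two-level step
#' function; the threshold is the midpoint of the two segment means. Ties
#' are broken toward the smaller split index. A constant vector is
#' degenerate: the threshold is that constant and the fit is flagged.
#'
#' @param values Non-empty numeric vector.
#' @return An object of class `StepFit`: list with `threshold`,
#'   `low_mean`, `high_mean`, `sse`, `split_index` (number of values in the
#'   low segment after sorting) and `degenerate`.
#' @export
fit_step_threshold <- function(values) {
  .assert(length(values) > 0L, "empty input")
  .assert(all(is.finite(values)), "values must be finite")
  v <- sort(values)
  n <- length(v)
  if (length(unique(v)) < 2L) {
    return(structure(list(threshold = v[1L], low_mean = v[1L],
                          high_mean = v[1L], sse = 0,
                          split_index = NA_integer_, degenerate = TRUE),
                     class = "StepFit"))
  }
  cs <- cumsum(v); cs2 <- cumsum(v^2)
  i <- seq_len(n - 1L)
  ss_left <- cs2[i] - cs[i]^2 / i
  nr <- n - i
  sum_r <- cs[n] - cs[i]
  ss_right <- (cs2[n] - cs2[i]) - sum_r^2 / nr
  sse <- ss_left + ss_right
  best <- which.min(sse)  # first minimum = smaller split index
  low <- cs[best] / best
  high <- sum_r[best] / nr[best]
  structure(list(threshold = (low + high) / 2, low_mean = low,
                 high_mean = high, sse = sse[best],
                 split_index = best, degenerate = FALSE),
            class = "StepFit")
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times Non-negative event/censoring times.
#' @param events 0/1 event indicators (0 = censored).
#' @return An object of class `KMCurve`: list with `time` (sorted unique
#'   observed times), `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(times, events) {
  .assert(length(times) == length(events), "times/events length mismatch")
  .assert(all(times >= 0), "negative survival time")
  .assert(all(events %in% c(0, 1)), "events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 surv = fit$surv),
            class = "KMCurve")
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square with the hypergeometric variance term.
#'
#' @param times_a,events_a Times and 0/1 indicators of group A.
#' @param times_b,events_b Times and 0/1 indicators of group B.
#' @return List with `chi2` and `p`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  .assert(length(times_a) > 0L && length(times_b) > 0L,
          "both groups must be non-empty")
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  grp <- rep(c("a", "b"), c(length(times_a), length(times_b)))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chi2 <- unname(sd_$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Stratify a cohort by composite signature score and compare survival
#'
#' Scores every patient by the composite z-score of the signature over the
#' cohort expression matrix, splits at a threshold (`step`: one-step SSE
#' fit; `median`: patients strictly above the median are "high", so the
#' median patient falls in the low group), and compares the strata by
#' Kaplan-Meier / log-rank.
#'
#' @param cohort A [cohort_table].
#' @param sig A [gene_set]; at least one gene must be present in the cohort
#'   expression.
#' @param method `"step"` or `"median"`.
#' @return List with `scores`, `threshold`, `groups` (named factor
#'   high/low), `n_high`, `n_low`, `km` (list of `KMCurve` per stratum) and
#'   `logrank`.
#' @export
stratified_survival <- function(cohort, sig, method = c("step", "median")) {
  method <- match.arg(method)
  sc <- .composite(cohort$expression, .as_genes(sig), context = "cohort signature")
  thr <- switch(method,
                step = fit_step_threshold(sc)$threshold,
                median = stats::median(sc))
  high <- sc > thr
  if (all(high) || !any(high))
    stop(sprintf("threshold %.4g yields an empty stratum", thr), call. = FALSE)
  pt <- cohort$patients
  km <- list(high = km_estimate(pt$time[high], pt$event[high]),
             low = km_estimate(pt$time[!high], pt$event[!high]))
  lr <- logrank_test(pt$time[high], pt$event[high],
                     pt$time[!high], pt$event[!high])
  list(scores = stats::setNames(sc, pt$patient_id), threshold = thr,
       groups = factor(ifelse(high, "high", "low"), levels = c("low", "high")),
       n_high = sum(high), n_low = sum(!high), km = km, logrank = lr)
}
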