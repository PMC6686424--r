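#' Partition samples into carriers and non-carriers of a gene set
#'
#' A sample is a carrier when it holds at least one mutation in any gene of
#' the set (counted once regardless of how many set genes are hit).
#'
#' @param mutations Tibble with columns `sample_id`, `gene_id` (one row per
#'   mutated gene per sample).
#' @param gene_set Non-empty character vector of gene ids.
#' @param all_samples Character vector of the full sample universe (samples
#'   without mutations are non-carriers).
#' @return List: `carriers` (named logical over `all_samples`), `fraction`.
#' @export
carrier_partition <- function(mutations, gene_set, all_samples) {
  if (length(gene_set) == 0L) stop("gene_set must be non-empty",
                                   call. = FALSE)
  hit <- unique(mutations$sample_id[mutations$gene_id %in% gene_set])
  flags <- stats::setNames(all_samples %in% hit, all_samples)
  list(carriers = flags, fraction = mean(flags))
}

#' Kaplan-Meier product-limit survival estimate
#'
#' `S(t)` is the product over distinct event times `t_i <= t` of
#' `(1 - d_i / n_i)`, where `d_i` counts events at `t_i` and `n_i` the
#' subjects still at risk. When an event and a censoring coincide, the
#' event is processed first (the censored subject is still at risk at its
#' own time). With no censoring the curve equals the empirical survival
#' function.
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicators (1 = death observed, 0 = censored).
#' @return Tibble: `time` (distinct event times, ordered), `n_risk`,
#'   `n_event`, `surv`. `S(0) = 1` is implicit (first row already reflects
#'   the first event time).
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 0, 1))
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0)) stop("times must be non-negative", call. = FALSE)
  if (length(time) < 1L) stop("need at least one record", call. = FALSE)
  event <- as.integer(event)
  et <- sort(unique(time[event == 1L]))
  if (length(et) == 0L) {
    return(tibble::tibble(time = numeric(0), n_risk = integer(0),
                          n_event = integer(0), surv = numeric(0)))
  }
  ts <- sort(time)
  # subjects at risk at t: those with follow-up >= t (events before
  # censorings at tied times by construction: both still at risk at t)
  n_risk <- length(ts) - findInterval(et, ts, left.open = TRUE)
  n_event <- as.integer(table(factor(time[event == 1L], levels = et)))
  surv <- cumprod(1 - n_event / n_risk)
  tibble::tibble(time = et, n_risk = as.integer(n_risk),
                 n_event = n_event, surv = surv)
}

#' Evaluate a KM curve at arbitrary times
#'
#' @param km Tibble from [km_estimate()].
#' @param t Times to evaluate at.
#' @return `S(t)`, right-continuous step function with `S(0) = 1`.
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(x) {
    i <- sum(km$time <= x)
    if (i == 0L) 1 else km$surv[i]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' At each distinct event time (both arms pooled), the observed number of
#' events in arm A is compared with its hypergeometric expectation given
#' the margins; the squared standardised sum is referred to chi-square with
#' one degree of freedom (two-sided). Invariant to exchanging arm labels.
#'
#' @param time_a,event_a Arm A follow-up times and event indicators.
#' @param time_b,event_b Arm B likewise.
#' @return List: `chisq`, `p`, `log10_p`, `observed` (arm A events),
#'   `expected` (arm A expectation), `n_events`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  event_a <- as.integer(event_a); event_b <- as.integer(event_b)
  d_total <- sum(event_a) + sum(event_b)
  if (d_total == 0L) stop("log-rank requires at least one event",
                          call. = FALSE)
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  arm_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  et <- sort(unique(time[event == 1L]))
  o_sum <- 0; e_sum <- 0; v_sum <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & arm_a)
    d <- sum(time == t & event == 1L)
    d1 <- sum(time == t & event == 1L & arm_a)
    o_sum <- o_sum + d1
    e_sum <- e_sum + d * n1 / n
    if (n > 1L) {
      v_sum <- v_sum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  if (v_sum <= 0) {
    chisq <- 0
  } else {
    chisq <- (o_sum - e_sum)^2 / v_sum
  }
  log_p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE, log.p = TRUE)
  list(chisq = chisq, p = exp(log_p), log10_p = log_p / log(10),
       observed = o_sum, expected = e_sum, n_events = d_total)
}

#' Survival contrast of carriers for two gene sets
#'
#' For each gene set (e.g. the most and least batch-sensitive deciles),
#' splits the cohort into carriers and non-carriers, fits KM curves for
#' both arms, and runs the carriers-vs-rest log-rank test. Carrier
#' fractions are reported side by side so differential power is visible.
#'
#' @param records Tibble with sample_id, time, event.
#' @param mutations Tibble with sample_id, gene_id.
#' @param set_a,set_b Gene-id vectors (e.g. batch-sensitive and
#'   batch-resistant sets).
#' @param labels Length-2 labels for the report.
#' @return List of two per-set reports (`carrier_fraction`, `km_carrier`,
#'   `km_noncarrier`, `logrank` or NA when an arm is empty of events).
#' @export
gene_set_contrast <- function(records, mutations, set_a, set_b,
                              labels = c("set_a", "set_b")) {
  one <- function(gene_set) {
    cp <- carrier_partition(mutations, gene_set, records$sample_id)
    flag <- cp$carriers[records$sample_id]
    res <- list(carrier_fraction = cp$fraction,
                n_carriers = sum(flag),
                km_carrier = NULL, km_noncarrier = NULL, logrank = NULL)
    if (sum(flag) == 0L || sum(!flag) == 0L) return(res)
    res$km_carrier <- km_estimate(records$time[flag], records$event[flag])
    res$km_noncarrier <- km_estimate(records$time[!flag],
                                     records$event[!flag])
    if (sum(records$event) > 0L) {
      res$logrank <- logrank_test(records$time[flag], records$event[flag],
                                  records$time[!flag], records$event[!flag])
    }
    res
  }
  out <- list(one(set_a), one(set_b))
  names(out) <- labels
  out
}
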