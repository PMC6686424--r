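# Independent brute-force oracles used across tests. These deliberately use
# the most naive formulation available so they share no code path with the
# package implementation.

# KS D by evaluating both ECDFs at every observed location
oracle_ks_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(vapply(pts, function(v) {
    abs(mean(x <= v) - mean(y <= v))
  }, numeric(1)))
}

# Pearson correlation from the textbook sum formula
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

# One-way ANOVA from hand-expanded sums of squares
oracle_anova_f <- function(values, labels) {
  groups <- split(values, labels)
  k <- length(groups)
  n <- length(values)
  grand <- mean(values)
  ss_between <- sum(vapply(groups, function(g) {
    length(g) * (mean(g) - grand)^2
  }, numeric(1)))
  ss_within <- sum(vapply(groups, function(g) {
    sum((g - mean(g))^2)
  }, numeric(1)))
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

# Product-limit estimate by explicit per-event-time products
oracle_km <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  surv <- numeric(length(et))
  s <- 1
  for (i in seq_along(et)) {
    n_i <- sum(time >= et[i])
    d_i <- sum(time == et[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  data.frame(time = et, surv = surv)
}

# Log-rank O/E/V by hand-expanded hypergeometric terms
oracle_logrank <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  in_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  et <- sort(unique(time[event == 1]))
  o <- e <- v <- 0
  for (t in et) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & in_a)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & in_a)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * ((n - n1) / n) * ((n - d) / (n - 1))
  }
  list(observed = o, expected = e, variance = v,
       chisq = (o - e)^2 / v)
}

# Median survival time read off a KM curve (first time S drops below 0.5)
km_median <- function(km) {
  i <- which(km$surv <= 0.5)
  if (length(i) == 0) NA_real_ else km$time[min(i)]
}

# Enumerate all multisets of a given size over positions 0..(m-1)
enumerate_multisets <- function(size, m) {
  if (size == 1) return(lapply(0:(m - 1), identity))
  smaller <- enumerate_multisets(size - 1, m)
  out <- list()
  for (s in smaller) {
    last <- s[length(s)]
    for (v in last:(m - 1)) out[[length(out) + 1]] <- c(s, v)
  }
  out
}
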