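#' Classify a single-nucleotide substitution
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine exchanges
#' (`A<->G`, `C<->T`); every other substitution is a transversion.
#'
#' @param ref,alt Single nucleotides in `{A,C,G,T}`, `ref != alt`.
#'   Vectorised.
#' @return Character vector, `"transition"` or `"transversion"`.
#' @examples
#' classify_substitution("A", "G") # transition
#' classify_substitution("A", "C") # transversion
#' @export
classify_substitution <- function(ref, alt) {
  nt <- c("A", "C", "G", "T")
  if (!all(ref %in% nt) || !all(alt %in% nt) || any(ref == alt))
    stop("ref and alt must be distinct nucleotides in {A,C,G,T}",
         call. = FALSE)
  ti <- (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
  ifelse(ti, "transition", "transversion")
}

#' Per-sample variant counts and substitution spectrum
#'
#' For each sample: total SNV count, transition and transversion counts, and
#' the TiTv ratio (NA when the sample has no transversions). Input must be
#' SNV-filtered (see [filter_snv()]).
#'
#' @param calls Merged call tibble with sample_id, ref, alt.
#' @param all_samples Optional character vector of sample ids that must
#'   appear in the output even with zero calls.
#' @return Tibble: sample_id, n_variants, n_transitions, n_transversions,
#'   titv.
#' @export
summarize_samples <- function(calls, all_samples = NULL) {
  if (nrow(calls) > 0L) {
    is_ti <- classify_substitution(calls$ref, calls$alt) == "transition"
    out <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(sample_id = calls$sample_id, ti = is_ti),
                      .data$sample_id),
      n_variants = dplyr::n(),
      n_transitions = sum(.data$ti),
      n_transversions = sum(!.data$ti),
      .groups = "drop"
    )
  } else {
    out <- tibble::tibble(sample_id = character(0), n_variants = integer(0),
                          n_transitions = integer(0),
                          n_transversions = integer(0))
  }
  if (!is.null(all_samples)) {
    missing <- setdiff(all_samples, out$sample_id)
    if (length(missing) > 0L) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        sample_id = missing, n_variants = 0L, n_transitions = 0L,
        n_transversions = 0L))
    }
    out <- out[match(all_samples, out$sample_id), , drop = FALSE]
  }
  out$titv <- ifelse(out$n_transversions > 0,
                     out$n_transitions / out$n_transversions, NA_real_)
  out
}

#' One-way fixed-effects ANOVA with underflow-safe p-value
#'
#' Classical one-way ANOVA: `F` is the ratio of between-group to
#' within-group mean squares, with `(k - 1, N - k)` degrees of freedom. The
#' `F` statistic is computed via [stats::oneway.test()] (equal variances);
#' the p-value is recomputed on the log scale from the F distribution, so
#' `log10_p` stays finite far below double-precision underflow.
#'
#' @param values Numeric per-sample metric.
#' @param labels Group label per value.
#' @return List: `f` statistic, `p` (0 when underflowed), `log10_p`,
#'   `df1`, `df2`, `n_groups`.
#' @examples
#' group_anova(c(0, 0, 1, 1, 2, 2, 3, 3), rep(c("a", "b"), each = 4))
#' @export
group_anova <- function(values, labels) {
  keep <- is.finite(values)
  values <- values[keep]
  labels <- as.character(labels[keep])
  sizes <- table(labels)
  if (length(sizes) < 2L)
    stop("ANOVA requires at least two groups", call. = FALSE)
  if (any(sizes < 2L))
    stop("every group needs at least two finite values", call. = FALSE)
  if (isTRUE(all.equal(stats::var(values), 0)) ||
      sum(tapply(values, labels, stats::var) * (sizes - 1)) == 0)
    stop("zero within-group variance: ANOVA is degenerate", call. = FALSE)
  ow <- stats::oneway.test(values ~ factor(labels), var.equal = TRUE)
  f <- unname(ow$statistic)
  df1 <- unname(ow$parameter[1])
  df2 <- unname(ow$parameter[2])
  log_p <- stats::pf(f, df1, df2, lower.tail = FALSE, log.p = TRUE)
  list(f = f, p = exp(log_p), log10_p = log_p / log(10),
       df1 = df1, df2 = df2, n_groups = length(sizes))
}

#' Group-level summary of per-sample metrics with ANOVA
#'
#' One row per group (sequencing center or cancer type): sample count, mean
#' and SD of per-sample variant totals and TiTv ratios. An ANOVA line (F,
#' log10 p) across groups is attached as the `anova` attribute for each
#' metric; with a single group the ANOVA is marked not applicable. The group
#' TiTv is the mean of per-sample ratios (the per-sample view); the
#' pooled-count ratio is reported alongside as `titv_pooled`. Samples with
#' zero transversions are excluded from TiTv summaries and their count is
#' reported.
#'
#' @param summaries Per-sample tibble from [summarize_samples()].
#' @param metadata Metadata tibble covering every sample.
#' @param by Grouping column: `"center"` or `"group"`.
#' @return Tibble of group summaries with attribute `anova` (named list for
#'   `n_variants` and `titv`) and attribute `n_titv_excluded`.
#' @export
group_summary <- function(summaries, metadata, by = c("center", "group")) {
  by <- match.arg(by)
  orphans <- setdiff(summaries$sample_id, metadata$sample_id)
  if (length(orphans) > 0L)
    stop("samples without metadata: ", paste(orphans, collapse = ", "),
         call. = FALSE)
  df <- dplyr::inner_join(summaries, metadata, by = "sample_id")
  df$.grp <- df[[by]]
  tab <- dplyr::summarise(
    dplyr::group_by(df, .data$.grp),
    n = dplyr::n(),
    mean_n_variants = mean(.data$n_variants),
    sd_n_variants = stats::sd(.data$n_variants),
    mean_titv = mean(.data$titv, na.rm = TRUE),
    sd_titv = stats::sd(.data$titv, na.rm = TRUE),
    titv_pooled = sum(.data$n_transitions) /
      max(sum(.data$n_transversions), 1L),
    .groups = "drop"
  )
  names(tab)[1] <- by
  n_excl <- sum(is.na(df$titv))
  anova <- list(n_variants = NULL, titv = NULL)
  if (nrow(tab) >= 2L) {
    anova$n_variants <- tryCatch(group_anova(df$n_variants, df$.grp),
                                 error = function(e) NULL)
    ok <- !is.na(df$titv)
    anova$titv <- tryCatch(group_anova(df$titv[ok], df$.grp[ok]),
                           error = function(e) NULL)
  }
  attr(tab, "anova") <- anova
  attr(tab, "n_titv_excluded") <- n_excl
  tab
}

#' Strip/box plot of a per-sample metric by group, colored by center
#'
#' @param summaries Per-sample tibble from [summarize_samples()].
#' @param metadata Metadata tibble.
#' @param metric Column of `summaries` to plot.
#' @return A ggplot object.
#' @export
plot_sample_metric <- function(summaries, metadata,
                               metric = c("n_variants", "titv")) {
  metric <- match.arg(metric)
  df <- dplyr::inner_join(summaries, metadata, by = "sample_id")
  df <- df[is.finite(df[[metric]]), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data[[metric]],
                                   fill = .data$center)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = "group", y = metric,
                  title = sprintf("Per-sample %s by group and center",
                                  metric)) +
    ggplot2::theme_minimal()
}
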