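#' Configuration for the synthetic multi-center cohort generator
#'
#' Builds and validates the parameter set that drives [generate_gene_models()],
#' [generate_cohort()] and [generate_survival()]. The defaults emulate the
#' structure of a six-cancer-type, three-center germline WES cohort: three
#' groups sequenced at the reference center (`BI`), two at `WUGSC`, one at
#' `BCM`; non-reference centers call 30% more variants per sample on average;
#' the reference center has a per-sample transition-transversion (TiTv) ratio
#' of 2.73 against 2.57 elsewhere. Sample counts and per-sample variant totals
#' default to desk-scale values; raise them for calibration runs.
#'
#' The first element of `centers` is the reference center. For genes flagged
#' "affected", samples from non-reference centers draw within-gene variant
#' positions from a Beta law whose parameters are linearly interpolated from
#' `beta_base` toward `beta_alt` by `shift`; the reference center always uses
#' `beta_base`, as do all centers for unaffected genes. `shift = 0` therefore
#' removes the positional batch effect entirely.
#'
#' @param centers Character vector of sequencing-center labels; the first is
#'   the reference center.
#' @param groups Data frame with columns `group`, `center`, `n_samples`
#'   (one row per cancer-type group; each group belongs to exactly one center).
#' @param n_genes Number of synthetic genes.
#' @param exon_count Integer range `c(min, max)` of exons per gene.
#' @param exon_length Range `c(min, max)` of exon lengths (nt).
#' @param intron_length Range `c(min, max)` of intron lengths (nt).
#' @param count_mean Named numeric: mean per-sample variant total per center.
#' @param count_dispersion Negative-binomial size (dispersion) parameter for
#'   per-sample totals; larger is closer to Poisson.
#' @param titv Named numeric: target per-center TiTv ratio r. Each substitution
#'   is a transition with probability r / (r + 1).
#' @param affected_frac Fraction of genes whose within-gene location
#'   distribution differs by center.
#' @param shift Mixture-shift magnitude in `[0, 1]` for affected genes.
#' @param beta_base,beta_alt Beta `(shape1, shape2)` pairs for the shared and
#'   fully shifted positional laws.
#' @param density_skew Scale (sd of a log-normal perturbation) of per-center,
#'   per-gene density-weight skew; 0 means every center shares gene weights.
#' @param n_callers Number of caller replicates per sample.
#' @param fp_rate Per-caller false-positive rate (expected spurious calls as a
#'   fraction of the sample's true calls).
#' @param fn_rate Per-caller probability of missing a true call.
#' @param survival List with `baseline_hazard`, `hazard_ratio` (carrier vs
#'   non-carrier), `censor_rate` (hazard of the independent exponential
#'   censoring process; 0 disables censoring).
#' @param seed Integer base seed; identical config + seed reproduces all
#'   outputs byte-identically.
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @examples
#' cfg <- cohort_config(n_genes = 20, seed = 7)
#' cfg$groups
#' @export
cohort_config <- function(centers = c("BI", "WUGSC", "BCM"),
                          groups = default_groups(centers),
                          n_genes = 50,
                          exon_count = c(2L, 10L),
                          exon_length = c(80L, 400L),
                          intron_length = c(50L, 200L),
                          count_mean = stats::setNames(
                            c(100, rep(130, length(centers) - 1L)), centers
                          ),
                          count_dispersion = 50,
                          titv = stats::setNames(
                            c(2.73, rep(2.57, length(centers) - 1L)), centers
                          ),
                          affected_frac = 0.2,
                          shift = 0.5,
                          beta_base = c(1, 3),
                          beta_alt = c(3, 1),
                          density_skew = 0,
                          n_callers = 2L,
                          fp_rate = 0.02,
                          fn_rate = 0.05,
                          survival = list(baseline_hazard = 0.1,
                                          hazard_ratio = 2,
                                          censor_rate = 0.02),
                          seed = 1L) {
  groups <- as.data.frame(groups)
  cfg <- structure(
    list(centers = as.character(centers), groups = groups,
         n_genes = as.integer(n_genes),
         exon_count = as.integer(exon_count),
         exon_length = as.integer(exon_length),
         intron_length = as.integer(intron_length),
         count_mean = count_mean, count_dispersion = count_dispersion,
         titv = titv, affected_frac = affected_frac, shift = shift,
         beta_base = beta_base, beta_alt = beta_alt,
         density_skew = density_skew,
         n_callers = as.integer(n_callers),
         fp_rate = fp_rate, fn_rate = fn_rate,
         survival = survival, seed = as.integer(seed)),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @export
default_groups <- function(centers = c("BI", "WUGSC", "BCM")) {
  labels <- list(c("SKCM", "STAD", "THCA"), c("BRCA", "UCEC"), c("LIHC"))
  out <- do.call(rbind, lapply(seq_along(centers), function(i) {
    g <- if (i <= length(labels)) labels[[i]] else paste0("G", i)
    data.frame(group = g, center = centers[i], n_samples = 30L)
  }))
  rownames(out) <- NULL
  out
}

validate_cohort_config <- function(cfg) {
  g <- cfg$groups
  if (!all(c("group", "center", "n_samples") %in% names(g)))
    abort_config("groups must have columns group, center, n_samples")
  if (anyDuplicated(g$group))
    abort_config("group labels must be unique (each group maps to one center)")
  if (!all(g$center %in% cfg$centers))
    abort_config("groups reference unknown centers")
  if (any(g$n_samples <= 0)) abort_config("all sample counts must be > 0")
  if (cfg$n_genes <= 0) abort_config("n_genes must be > 0")
  for (fld in c("exon_count", "exon_length", "intron_length")) {
    r <- cfg[[fld]]
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2])
      abort_config(sprintf("%s must be a positive c(min, max) range", fld))
  }
  for (fld in c("count_mean", "titv")) {
    v <- cfg[[fld]]
    if (!all(cfg$centers %in% names(v)))
      abort_config(sprintf("%s must be named for every center", fld))
    if (any(v <= 0)) abort_config(sprintf("%s entries must be > 0", fld))
  }
  p_ti <- cfg$titv / (1 + cfg$titv)
  if (any(p_ti <= 0 | p_ti >= 1))
    abort_config("derived transition probabilities must lie in (0, 1)")
  if (cfg$count_dispersion <= 0) abort_config("count_dispersion must be > 0")
  if (cfg$affected_frac < 0 || cfg$affected_frac > 1)
    abort_config("affected_frac must lie in [0, 1]")
  if (cfg$shift < 0 || cfg$shift > 1)
    abort_config("shift magnitude must lie in [0, 1]")
  if (any(cfg$beta_base <= 0) || any(cfg$beta_alt <= 0))
    abort_config("Beta parameters must be positive")
  if (cfg$density_skew < 0) abort_config("density_skew must be >= 0")
  if (cfg$n_callers < 1L) abort_config("n_callers must be >= 1")
  if (cfg$fp_rate < 0 || cfg$fp_rate >= 1 || cfg$fn_rate < 0 || cfg$fn_rate >= 1)
    abort_config("fp_rate and fn_rate must lie in [0, 1)")
  sv <- cfg$survival
  if (sv$baseline_hazard <= 0) abort_config("baseline_hazard must be > 0")
  if (sv$hazard_ratio <= 0) abort_config("hazard_ratio must be > 0")
  if (sv$censor_rate < 0) abort_config("censor_rate must be >= 0")
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  centers:", paste(x$centers, collapse = ", "),
      sprintf("(reference: %s)\n", x$centers[1]))
  cat(sprintf("  groups: %d (%d samples total)\n", nrow(x$groups),
              sum(x$groups$n_samples)))
  cat(sprintf("  genes: %d (affected fraction %.2f, shift %.2f)\n",
              x$n_genes, x$affected_frac, x$shift))
  cat(sprintf("  callers: %d (FP %.3f, FN %.3f); seed %d\n",
              x$n_callers, x$fp_rate, x$fn_rate, x$seed))
  invisible(x)
}
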