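# Shared synthetic-cohort fixtures, built once per test run.

make_config <- function(n_samples = 6L, ...) {
  args <- utils::modifyList(
    list(n_genes = 25L, seed = 202L, n_callers = 2L,
         fp_rate = 0.05, fn_rate = 0.05),
    list(...)
  )
  cfg <- do.call(cohort_config, args)
  cfg$groups$n_samples <- as.integer(n_samples)
  cfg
}

# clean cohort: no caller noise, calls == truth (used as an oracle substrate)
clean_cohort <- local({
  value <- NULL
  function() {
    if (is.null(value)) {
      cfg <- make_config(n_samples = 10L, n_genes = 30L, seed = 303L,
                         n_callers = 1L, fp_rate = 0, fn_rate = 0,
                         count_mean = c(BI = 120, WUGSC = 156, BCM = 156))
      value <<- generate_cohort(cfg)
    }
    value
  }
})

# strongly shifted cohort for within-gene power-style checks
shifted_cohort <- local({
  value <- NULL
  function() {
    if (is.null(value)) {
      cfg <- make_config(n_samples = 15L, n_genes = 40L, seed = 404L,
                         n_callers = 1L, fp_rate = 0, fn_rate = 0,
                         affected_frac = 0.5, shift = 1,
                         count_mean = c(BI = 250, WUGSC = 250, BCM = 250))
      value <<- generate_cohort(cfg)
    }
    value
  }
})

# merged + annotated calls for a cohort (its own single-caller union)
annotated_calls <- function(cohort) {
  merged <- merge_callers(cohort$calls, mode = "consensus", min_callers = 1L)
  varbatch:::annotate_gene_coords(merged, cohort$models)
}
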