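#' Generate a synthetic multi-center cohort with injectable batch structure
#'
#' Draws a full multi-caller germline SNV call set over the gene models,
#' emulating the batch structure seen in multi-center WES cohorts:
#'
#' * per-sample variant totals are negative-binomial with center-specific
#'   means (count inflation across centers);
#' * each substitution is a transition with the center's probability
#'   `r / (r + 1)` derived from its target TiTv ratio `r`;
#' * variants land in genes according to per-gene weights, optionally skewed
#'   per center (`density_skew`), so samples from one center share a density
#'   profile;
#' * within-gene positions follow a Beta law over gene-exomic coordinates
#'   `[0, L)`; for "affected" genes, non-reference centers interpolate the
#'   Beta parameters toward an alternative pair by the shift magnitude;
#' * each of `n_callers` caller replicates independently drops true calls at
#'   the false-negative rate and adds spurious calls (uniform positions,
#'   error-like TiTv of 0.5) at the false-positive rate, to exercise
#'   union/consensus merging.
#'
#' Within a sample, duplicate (position, ref, alt) draws are collapsed (a
#' diploid sample carries one genotype per site); the same site may still
#' recur across samples, so within-gene location collections are multisets.
#' Every unit has its own RNG stream keyed by (seed, sample, caller), so
#' identical config + seed reproduces the cohort exactly and adding samples
#' never reshuffles earlier ones.
#'
#' @param config A [cohort_config()].
#' @param models Gene models; defaults to [generate_gene_models()] under the
#'   same config.
#' @return A `synthetic_cohort` object: list with `calls` (tibble: sample_id,
#'   caller, contig, position, ref, alt, qual), `truth` (gene table with
#'   affected flags and density weights, per-sample true counts/spectrum and
#'   carrier flags, per-center configured targets), `metadata`, `models`,
#'   and the `config`.
#' @examples
#' cfg <- cohort_config(n_genes = 10, seed = 42)
#' cfg$groups$n_samples <- 3L
#' coh <- generate_cohort(cfg)
#' head(coh$calls)
#' @export
generate_cohort <- function(config, models = generate_gene_models(config)) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_genes < 1L || sum(config$groups$n_samples) < 1L)
    abort_config("cohort generation requires at least one gene and one sample")

  genes <- models$genes
  ngene <- nrow(genes)
  L <- genes$tx_length

  # gene-level structure: affected flags and density weights
  n_aff <- round(config$affected_frac * ngene)
  affected <- with_seed(derive_seed(config$seed, "affected"), {
    flags <- rep(FALSE, ngene)
    flags[sample.int(ngene, n_aff)] <- TRUE
    flags
  })
  w_base <- with_seed(derive_seed(config$seed, "weights"),
                      stats::rgamma(ngene, shape = 2, rate = 1) * L / mean(L))
  weights <- sapply(config$centers, function(ctr) {
    z <- with_seed(derive_seed(config$seed, "skew", ctr),
                   stats::rnorm(ngene))
    w <- w_base * exp(config$density_skew * z)
    w / sum(w)
  })
  if (is.null(dim(weights))) {
    weights <- matrix(weights, nrow = ngene,
                      dimnames = list(NULL, config$centers))
  }
  colnames(weights) <- config$centers

  # sample sheet in group order; sample index is global and stable
  meta <- do.call(rbind, lapply(seq_len(nrow(config$groups)), function(i) {
    g <- config$groups[i, ]
    data.frame(group = g$group, center = g$center,
               n = seq_len(g$n_samples))
  }))
  meta <- tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(nrow(meta))),
    center = meta$center, group = meta$group,
    ethnicity = "EUR", platform = "Illumina"
  )

  p_ti <- config$titv / (1 + config$titv)
  shifted_params <- (1 - config$shift) * config$beta_base +
    config$shift * config$beta_alt

  draw_positions <- function(gidx, center) {
    # Beta positional law per variant; affected genes shift in
    # non-reference centers only
    n <- length(gidx)
    use_shift <- affected[gidx] & center != config$centers[1]
    u <- numeric(n)
    if (any(!use_shift))
      u[!use_shift] <- stats::rbeta(sum(!use_shift), config$beta_base[1],
                                    config$beta_base[2])
    if (any(use_shift))
      u[use_shift] <- stats::rbeta(sum(use_shift), shifted_params[1],
                                   shifted_params[2])
    pmin(as.integer(floor(u * L[gidx])), L[gidx] - 1L)
  }

  TI_PAIRS <- matrix(c("A", "G", "G", "A", "C", "T", "T", "C"),
                     ncol = 2, byrow = TRUE)
  TV_PAIRS <- matrix(c("A", "C", "C", "A", "A", "T", "T", "A",
                       "C", "G", "G", "C", "G", "T", "T", "G"),
                     ncol = 2, byrow = TRUE)
  draw_alleles <- function(is_ti) {
    n <- length(is_ti)
    ref <- character(n); alt <- character(n)
    if (any(is_ti)) {
      k <- sample.int(4L, sum(is_ti), replace = TRUE)
      ref[is_ti] <- TI_PAIRS[k, 1]; alt[is_ti] <- TI_PAIRS[k, 2]
    }
    if (any(!is_ti)) {
      k <- sample.int(8L, sum(!is_ti), replace = TRUE)
      ref[!is_ti] <- TV_PAIRS[k, 1]; alt[!is_ti] <- TV_PAIRS[k, 2]
    }
    list(ref = ref, alt = alt)
  }

  # true call set, one RNG stream per sample
  truth_rows <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    ctr <- meta$center[i]
    truth_rows[[i]] <- with_seed(derive_seed(config$seed, "sample", i), {
      n <- stats::rnbinom(1L, size = config$count_dispersion,
                          mu = config$count_mean[[ctr]])
      if (n == 0L) return(NULL)
      gidx <- sample.int(ngene, n, replace = TRUE, prob = weights[, ctr])
      coord <- draw_positions(gidx, ctr)
      is_ti <- stats::runif(n) < p_ti[[ctr]]
      al <- draw_alleles(is_ti)
      tibble::tibble(sample_id = meta$sample_id[i], gene_idx = gidx,
                     gene_coord = coord, ref = al$ref, alt = al$alt,
                     is_ti = is_ti)
    })
  }
  truth_calls <- dplyr::bind_rows(truth_rows)
  truth_calls$position <- map_pooled_to_genomic(truth_calls$gene_idx,
                                                truth_calls$gene_coord, models)
  truth_calls$gene_id <- genes$gene_id[truth_calls$gene_idx]
  truth_calls$contig <- genes$contig[truth_calls$gene_idx]
  truth_calls <- dplyr::distinct(truth_calls, .data$sample_id, .data$position,
                                 .data$ref, .data$alt, .keep_all = TRUE)

  # caller replicates: FN dropout + FP injection per (sample, caller) stream
  truth_by_sample <- split(truth_calls,
                           factor(truth_calls$sample_id,
                                  levels = meta$sample_id))
  empty_truth <- truth_calls[0, ]
  call_rows <- vector("list", nrow(meta) * config$n_callers)
  slot <- 0L
  for (i in seq_len(nrow(meta))) {
    sid <- meta$sample_id[i]
    ctr <- meta$center[i]
    tc <- truth_by_sample[[i]] %||% empty_truth
    for (j in seq_len(config$n_callers)) {
      slot <- slot + 1L
      call_rows[[slot]] <- with_seed(derive_seed(config$seed, "caller", i, j), {
        keep <- stats::runif(nrow(tc)) >= config$fn_rate
        kept <- tc[keep, c("sample_id", "gene_idx", "gene_coord",
                           "ref", "alt", "position", "contig")]
        n_fp <- stats::rpois(1L, config$fp_rate * nrow(tc))
        if (n_fp > 0L) {
          gidx <- sample.int(ngene, n_fp, replace = TRUE, prob = weights[, ctr])
          coord <- pmin(as.integer(floor(stats::runif(n_fp) * L[gidx])),
                        L[gidx] - 1L)
          al <- draw_alleles(stats::runif(n_fp) < 1 / 3) # error-like TiTv 0.5
          fp <- tibble::tibble(sample_id = sid, gene_idx = gidx,
                               gene_coord = coord, ref = al$ref, alt = al$alt,
                               position = map_pooled_to_genomic(gidx, coord,
                                                                models),
                               contig = genes$contig[gidx])
          kept <- dplyr::bind_rows(kept, fp)
        }
        kept$caller <- sprintf("caller%d", j)
        kept
      })
    }
  }
  calls <- dplyr::bind_rows(call_rows)
  calls <- dplyr::distinct(calls, .data$sample_id, .data$caller,
                           .data$position, .data$ref, .data$alt,
                           .keep_all = TRUE)
  calls <- tibble::tibble(
    sample_id = calls$sample_id, caller = calls$caller,
    contig = calls$contig, position = calls$position,
    ref = calls$ref, alt = calls$alt, qual = 100
  )
  calls <- dplyr::arrange(calls, .data$sample_id, .data$caller,
                          .data$position, .data$alt)

  sample_truth <- dplyr::summarise(
    dplyr::group_by(truth_calls, .data$sample_id),
    n_true = dplyr::n(), n_ti = sum(.data$is_ti),
    n_tv = sum(!.data$is_ti), .groups = "drop"
  )
  sample_truth <- dplyr::left_join(meta[, c("sample_id", "center", "group")],
                                   sample_truth, by = "sample_id")
  sample_truth[is.na(sample_truth)] <- 0L
  carrier_set <- genes$gene_id[affected]
  carriers <- vapply(split(truth_calls$gene_id, truth_calls$sample_id),
                     function(gs) any(gs %in% carrier_set), logical(1))
  sample_truth$carrier <- unname(carriers[sample_truth$sample_id])
  sample_truth$carrier[is.na(sample_truth$carrier)] <- FALSE

  truth <- list(
    genes = tibble::tibble(gene_id = genes$gene_id,
                           tx_length = genes$tx_length,
                           affected = affected),
    samples = sample_truth,
    centers = tibble::tibble(center = config$centers,
                             titv_target = unname(config$titv[config$centers]),
                             count_mean_target =
                               unname(config$count_mean[config$centers])),
    carrier_gene_set = carrier_set,
    truth_calls = truth_calls[, c("sample_id", "gene_id", "gene_coord",
                                  "contig", "position", "ref", "alt", "is_ti")]
  )

  structure(list(calls = calls, metadata = meta, truth = truth,
                 models = models, config = config),
            class = "synthetic_cohort")
}

# vectorised pooled gene-exomic -> genomic mapping (one pass per gene)
map_pooled_to_genomic <- function(gene_idx, gene_coord, models) {
  pos <- integer(length(gene_idx))
  if (length(gene_idx) == 0L) return(pos)
  for (gi in unique(gene_idx)) {
    sel <- gene_idx == gi
    pos[sel] <- gene_to_genomic(gene_coord[sel],
                                models$genes$gene_id[gi], models)
  }
  pos
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d samples x %d callers, %d calls, %d genes (%d affected)\n",
    nrow(x$metadata), x$config$n_callers, nrow(x$calls),
    nrow(x$truth$genes), sum(x$truth$genes$affected)))
  invisible(x)
}

#' Generate survival outcomes with carrier-dependent hazard
#'
#' Event times are exponential with hazard `baseline_hazard` for
#' non-carriers and `baseline_hazard * hazard_ratio` for carriers; censoring
#' is an independent exponential with hazard `censor_rate` (0 disables it).
#'
#' @param config A [cohort_config()] (fields under `survival` are used).
#' @param carriers Named logical vector: sample id -> carrier flag.
#' @return Tibble with columns `sample_id`, `time`, `event`, `carrier`.
#' @examples
#' cfg <- cohort_config(seed = 3)
#' generate_survival(cfg, c(S1 = TRUE, S2 = FALSE))
#' @export
generate_survival <- function(config, carriers) {
  stopifnot(inherits(config, "cohort_config"))
  sv <- config$survival
  if (sv$hazard_ratio <= 0) abort_config("hazard_ratio must be > 0")
  with_seed(derive_seed(config$seed, "survival"), {
    n <- length(carriers)
    haz <- sv$baseline_hazard * ifelse(carriers, sv$hazard_ratio, 1)
    t_event <- stats::rexp(n, rate = haz)
    t_cens <- if (sv$censor_rate > 0) {
      stats::rexp(n, rate = sv$censor_rate)
    } else rep(Inf, n)
    tibble::tibble(
      sample_id = names(carriers) %||% sprintf("S%04d", seq_len(n)),
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      carrier = unname(carriers)
    )
  })
}

#' Write a synthetic cohort to disk
#'
#' Serialises the cohort as the file set the ingest stage consumes: one VCF
#' 4.2 per sample per caller (`<sample>.<caller>.vcf`), a metadata TSV
#' (sample_id, center, group, ethnicity, platform), BED12 gene models, a
#' truth JSON, and optionally a survival TSV.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @param survival Optional survival table from [generate_survival()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, survival = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  callers <- sprintf("caller%d", seq_len(cohort$config$n_callers))
  key <- factor(paste(cohort$calls$sample_id, cohort$calls$caller, sep = "."),
                levels = as.vector(outer(cohort$metadata$sample_id, callers,
                                         paste, sep = ".")))
  by_file <- split(cohort$calls, key)
  for (nm in names(by_file)) {
    sid <- sub("\\.caller[0-9]+$", "", nm)
    write_vcf(by_file[[nm]], file.path(dir, paste0(nm, ".vcf")),
              sample_id = sid)
  }
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_models(cohort$models, file.path(dir, "genes.bed"))
  truth <- cohort$truth
  truth$truth_calls <- NULL # summary truth only; calls live in the VCFs
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  if (!is.null(survival)) {
    utils::write.table(survival, file.path(dir, "survival.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Write calls for one sample as a minimal VCF 4.2
#'
#' @param calls Tibble with contig, position, ref, alt, qual for one sample.
#' @param path Output path.
#' @param sample_id Sample column name in the VCF.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample_id = "SAMPLE") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=varbatch-synthetic-cohort",
    "##contig=<ID=chrS>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  body <- if (nrow(calls) > 0L) {
    o <- order(calls$contig, calls$position, calls$alt)
    paste(calls$contig[o], calls$position[o], ".", calls$ref[o], calls$alt[o],
          format(calls$qual[o], trim = TRUE), "PASS", ".", "GT", "0/1",
          sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
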