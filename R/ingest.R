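#' Read one caller's VCF into a call table
#'
#' Parses a VCF (via `vcfR`) into a flat tibble of calls, splitting
#' multi-allelic records into one row per ALT allele and tagging every row
#' with the caller label. No filtering is applied here; see [filter_snv()].
#'
#' @param path VCF file path.
#' @param caller_label Label recorded in the `caller` column.
#' @param sample_id Sample label; defaults to the VCF's sample column name,
#'   falling back to the file name stem.
#' @return Tibble: sample_id, caller, contig, position, ref, alt, qual.
#' @export
read_vcf <- function(path, caller_label, sample_id = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (is.null(sample_id)) {
    cols <- colnames(v@gt)
    sample_id <- if (!is.null(cols) && length(cols) > 1L) {
      cols[2]
    } else sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  if (nrow(fix) == 0L) {
    return(tibble::tibble(sample_id = character(0), caller = character(0),
                          contig = character(0), position = integer(0),
                          ref = character(0), alt = character(0),
                          qual = numeric(0)))
  }
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep.int(seq_len(nrow(fix)), n_alt)
  tibble::tibble(
    sample_id = sample_id,
    caller = caller_label,
    contig = fix$CHROM[idx],
    position = as.integer(fix$POS[idx]),
    ref = fix$REF[idx],
    alt = unlist(alts, use.names = FALSE),
    qual = suppressWarnings(as.numeric(fix$QUAL[idx]))
  )
}

#' Retain single-nucleotide variants above a quality threshold
#'
#' Keeps calls whose REF and ALT are both single nucleotides in `{A,C,G,T}`
#' and whose quality is at least `min_qual` (inclusive; records with missing
#' QUAL are dropped). Indels and other non-SNV records are removed; row
#' order is preserved.
#'
#' @param calls Call tibble (as from [read_vcf()]).
#' @param min_qual Minimum quality score (default 30).
#' @return The filtered tibble.
#' @export
filter_snv <- function(calls, min_qual = 30) {
  nt <- c("A", "C", "G", "T")
  keep <- calls$ref %in% nt & calls$alt %in% nt & calls$ref != calls$alt &
    !is.na(calls$qual) & calls$qual >= min_qual
  calls[keep, , drop = FALSE]
}

#' Merge per-caller call sets by union or consensus
#'
#' Variant identity is `(contig, position, ref, alt)` within a sample;
#' genotype is ignored. Union mode keeps every distinct variant reported by
#' any caller; consensus mode keeps variants supported by at least
#' `min_callers` callers. `merge_callers(..., mode = "consensus",
#' min_callers = 1)` is identical to union, and raising `min_callers` can
#' only remove variants.
#'
#' When `require_all_callers` is set, samples missing any of the expected
#' caller call sets are discarded with a warning rather than merged from an
#' incomplete set.
#'
#' @param calls Call tibble covering one or more samples, with a `caller`
#'   column.
#' @param mode `"union"` or `"consensus"`.
#' @param min_callers Minimum supporting callers in consensus mode (>= 2 by
#'   convention; 1 reduces to union).
#' @param require_all_callers Optional character vector of caller labels
#'   that every sample must have; incomplete samples are dropped.
#' @return Tibble: sample_id, contig, position, ref, alt, qual (maximum over
#'   supporting callers), n_callers, callers (comma-joined labels).
#' @export
merge_callers <- function(calls, mode = c("consensus", "union"),
                          min_callers = 2L, require_all_callers = NULL) {
  mode <- match.arg(mode)
  if (mode == "union") min_callers <- 1L
  if (min_callers < 1L) stop("min_callers must be >= 1", call. = FALSE)
  if (!is.null(require_all_callers)) {
    have <- tapply(calls$caller, calls$sample_id,
                   function(x) all(require_all_callers %in% x))
    bad <- names(have)[!have]
    if (length(bad) > 0L) {
      warning(sprintf(
        "discarding %d sample(s) with missing/incomplete caller sets: %s",
        length(bad), paste(bad, collapse = ", ")), call. = FALSE)
      calls <- calls[!calls$sample_id %in% bad, , drop = FALSE]
    }
  }
  if (nrow(calls) == 0L) {
    return(tibble::tibble(sample_id = character(0), contig = character(0),
                          position = integer(0), ref = character(0),
                          alt = character(0), qual = numeric(0),
                          n_callers = integer(0), callers = character(0)))
  }
  merged <- dplyr::summarise(
    dplyr::group_by(calls, .data$sample_id, .data$contig, .data$position,
                    .data$ref, .data$alt),
    qual = max(.data$qual),
    n_callers = dplyr::n_distinct(.data$caller),
    callers = paste(sort(unique(.data$caller)), collapse = ","),
    .groups = "drop"
  )
  merged <- merged[merged$n_callers >= min_callers, , drop = FALSE]
  dplyr::arrange(merged, .data$sample_id, .data$contig, .data$position,
                 .data$alt)
}

#' Read sample metadata
#'
#' @param path TSV with columns sample_id, center, group, and optionally
#'   ethnicity and platform.
#' @return Tibble of metadata; errors if sample ids are duplicated or any
#'   group maps to more than one center.
#' @export
read_metadata <- function(path) {
  meta <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  req <- c("sample_id", "center", "group")
  if (!all(req %in% names(meta)))
    stop("metadata must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  g2c <- unique(meta[, c("group", "center")])
  if (anyDuplicated(g2c$group))
    stop("each group must map to exactly one sequencing center", call. = FALSE)
  meta
}

#' Ingest a cohort directory: read, filter, merge, and annotate calls
#'
#' End-to-end ingest over a directory of `<sample>.<caller>.vcf` files:
#' reads every VCF, applies the SNV + quality filter per caller (before
#' merging), merges callers in the requested mode, and annotates each
#' variant with the gene(s) whose exons contain it and the gene-exomic
#' coordinate. Variants inside two overlapping genes are annotated once per
#' gene; intergenic/intronic variants keep `NA`.
#'
#' @param vcf_dir Directory of per-sample, per-caller VCFs.
#' @param models A `gene_models` object (see [read_gene_models()]).
#' @param mode,min_callers Merging behaviour, see [merge_callers()].
#' @param min_qual Per-caller quality threshold applied before merging.
#' @param require_complete Drop samples that lack any caller's file.
#' @return Tibble: sample_id, contig, position, ref, alt, qual, n_callers,
#'   gene_id, gene_coord.
#' @export
ingest_cohort <- function(vcf_dir, models, mode = "consensus",
                          min_callers = 2L, min_qual = 30,
                          require_complete = TRUE) {
  files <- list.files(vcf_dir, pattern = "\\.vcf(\\.gz)?$", full.names = TRUE)
  if (length(files) == 0L) stop("no VCF files in ", vcf_dir, call. = FALSE)
  stem <- sub("\\.vcf(\\.gz)?$", "", basename(files))
  parts <- strsplit(stem, ".", fixed = TRUE)
  ok <- lengths(parts) >= 2L
  if (!all(ok)) stop("VCF files must be named <sample>.<caller>.vcf",
                     call. = FALSE)
  sample_ids <- vapply(parts, function(p) paste(p[-length(p)], collapse = "."),
                       character(1))
  caller_ids <- vapply(parts, function(p) p[length(p)], character(1))
  calls <- dplyr::bind_rows(lapply(seq_along(files), function(i) {
    filter_snv(read_vcf(files[i], caller_ids[i], sample_id = sample_ids[i]),
               min_qual = min_qual)
  }))
  merged <- merge_callers(
    calls, mode = mode, min_callers = min_callers,
    require_all_callers = if (require_complete) unique(caller_ids) else NULL
  )
  annotated <- annotate_gene_coords(merged, models)
  outside <- dplyr::anti_join(
    merged, annotated,
    by = c("sample_id", "contig", "position", "ref", "alt"))
  if (nrow(outside) > 0L) {
    outside$gene_id <- NA_character_
    outside$gene_coord <- NA_integer_
  }
  out <- dplyr::bind_rows(annotated, outside)
  dplyr::arrange(out, .data$sample_id, .data$contig, .data$position,
                 .data$alt, .data$gene_id)
}
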