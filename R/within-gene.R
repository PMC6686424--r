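#' Within-gene variant location collections per group
#'
#' For every gene and sample group (cancer type), collects the multiset of
#' gene-exomic coordinates of all called variants across the group's
#' samples. Duplicates are preserved: the same location — or the same
#' variant seen in several individuals — appears once per call, so a
#' variant called in two samples at position 183 contributes 183 twice.
#'
#' @param calls Annotated call tibble with sample_id, gene_id, gene_coord
#'   (rows with `NA` gene_id are ignored).
#' @param metadata Metadata tibble mapping sample_id to group.
#' @return Tibble: gene_id, group, `locations` (list column of sorted
#'   integer vectors), `k` (multiset size).
#' @export
build_location_collections <- function(calls, metadata) {
  calls <- calls[!is.na(calls$gene_id), , drop = FALSE]
  grp <- metadata$group[match(calls$sample_id, metadata$sample_id)]
  if (anyNA(grp))
    stop("calls contain samples absent from metadata", call. = FALSE)
  df <- tibble::tibble(gene_id = calls$gene_id, group = grp,
                       loc = calls$gene_coord)
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$gene_id, .data$group),
    locations = list(sort(.data$loc)),
    k = dplyr::n(),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$gene_id, .data$group)
}

#' Two-sided two-sample Kolmogorov-Smirnov test on location multisets
#'
#' The statistic is `D = sup_x |F1(x) - F2(x)|` where the empirical CDFs
#' are defined on the multisets: tied values raise the step height, so
#' discrete coordinate data is handled directly. The p-value comes from the
#' asymptotic two-sided Smirnov distribution evaluated at
#' `sqrt(n) * D` with effective size `n = k1 k2 / (k1 + k2)`; ties make it
#' anti-conservative, which is accepted and documented. `exact = TRUE`
#' computes the exact conditional p-value (permutation distribution given
#' the tie pattern, via [stats::psmirnov()]), intended as a validation aid
#' for small collections.
#'
#' @param x,y Numeric vectors (multisets of gene-exomic coordinates).
#' @param exact Use the exact conditional null distribution.
#' @return List: `d` statistic, `p` p-value in (0, 1], `n_eff`,
#'   `k1`, `k2`.
#' @examples
#' ks_two_sample(c(17, 65, 183, 183), c(17, 65, 183, 184))
#' @export
ks_two_sample <- function(x, y, exact = FALSE) {
  k1 <- length(x); k2 <- length(y)
  if (k1 < 1L || k2 < 1L) stop("both collections must be non-empty",
                               call. = FALSE)
  pooled <- sort(unique(c(x, y)))
  f1 <- findInterval(pooled, sort(x)) / k1
  f2 <- findInterval(pooled, sort(y)) / k2
  d <- max(abs(f1 - f2))
  n_eff <- k1 * k2 / (k1 + k2)
  p <- if (exact) {
    stats::psmirnov(d, sizes = c(k1, k2), z = c(x, y), two.sided = TRUE,
                    exact = TRUE, lower.tail = FALSE)
  } else {
    kolmogorov_upper(sqrt(n_eff) * d)
  }
  list(d = d, p = max(min(p, 1), .Machine$double.xmin),
       n_eff = n_eff, k1 = k1, k2 = k2)
}

# Upper tail of the asymptotic Kolmogorov distribution at lambda.
# Large-lambda alternating series; theta-function series below the
# Marsaglia crossover where the alternating series loses accuracy.
kolmogorov_upper <- function(lambda) {
  if (lambda < 1e-8) return(1)
  if (lambda < 1.18) {
    z <- exp(-pi^2 / (8 * lambda^2))
    cdf <- sqrt(2 * pi) / lambda * (z + z^9 + z^25 + z^49)
    return(max(0, min(1, 1 - cdf)))
  }
  k <- seq_len(101)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  max(min(p, 1), 0)
}

#' All-pairs KS matrix per gene
#'
#' Applies [ks_two_sample()] to every unordered pair of groups within each
#' gene (six groups give 15 pairs). A pair is evaluable only when both
#' collections have at least `min_k` locations; non-evaluable pairs are kept
#' with `NA` p-values and flagged.
#'
#' @param collections Tibble from [build_location_collections()].
#' @param groups Character vector fixing the group universe (defaults to
#'   groups present); genes missing a group get empty collections.
#' @param min_k Minimum collection size per side (default 3; 1 reproduces
#'   the any-variant-in-every-group behaviour).
#' @param exact Passed to [ks_two_sample()].
#' @return Tibble: gene_id, group1, group2, pair (`"g1|g2"`, sorted), k1,
#'   k2, d, p, evaluable.
#' @export
pairwise_ks <- function(collections, groups = NULL, min_k = 3L,
                        exact = FALSE) {
  if (is.null(groups)) groups <- sort(unique(collections$group))
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  pairs <- utils::combn(sort(groups), 2L)
  genes <- unique(collections$gene_id)
  key <- split(seq_len(nrow(collections)),
               collections$gene_id)
  rows <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    idx <- key[[genes[gi]]]
    locs <- stats::setNames(collections$locations[idx],
                            collections$group[idx])
    res <- lapply(seq_len(ncol(pairs)), function(j) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      l1 <- locs[[g1]] %||% integer(0)
      l2 <- locs[[g2]] %||% integer(0)
      if (length(l1) >= min_k && length(l2) >= min_k) {
        ks <- ks_two_sample(l1, l2, exact = exact)
        list(k1 = ks$k1, k2 = ks$k2, d = ks$d, p = ks$p, evaluable = TRUE)
      } else {
        list(k1 = length(l1), k2 = length(l2), d = NA_real_, p = NA_real_,
             evaluable = FALSE)
      }
    })
    rows[[gi]] <- tibble::tibble(
      gene_id = genes[gi],
      group1 = pairs[1, ], group2 = pairs[2, ],
      pair = paste(pairs[1, ], pairs[2, ], sep = "|"),
      k1 = vapply(res, `[[`, numeric(1), "k1"),
      k2 = vapply(res, `[[`, numeric(1), "k2"),
      d = vapply(res, `[[`, numeric(1), "d"),
      p = vapply(res, `[[`, numeric(1), "p"),
      evaluable = vapply(res, `[[`, logical(1), "evaluable")
    )
  }
  dplyr::bind_rows(rows)
}

#' Design of within-center and between-center group pairs
#'
#' The batch-sensitivity ratio compares KS p-values of group pairs sequenced
#' at the same center ("within", no batch difference expected) against pairs
#' from different centers ("between"). The `"reference"` design mirrors the
#' published audit: within pairs are all pairs among the reference center's
#' groups, between pairs cross the reference center with one designated
#' contrast center (other centers' pairs are left out). The `"generalized"`
#' design uses every same-center pair against every cross-center pair.
#'
#' @param groups Data frame with columns `group`, `center`.
#' @param type `"reference"` or `"generalized"`.
#' @param reference Reference center (default: center of the first group).
#' @param contrast Contrast center for the reference design (default: first
#'   other center with at least one group).
#' @return List of class `pair_design`: `within_pairs`, `between_pairs`
#'   (canonical `"g1|g2"` keys, g1 < g2).
#' @export
pair_design <- function(groups, type = c("reference", "generalized"),
                        reference = NULL, contrast = NULL) {
  type <- match.arg(type)
  groups <- unique(as.data.frame(groups)[, c("group", "center")])
  pkey <- function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "|")
  }
  all_pairs <- utils::combn(sort(groups$group), 2L)
  ctr <- stats::setNames(groups$center, groups$group)
  same <- ctr[all_pairs[1, ]] == ctr[all_pairs[2, ]]
  keys <- pkey(all_pairs[1, ], all_pairs[2, ])
  if (type == "generalized") {
    within <- keys[same]
    between <- keys[!same]
  } else {
    reference <- reference %||% groups$center[1]
    others <- setdiff(unique(groups$center), reference)
    contrast <- contrast %||% others[1]
    if (!reference %in% groups$center || !contrast %in% groups$center)
      stop("reference/contrast centers must own at least one group",
           call. = FALSE)
    within <- keys[same & ctr[all_pairs[1, ]] == reference]
    between <- keys[(ctr[all_pairs[1, ]] == reference &
                       ctr[all_pairs[2, ]] == contrast) |
                      (ctr[all_pairs[1, ]] == contrast &
                         ctr[all_pairs[2, ]] == reference)]
  }
  if (length(within) == 0L || length(between) == 0L)
    stop("design requires non-empty within and between pair sets",
         call. = FALSE)
  structure(list(within_pairs = sort(within), between_pairs = sort(between),
                 type = type),
            class = "pair_design")
}

#' Per-gene batch-sensitivity ratio r_g
#'
#' For each gene, `p_min` is the minimum KS p-value over the design's
#' within-center pairs and `p_max` the maximum over its between-center
#' pairs; the ratio `r_g = p_min / p_max` (with `p_max` floored at 1e-300
#' and `r_g` capped at 1e300) declares the gene possibly batch-affected
#' when `r_g > 1`. This is a conservative min-to-max rule: a gene is
#' affected only if every between-center p-value is smaller than every
#' within-center p-value. Genes with any non-evaluable design pair are
#' flagged not evaluable.
#'
#' @param ks_tbl Pairwise KS tibble from [pairwise_ks()].
#' @param design A [pair_design()].
#' @return Tibble: gene_id, p_min, p_max, r_g, affected, evaluable.
#' @export
batch_ratio <- function(ks_tbl, design) {
  stopifnot(inherits(design, "pair_design"))
  need <- c(design$within_pairs, design$between_pairs)
  sub <- ks_tbl[ks_tbl$pair %in% need, , drop = FALSE]
  per_gene <- split(sub, sub$gene_id)
  rows <- lapply(per_gene, function(g) {
    ok <- nrow(g) == length(need) && all(g$evaluable) &&
      setequal(g$pair, need)
    if (!ok) {
      return(tibble::tibble(gene_id = g$gene_id[1], p_min = NA_real_,
                            p_max = NA_real_, r_g = NA_real_,
                            affected = FALSE, evaluable = FALSE))
    }
    p_min <- min(g$p[g$pair %in% design$within_pairs])
    p_max <- max(g$p[g$pair %in% design$between_pairs])
    r_g <- min(p_min / max(p_max, 1e-300), 1e300)
    tibble::tibble(gene_id = g$gene_id[1], p_min = p_min, p_max = p_max,
                   r_g = r_g, affected = r_g > 1, evaluable = TRUE)
  })
  dplyr::bind_rows(rows)
}

#' Rank genes by batch sensitivity and extract decile gene sets
#'
#' Sorts genes by `r_g` descending (most batch-sensitive first; ties broken
#' lexicographically by gene id) and returns the top and bottom
#' `floor(decile * n)` genes.
#'
#' @param sensitivities Tibble from [batch_ratio()].
#' @param gene_subset Optional gene ids to restrict the ranking to (e.g. a
#'   cancer-predisposition panel); all must be evaluable.
#' @param decile Fraction for the extreme sets (default 0.10).
#' @return List: `ranked` (tibble in rank order), `top`, `bottom`
#'   (character vectors of gene ids).
#' @export
rank_and_partition <- function(sensitivities, gene_subset = NULL,
                               decile = 0.10) {
  s <- sensitivities
  if (!is.null(gene_subset)) s <- s[s$gene_id %in% gene_subset, , drop = FALSE]
  if (any(!s$evaluable))
    stop("all genes in the ranking must be evaluable", call. = FALSE)
  n_set <- floor(decile * nrow(s))
  if (n_set < 1L)
    stop("decile * n_genes is below 1; no extreme sets can be formed",
         call. = FALSE)
  o <- order(-s$r_g, s$gene_id)
  ranked <- s[o, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  list(ranked = ranked,
       top = ranked$gene_id[seq_len(n_set)],
       bottom = ranked$gene_id[seq.int(nrow(ranked) - n_set + 1L,
                                       nrow(ranked))])
}

#' Kernel density estimate of within-gene variant locations
#'
#' Gaussian KDE over gene-exomic coordinates `[0, L)` with bandwidth equal
#' to the window size, evaluated once per nucleotide and renormalised so the
#' curve integrates to 1 over the transcript (trapezoid rule). Presentation
#' only; no statistic is computed from the smoothed curve.
#'
#' @param locations Numeric vector of gene-exomic coordinates (k >= 1).
#' @param tx_length Transcript length L in nt.
#' @param window Kernel bandwidth in nt (default 100).
#' @return Tibble: `x` (0 .. L-1), `density`.
#' @export
kde_curve <- function(locations, tx_length, window = 100) {
  if (length(locations) < 1L) stop("need at least one location",
                                   call. = FALSE)
  n_grid <- max(as.integer(tx_length), 2L)
  d <- stats::density(locations, bw = window, from = 0, to = tx_length - 1,
                      n = n_grid)
  dx <- d$x[2] - d$x[1]
  mass <- sum((d$y[-1] + d$y[-n_grid]) / 2) * dx
  tibble::tibble(x = d$x, density = d$y / mass)
}

#' Plot per-group within-gene location densities for one gene
#'
#' One KDE curve per group, colored by sequencing center, with exon
#' boundaries marked along the gene-exomic axis.
#'
#' @param collections Tibble from [build_location_collections()] for one
#'   gene (or filtered to it via `gene_id`).
#' @param gene_id Gene to plot.
#' @param models A `gene_models` object.
#' @param metadata Metadata tibble (for center colors).
#' @param window KDE bandwidth in nt.
#' @return A ggplot object.
#' @export
plot_gene_densities <- function(collections, gene_id, models, metadata,
                                window = 100) {
  sub <- collections[collections$gene_id == gene_id, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no collections for gene ", gene_id,
                            call. = FALSE)
  L <- models$genes$tx_length[models$genes$gene_id == gene_id]
  g2c <- unique(metadata[, c("group", "center")])
  curves <- dplyr::bind_rows(lapply(seq_len(nrow(sub)), function(i) {
    if (sub$k[i] < 1L) return(NULL)
    cv <- kde_curve(sub$locations[[i]], L, window)
    cv$group <- sub$group[i]
    cv
  }))
  curves$center <- g2c$center[match(curves$group, g2c$group)]
  ex <- models$exons[models$exons$gene_id == gene_id, ]
  widths <- ex$end - ex$start
  bounds <- cumsum(widths)[-length(widths)]
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$x, y = .data$density,
                                       color = .data$center,
                                       group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = bounds, linetype = 3,
                        color = "grey70") +
    ggplot2::labs(title = paste("Within-gene variant location density:",
                                gene_id),
                  x = "gene-exomic coordinate (nt)", y = "density") +
    ggplot2::theme_minimal()
}

#' Bi-cluster the genes-by-pairs log10 p-value matrix
#'
#' Independent agglomerative hierarchical clusterings (average linkage,
#' Euclidean distance) of the rows (genes) and columns (group pairs) of the
#' log10 KS p-value matrix. Non-evaluable entries are imputed as
#' `log10(p) = 0` (p = 1) with a message.
#'
#' @param ks_tbl Pairwise KS tibble from [pairwise_ks()].
#' @param file Optional path: render the clustered heatmap (pheatmap).
#' @return List: `matrix` (genes x pairs, log10 p), `row_order`,
#'   `col_order` (leaf orders), `row_hclust`, `col_hclust`.
#' @export
bicluster_logp <- function(ks_tbl, file = NULL) {
  wide <- tidyr::pivot_wider(ks_tbl[, c("gene_id", "pair", "p")],
                             names_from = "pair", values_from = "p")
  m <- log10(as.matrix(wide[, -1, drop = FALSE]))
  rownames(m) <- wide$gene_id
  # canonical ordering so results do not depend on input row order
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  if (anyNA(m)) {
    message(sprintf("imputing %d non-evaluable entries as log10 p = 0",
                    sum(is.na(m))))
    m[is.na(m)] <- 0
  }
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("bi-clustering needs at least a 2 x 2 matrix", call. = FALSE)
  hr <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "average")
  hc <- stats::hclust(stats::dist(t(m), method = "euclidean"),
                      method = "average")
  if (!is.null(file)) {
    pheatmap::pheatmap(m, cluster_rows = hr, cluster_cols = hc,
                       show_rownames = nrow(m) <= 60,
                       main = "log10 KS p-values, genes x group pairs",
                       filename = file)
  }
  list(matrix = m, row_order = rownames(m)[hr$order],
       col_order = colnames(m)[hc$order], row_hclust = hr, col_hclust = hc)
}

#' Distribution of KS p-values per group pair across all genes
#'
#' For every group pair, collects `-log10 p` across all evaluable genes and
#' labels the pair within-center or between-center. Values above `trunc` are
#' truncated for plotting; the table keeps the untruncated values.
#'
#' @param ks_tbl Pairwise KS tibble from [pairwise_ks()].
#' @param metadata Metadata tibble (for pair center labels).
#' @param trunc Plotting truncation for `-log10 p` (default 2.5).
#' @param file Optional path for the violin figure.
#' @return Tibble: pair, group1, group2, pair_type, gene_id, p, neglog10p,
#'   neglog10p_plot.
#' @export
pairwise_violin_summary <- function(ks_tbl, metadata, trunc = 2.5,
                                    file = NULL) {
  g2c <- unique(metadata[, c("group", "center")])
  ctr <- stats::setNames(g2c$center, g2c$group)
  tab <- ks_tbl[ks_tbl$evaluable, , drop = FALSE]
  tab$pair_type <- unname(ifelse(ctr[tab$group1] == ctr[tab$group2],
                                 "within-center", "between-center"))
  tab$neglog10p <- -log10(tab$p)
  tab$neglog10p_plot <- pmin(tab$neglog10p, trunc)
  out <- tab[, c("pair", "group1", "group2", "pair_type", "gene_id", "p",
                 "neglog10p", "neglog10p_plot")]
  if (!is.null(file)) {
    gg <- ggplot2::ggplot(out, ggplot2::aes(x = .data$pair,
                                            y = .data$neglog10p_plot,
                                            fill = .data$pair_type)) +
      ggplot2::geom_violin(scale = "width") +
      ggplot2::labs(x = NULL, y = sprintf("-log10 p (truncated at %.1f)",
                                          trunc)) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                         hjust = 1))
    ggplot2::ggsave(file, gg, width = 9, height = 5)
  }
  out
}
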