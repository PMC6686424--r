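#' Gene/transcript models with a genomic-to-gene-exomic coordinate map
#'
#' A `gene_models` object holds transcript structures: one row per gene
#' (`gene_id`, `contig`, `strand`, `start`, `end`, `tx_length`) plus an exon
#' table (`gene_id`, `start`, `end`, `rank`) with 0-based half-open genomic
#' intervals, ranked in genomic order. The gene-exomic coordinate of a
#' position is its 0-based offset within the concatenation of exons in
#' transcript order; for minus-strand genes the concatenation runs 3' to 5'
#' genomically.
#'
#' @name gene_models
NULL

new_gene_models <- function(genes, exons) {
  genes <- tibble::as_tibble(genes)
  exons <- tibble::as_tibble(exons)
  exons <- dplyr::arrange(exons, .data$gene_id, .data$start)
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes, %d exons, contigs: %s\n",
              nrow(x$genes), nrow(x$exons),
              paste(unique(x$genes$contig), collapse = ", ")))
  invisible(x)
}

#' Generate synthetic gene models
#'
#' Lays `config$n_genes` non-overlapping genes along one synthetic contig.
#' Exon counts and lengths are drawn uniformly from the configured ranges;
#' exons within a gene are separated by uniform intron gaps, so they are
#' ordered, disjoint, and strictly inside the gene span. Strands alternate
#' deterministically pseudo-randomly. Transcript length is the sum of exon
#' lengths.
#'
#' @param config A [cohort_config()].
#' @return A `gene_models` object.
#' @examples
#' gm <- generate_gene_models(cohort_config(n_genes = 5, seed = 1))
#' gm$genes
#' @export
generate_gene_models <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(derive_seed(config$seed, "genes"), {
    n <- config$n_genes
    contig <- "chrS"
    cursor <- 1000L
    genes <- vector("list", n)
    exons <- vector("list", n)
    # sample() interprets a length-1 vector as 1:n; draw from ranges safely
    runi <- function(lo, hi, size) {
      lo + sample.int(hi - lo + 1L, size, replace = TRUE) - 1L
    }
    for (i in seq_len(n)) {
      gid <- sprintf("G%04d", i)
      k <- runi(config$exon_count[1], config$exon_count[2], 1L)
      lens <- runi(config$exon_length[1], config$exon_length[2], k)
      gaps <- if (k > 1L) {
        runi(config$intron_length[1], config$intron_length[2], k - 1L)
      } else integer(0)
      starts <- cursor + c(0L, cumsum(lens[-k] + gaps))
      ends <- starts + lens
      strand <- sample(c("+", "-"), 1L)
      genes[[i]] <- tibble::tibble(
        gene_id = gid, contig = contig, strand = strand,
        start = starts[1], end = ends[k], tx_length = sum(lens)
      )
      exons[[i]] <- tibble::tibble(gene_id = gid, start = starts, end = ends,
                                   rank = seq_len(k))
      cursor <- ends[k] + runi(500L, 2000L, 1L)
    }
    new_gene_models(dplyr::bind_rows(genes), dplyr::bind_rows(exons))
  })
}

#' Write gene models as BED12
#'
#' One BED12 line per gene: 0-based half-open chromStart/chromEnd, exon
#' blocks as blockSizes/blockStarts relative to chromStart.
#'
#' @param models A `gene_models` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  lines <- vapply(seq_len(nrow(models$genes)), function(i) {
    g <- models$genes[i, ]
    ex <- models$exons[models$exons$gene_id == g$gene_id, ]
    ex <- ex[order(ex$start), ]
    paste(g$contig, g$start, g$end, g$gene_id, 0L, g$strand, g$start, g$end,
          "0", nrow(ex),
          paste0(paste(ex$end - ex$start, collapse = ","), ","),
          paste0(paste(ex$start - g$start, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a BED12 file
#'
#' Imports via `rtracklayer` and converts exon blocks to the internal
#' 0-based half-open exon table.
#'
#' @param path BED12 file path.
#' @return A `gene_models` object.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$blocks)) {
    blocks <- IRanges::IRangesList(lapply(IRanges::width(gr), function(w)
      IRanges::IRanges(1L, w)))
  } else {
    blocks <- gr$blocks
  }
  genes <- vector("list", length(gr))
  exons <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    gstart0 <- BiocGenerics::start(gr)[i] - 1L # back to 0-based
    b <- blocks[[i]]
    ex_start <- gstart0 + BiocGenerics::start(b) - 1L
    ex_end <- ex_start + BiocGenerics::width(b)
    o <- order(ex_start)
    genes[[i]] <- tibble::tibble(
      gene_id = gr$name[i],
      contig = as.character(GenomicRanges::seqnames(gr))[i],
      strand = as.character(BiocGenerics::strand(gr))[i],
      start = gstart0, end = gstart0 + BiocGenerics::width(gr)[i],
      tx_length = sum(BiocGenerics::width(b))
    )
    exons[[i]] <- tibble::tibble(gene_id = gr$name[i], start = ex_start[o],
                                 end = ex_end[o], rank = seq_along(o))
  }
  new_gene_models(dplyr::bind_rows(genes), dplyr::bind_rows(exons))
}

#' Map a genomic position to a gene-exomic coordinate
#'
#' Returns the 0-based offset of a 1-based genomic position within the
#' concatenation of a gene's exons in transcript order (strand-aware), or
#' `NA` for intronic/intergenic positions or a contig mismatch.
#'
#' @param contig,position Genomic location (1-based position).
#' @param gene_id Gene to map into.
#' @param models A `gene_models` object.
#' @return Integer gene-exomic coordinate or `NA`.
#' @examples
#' gm <- generate_gene_models(cohort_config(n_genes = 2, seed = 1))
#' g <- gm$genes$gene_id[1]
#' map_to_gene_coordinate(gm$genes$contig[1], gm$exons$start[1] + 1, g, gm)
#' @export
map_to_gene_coordinate <- function(contig, position, gene_id, models) {
  g <- models$genes[models$genes$gene_id == gene_id, ]
  if (nrow(g) != 1L || !identical(as.character(contig), g$contig)) return(NA_integer_)
  ex <- models$exons[models$exons$gene_id == gene_id, ]
  ex <- ex[order(ex$start), ]
  b <- as.integer(position) - 1L # 0-based base
  hit <- which(b >= ex$start & b < ex$end)
  if (length(hit) == 0L) return(NA_integer_)
  widths <- ex$end - ex$start
  before <- if (hit > 1L) sum(widths[seq_len(hit - 1L)]) else 0L
  fwd <- before + (b - ex$start[hit])
  if (g$strand == "-") as.integer(g$tx_length - 1L - fwd) else as.integer(fwd)
}

# Inverse map used by the simulator: gene-exomic coordinate -> 1-based
# genomic position. Vectorised over coord for a single gene.
gene_to_genomic <- function(coord, gene_id, models) {
  g <- models$genes[models$genes$gene_id == gene_id, ]
  ex <- models$exons[models$exons$gene_id == gene_id, ]
  ex <- ex[order(ex$start), ]
  widths <- ex$end - ex$start
  cum <- cumsum(widths)
  fwd <- if (g$strand == "-") g$tx_length - 1L - coord else coord
  idx <- findInterval(fwd, c(0L, cum), rightmost.closed = FALSE)
  before <- c(0L, cum)[idx]
  as.integer(ex$start[idx] + (fwd - before) + 1L)
}

# Vectorised exon-overlap annotation: assigns each call to every gene whose
# exons contain it and computes the gene-exomic coordinate. A call inside two
# overlapping genes yields one output row per gene.
annotate_gene_coords <- function(calls, models) {
  stopifnot(inherits(models, "gene_models"))
  if (nrow(calls) == 0L) {
    return(dplyr::mutate(calls, gene_id = character(0), gene_coord = integer(0)))
  }
  ex <- dplyr::inner_join(models$exons, models$genes[, c("gene_id", "contig", "strand", "tx_length")],
                          by = "gene_id")
  ex <- dplyr::arrange(ex, .data$gene_id, .data$start)
  ex <- dplyr::group_by(ex, .data$gene_id)
  ex <- dplyr::mutate(ex, before = cumsum(.data$end - .data$start) - (.data$end - .data$start))
  ex <- dplyr::ungroup(ex)
  out <- vector("list", length(unique(ex$contig)))
  for (ctg in unique(ex$contig)) {
    exc <- ex[ex$contig == ctg, ]
    cc <- calls[calls$contig == ctg, ]
    if (nrow(cc) == 0L) next
    # IRanges on 1-based closed intervals: exon [start, end) -> [start+1, end]
    q <- IRanges::IRanges(cc$position, cc$position)
    s <- IRanges::IRanges(exc$start + 1L, exc$end)
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov) == 0L) next
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    fwd <- exc$before[si] + (cc$position[qi] - 1L - exc$start[si])
    coord <- ifelse(exc$strand[si] == "-", exc$tx_length[si] - 1L - fwd, fwd)
    res <- cc[qi, ]
    res$gene_id <- exc$gene_id[si]
    res$gene_coord <- as.integer(coord)
    out[[ctg]] <- res
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- dplyr::mutate(calls[0, ], gene_id = character(0), gene_coord = integer(0))
  }
  res
}
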