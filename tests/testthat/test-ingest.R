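make_vcf <- function(lines, path = withr::local_tempfile(fileext = ".vcf",
                                                         .local_envir = parent.frame())) {
  hdr <- c("##fileformat=VCFv4.2", "##contig=<ID=chr1>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "S1", sep = "\t"))
  writeLines(c(hdr, lines), path)
  path
}

test_that("read_vcf parses records and splits multi-allelic ALTs", {
  p <- make_vcf(c("chr1\t100\t.\tA\tG\t60\tPASS\t.\tGT\t0/1",
                  "chr1\t200\t.\tC\tA,T\t50\tPASS\t.\tGT\t1/2"))
  calls <- read_vcf(p, "gatk")
  expect_equal(nrow(calls), 3L)
  expect_equal(calls$position, c(100L, 200L, 200L))
  expect_equal(calls$alt, c("G", "A", "T"))
  expect_equal(unique(calls$caller), "gatk")
  expect_equal(unique(calls$sample_id), "S1")
  expect_error(read_vcf(file.path(tempdir(), "nope.vcf"), "x"), "not found")
})

test_that("VCF write/read round-trip preserves the call multiset", {
  coh <- clean_cohort()
  d <- withr::local_tempdir()
  write_cohort(coh, d)
  files <- list.files(d, pattern = "\\.vcf$", full.names = TRUE)
  back <- dplyr::bind_rows(lapply(files, function(f) {
    parts <- strsplit(sub("\\.vcf$", "", basename(f)), ".", fixed = TRUE)[[1]]
    read_vcf(f, parts[2], sample_id = parts[1])
  }))
  key <- function(df) {
    df <- df[order(df$sample_id, df$position, df$ref, df$alt), ]
    paste(df$sample_id, df$contig, df$position, df$ref, df$alt)
  }
  expect_identical(key(back), key(coh$calls))
})

test_that("filter_snv keeps only qualifying SNVs, inclusive at the threshold", {
  calls <- tibble::tibble(
    sample_id = "s", caller = "c", contig = "chr1",
    position = 1:6,
    ref = c("AT", "A", "C", "G", "T", "A"),
    alt = c("A", "AT", "T", "A", "C", "G"),
    qual = c(99, 99, 30, 29.9, 99, NA)
  )
  out <- filter_snv(calls, min_qual = 30)
  # deletion and insertion removed; qual 30 kept (boundary inclusive);
  # 29.9 and missing qual dropped
  expect_equal(out$position, c(3L, 5L))
  mixed <- tibble::tibble(sample_id = "s", caller = "c", contig = "chr1",
                          position = 1:5,
                          ref = c("A", "C", "G", "ACG", "T"),
                          alt = c("G", "T", "A", "A", "TA"),
                          qual = rep(99, 5))
  expect_equal(nrow(filter_snv(mixed)), 3L)
})

test_that("consensus merging follows the at-least-k-callers rule", {
  calls <- tibble::tibble(
    sample_id = "s",
    caller = c("c1", "c2", "c1", "c1", "c2", "c3", "c4"),
    contig = "chr1",
    position = c(10L, 10L, 20L, 30L, 30L, 30L, 30L),
    ref = "A", alt = "G", qual = 50
  )
  cons <- merge_callers(calls, mode = "consensus", min_callers = 2L)
  # pos 10 in 2/4 callers kept; pos 20 in 1/4 dropped; pos 30 in 4/4 kept
  expect_equal(cons$position, c(10L, 30L))
  expect_equal(cons$n_callers, c(2L, 4L))
  uni <- merge_callers(calls, mode = "union")
  expect_equal(uni$position, c(10L, 20L, 30L))
})

test_that("consensus at min_callers 1 equals union and merging is monotone", {
  coh <- generate_cohort(make_config(n_samples = 4L, n_genes = 10L,
                                     seed = 31L, n_callers = 4L,
                                     fp_rate = 0.1, fn_rate = 0.15))
  uni <- merge_callers(coh$calls, mode = "union")
  c1 <- merge_callers(coh$calls, mode = "consensus", min_callers = 1L)
  expect_identical(as.data.frame(uni), as.data.frame(c1))
  prev <- uni
  for (k in 2:4) {
    ck <- merge_callers(coh$calls, mode = "consensus", min_callers = k)
    expect_lte(nrow(ck), nrow(prev))
    key <- function(df) paste(df$sample_id, df$position, df$ref, df$alt)
    expect_true(all(key(ck) %in% key(prev)))
    prev <- ck
  }
  empty <- coh$calls[0, ]
  expect_equal(nrow(merge_callers(empty, mode = "union")), 0L)
  expect_equal(nrow(merge_callers(empty, mode = "consensus",
                                  min_callers = 2L)), 0L)
})

test_that("samples with incomplete caller sets are discarded with a warning", {
  calls <- tibble::tibble(
    sample_id = c("s1", "s1", "s2"),
    caller = c("c1", "c2", "c1"),
    contig = "chr1", position = 10L, ref = "A", alt = "G", qual = 50
  )
  expect_warning(
    out <- merge_callers(calls, mode = "consensus", min_callers = 2L,
                         require_all_callers = c("c1", "c2")),
    "s2"
  )
  expect_equal(unique(out$sample_id), "s1")
})

test_that("gene-exomic coordinates match per-base enumeration on both strands", {
  gm <- varbatch:::new_gene_models(
    genes = tibble::tibble(gene_id = c("gp", "gm"), contig = "chr1",
                           strand = c("+", "-"),
                           start = c(100L, 1000L), end = c(400L, 1300L),
                           tx_length = c(80L, 80L)),
    exons = tibble::tibble(gene_id = c("gp", "gp", "gm", "gm"),
                           start = c(100L, 300L, 1000L, 1200L),
                           end = c(150L, 330L, 1050L, 1230L),
                           rank = c(1L, 2L, 1L, 2L))
  )
  # brute-force: walk the exon concatenation base by base
  enumerate <- function(gid) {
    ex <- gm$exons[gm$exons$gene_id == gid, ]
    bases <- unlist(lapply(seq_len(nrow(ex)), function(i)
      seq.int(ex$start[i], ex$end[i] - 1L)))
    strand <- gm$genes$strand[gm$genes$gene_id == gid]
    if (strand == "-") bases <- rev(bases)
    bases
  }
  for (gid in c("gp", "gm")) {
    bases <- enumerate(gid)
    got <- vapply(seq_along(bases), function(i) {
      map_to_gene_coordinate("chr1", bases[i] + 1L, gid, gm)
    }, integer(1))
    expect_equal(got, seq_along(bases) - 1L, label = gid)
  }
  # + strand, exon1 length 50: third base of exon 2 -> coordinate 52
  expect_equal(map_to_gene_coordinate("chr1", 303L, "gp", gm), 52L)
  # origin, intron, intergenic, contig mismatch
  expect_equal(map_to_gene_coordinate("chr1", 101L, "gp", gm), 0L)
  expect_true(is.na(map_to_gene_coordinate("chr1", 200L, "gp", gm)))
  expect_true(is.na(map_to_gene_coordinate("chr1", 500L, "gp", gm)))
  expect_true(is.na(map_to_gene_coordinate("chrX", 101L, "gp", gm)))
})

test_that("the coordinate map is injective with image exactly [0, L)", {
  gm <- generate_gene_models(make_config(n_genes = 8L, seed = 41L))
  for (gid in gm$genes$gene_id) {
    g <- gm$genes[gm$genes$gene_id == gid, ]
    ex <- gm$exons[gm$exons$gene_id == gid, ]
    bases <- unlist(lapply(seq_len(nrow(ex)), function(i)
      seq.int(ex$start[i], ex$end[i] - 1L)))
    coords <- vapply(bases + 1L, function(p)
      map_to_gene_coordinate(g$contig, p, gid, gm), integer(1))
    expect_setequal(coords, 0:(g$tx_length - 1L))
    expect_equal(anyDuplicated(coords), 0L)
  }
})

test_that("BED12 round-trip preserves gene models", {
  gm <- generate_gene_models(make_config(n_genes = 12L, seed = 51L))
  p <- withr::local_tempfile(fileext = ".bed")
  write_gene_models(gm, p)
  back <- read_gene_models(p)
  o <- match(gm$genes$gene_id, back$genes$gene_id)
  expect_equal(as.data.frame(back$genes[o, ]), as.data.frame(gm$genes))
  expect_equal(as.data.frame(dplyr::arrange(back$exons, gene_id, start)),
               as.data.frame(dplyr::arrange(gm$exons, gene_id, start)))
})

test_that("ingest_cohort produces the fixed schema and honours consensus", {
  coh <- generate_cohort(make_config(n_samples = 3L, n_genes = 10L,
                                     seed = 61L, n_callers = 3L,
                                     fp_rate = 0.2, fn_rate = 0.1))
  d <- withr::local_tempdir()
  write_cohort(coh, d)
  out <- ingest_cohort(d, coh$models, mode = "consensus", min_callers = 2L)
  expect_true(all(c("sample_id", "contig", "position", "ref", "alt", "qual",
                    "n_callers", "gene_id", "gene_coord") %in% names(out)))
  expect_true(all(out$n_callers >= 2L))
  uni <- ingest_cohort(d, coh$models, mode = "union")
  expect_gte(nrow(uni), nrow(out))
})
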