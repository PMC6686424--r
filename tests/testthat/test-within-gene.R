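# metadata for a six-group, three-center design mirroring the default cohort
six_group_meta <- function(samples_per_group = 4L) {
  groups <- data.frame(
    group = c("SKCM", "STAD", "THCA", "BRCA", "UCEC", "LIHC"),
    center = c("BI", "BI", "BI", "WUGSC", "WUGSC", "BCM")
  )
  do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    data.frame(sample_id = sprintf("%s_%02d", groups$group[i],
                                   seq_len(samples_per_group)),
               group = groups$group[i], center = groups$center[i])
  }))
}

test_that("location collections preserve duplicates across samples", {
  meta <- six_group_meta()
  calls <- tibble::tibble(
    sample_id = c("SKCM_01", "SKCM_02", "SKCM_03", "SKCM_04"),
    gene_id = "KRAS",
    gene_coord = c(17L, 65L, 183L, 183L)
  )
  coll <- build_location_collections(calls, meta)
  expect_equal(nrow(coll), 1L)
  expect_equal(coll$locations[[1]], c(17L, 65L, 183L, 183L))
  expect_equal(coll$k, 4L)
  expect_error(build_location_collections(
    tibble::tibble(sample_id = "ghost", gene_id = "KRAS", gene_coord = 1L),
    meta), "absent")
})

test_that("KS statistic handles identity, disjoint supports and ties", {
  L <- c(17, 65, 183, 183)
  same <- ks_two_sample(L, L)
  expect_equal(same$d, 0)
  expect_equal(same$p, 1)
  disj <- ks_two_sample(c(1, 2, 3), c(101, 102, 103))
  expect_equal(disj$d, 1)
  tied <- ks_two_sample(L, c(17, 65, 183, 184))
  expect_equal(tied$d, oracle_ks_d(L, c(17, 65, 183, 184)))
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("KS D equals the brute-force ECDF oracle on enumerated multisets", {
  sets <- c(enumerate_multisets(1, 5), enumerate_multisets(2, 5),
            enumerate_multisets(3, 5))
  for (i in seq_along(sets)) {
    for (j in seq.int(i, length(sets))) {
      x <- sets[[i]]; y <- sets[[j]]
      expect_equal(ks_two_sample(x, y)$d, oracle_ks_d(x, y),
                   tolerance = 1e-14)
    }
  }
  # larger random multisets over 0..9 with heavy ties
  set.seed(23)
  for (r in 1:200) {
    x <- sample(0:9, sample(1:8, 1), replace = TRUE)
    y <- sample(0:9, sample(1:8, 1), replace = TRUE)
    expect_equal(ks_two_sample(x, y)$d, oracle_ks_d(x, y), tolerance = 1e-14)
  }
})

test_that("KS is symmetric and invariant under monotone relabelings", {
  set.seed(29)
  for (r in 1:50) {
    x <- sample(0:50, sample(3:12, 1), replace = TRUE)
    y <- sample(0:50, sample(3:12, 1), replace = TRUE)
    a <- ks_two_sample(x, y)
    b <- ks_two_sample(y, x)
    expect_equal(a$d, b$d)
    expect_equal(a$p, b$p)
    for (f in list(function(v) 2 * v + 3, function(v) exp(v / 10))) {
      m <- ks_two_sample(f(x), f(y))
      expect_equal(m$d, a$d)
      expect_equal(m$p, a$p)
    }
  }
})

test_that("asymptotic p-values agree with stats::ks.test on untied data", {
  set.seed(31)
  for (r in 1:20) {
    x <- rnorm(sample(10:60, 1))
    y <- rnorm(sample(10:60, 1), mean = runif(1, 0, 1))
    ours <- ks_two_sample(x, y)
    ref <- stats::ks.test(x, y, exact = FALSE)
    expect_equal(ours$d, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-4)
  }
})

test_that("exact p-values match the conditional permutation distribution", {
  x <- c(0, 1, 1, 3)
  y <- c(1, 2, 3, 3)
  ours <- ks_two_sample(x, y, exact = TRUE)
  ref <- stats::psmirnov(ours$d, sizes = c(4, 4), z = c(x, y),
                         two.sided = TRUE, exact = TRUE, lower.tail = FALSE)
  expect_equal(ours$p, ref)
})

test_that("pairwise KS produces one entry per unordered group pair", {
  meta <- six_group_meta()
  set.seed(37)
  calls <- tibble::tibble(
    sample_id = sample(meta$sample_id, 600, replace = TRUE),
    gene_id = sample(c("g1", "g2"), 600, replace = TRUE),
    gene_coord = sample(0:499, 600, replace = TRUE)
  )
  coll <- build_location_collections(calls, meta)
  ks6 <- pairwise_ks(coll, groups = unique(meta$group))
  expect_equal(sum(ks6$gene_id == "g1"), 15L) # C(6, 2)
  expect_true(all(table(ks6$gene_id) == 15L))
  ks2 <- pairwise_ks(coll[coll$group %in% c("SKCM", "BRCA"), ],
                     groups = c("SKCM", "BRCA"))
  expect_true(all(table(ks2$gene_id) == 1L))
  # identical collections across all groups -> all p = 1
  same <- tibble::tibble(
    gene_id = "g", group = unique(meta$group),
    locations = replicate(6, c(5L, 9L, 9L, 20L), simplify = FALSE),
    k = 4L)
  kss <- pairwise_ks(same, groups = unique(meta$group))
  expect_equal(kss$p, rep(1, 15))
  # undersized collections flagged not evaluable
  tiny <- same
  tiny$locations[[1]] <- c(1L, 2L)
  tiny$k[1] <- 2L
  kst <- pairwise_ks(tiny, groups = unique(meta$group), min_k = 3L)
  expect_equal(sum(!kst$evaluable), 5L)
})

test_that("pair designs split within- and between-center pairs correctly", {
  groups <- unique(six_group_meta()[, c("group", "center")])
  ref <- pair_design(groups, type = "reference", reference = "BI",
                     contrast = "WUGSC")
  expect_setequal(ref$within_pairs,
                  c("SKCM|STAD", "SKCM|THCA", "STAD|THCA"))
  expect_length(ref$between_pairs, 6L)
  expect_true(all(grepl("BRCA|UCEC", ref$between_pairs)))
  gen <- pair_design(groups, type = "generalized")
  expect_length(gen$within_pairs, 4L) # 3 BI pairs + 1 WUGSC pair
  expect_length(gen$between_pairs, 11L)
  expect_length(intersect(gen$within_pairs, gen$between_pairs), 0L)
})

test_that("batch ratio follows the min/max arithmetic and boundary rule", {
  groups <- unique(six_group_meta()[, c("group", "center")])
  design <- pair_design(groups, type = "reference", reference = "BI",
                        contrast = "WUGSC")
  mk <- function(within_p, between_p) {
    tibble::tibble(
      gene_id = "g",
      pair = c(design$within_pairs, design$between_pairs),
      p = c(within_p, between_p),
      evaluable = TRUE
    )
  }
  res <- batch_ratio(mk(c(0.5, 0.6, 0.7),
                        c(0.01, 0.05, 0.1, 0.15, 0.18, 0.2)), design)
  expect_equal(res$r_g, 0.5 / 0.2)
  expect_true(res$affected)
  # all nine p-values equal: r = 1, strict inequality -> not affected
  eq <- batch_ratio(mk(rep(0.3, 3), rep(0.3, 6)), design)
  expect_equal(eq$r_g, 1)
  expect_false(eq$affected)
  # missing design pair -> not evaluable
  broken <- mk(c(0.5, 0.6, 0.7), c(0.01, 0.05, 0.1, 0.15, 0.18, 0.2))[-1, ]
  nb <- batch_ratio(broken, design)
  expect_false(nb$evaluable)
  expect_true(is.na(nb$r_g))
})

test_that("affected verdicts are exactly the conservative all-pairs rule", {
  coh <- shifted_cohort()
  ann <- annotated_calls(coh)
  coll <- build_location_collections(ann, coh$metadata)
  ks_tbl <- pairwise_ks(coll, groups = sort(unique(coh$metadata$group)))
  design <- pair_design(unique(coh$metadata[, c("group", "center")]),
                        type = "reference", reference = "BI",
                        contrast = "WUGSC")
  sens <- batch_ratio(ks_tbl, design)
  sens <- sens[sens$evaluable, ]
  expect_gt(nrow(sens), 10)
  for (i in seq_len(nrow(sens))) {
    g <- ks_tbl[ks_tbl$gene_id == sens$gene_id[i], ]
    w <- g$p[g$pair %in% design$within_pairs]
    b <- g$p[g$pair %in% design$between_pairs]
    expect_equal(sens$affected[i], all(max(b) < min(w)))
  }
})

test_that("ranking and decile partition are stable and sized by floor", {
  sens <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:104),
    p_min = 0.5, p_max = 0.5,
    r_g = c(rep(2, 4), seq(1.9, 0.2, length.out = 100)),
    affected = TRUE, evaluable = TRUE
  )
  parts <- rank_and_partition(sens, decile = 0.10)
  expect_length(parts$top, 10L)
  expect_length(parts$bottom, 10L)
  # ties at r = 2 broken lexicographically by gene id
  expect_equal(parts$top[1:4], c("g001", "g002", "g003", "g004"))
  expect_equal(parts$ranked$rank, 1:104)
  small <- rank_and_partition(sens[1:10, ], decile = 0.10)
  expect_length(small$top, 1L)
  expect_error(rank_and_partition(sens[1:5, ], decile = 0.10), "below 1")
  bad <- sens
  bad$evaluable[1] <- FALSE
  expect_error(rank_and_partition(bad), "evaluable")
})

test_that("KDE curves normalise to unit mass and peak at the data", {
  single <- kde_curve(500, tx_length = 1000, window = 50)
  expect_equal(single$x[which.max(single$density)], 500, tolerance = 2)
  dx <- diff(single$x[1:2])
  mass <- sum((single$density[-1] + single$density[-nrow(single)]) / 2) * dx
  expect_equal(mass, 1, tolerance = 1e-6)
  # two well-separated equal clusters carry equal mass within 1%
  locs <- c(rnorm(500, 200, 10), rnorm(500, 1800, 10))
  cv <- kde_curve(locs, tx_length = 2000, window = 40)
  half <- cv$x <= 1000
  m1 <- sum(cv$density[half]) * diff(cv$x[1:2])
  m2 <- sum(cv$density[!half]) * diff(cv$x[1:2])
  expect_equal(m1 / (m1 + m2), 0.5, tolerance = 0.01)
})

test_that("bi-clustering keeps exact column blocks contiguous", {
  set.seed(41)
  genes <- sprintf("g%02d", 1:20)
  within_pairs <- c("A|B", "A|C", "B|C")
  between_pairs <- c("A|D", "B|D", "C|D")
  tbl <- dplyr::bind_rows(lapply(genes, function(g) {
    tibble::tibble(
      gene_id = g,
      pair = c(within_pairs, between_pairs),
      p = c(stats::runif(3, 0.5, 1), stats::runif(3, 1e-4, 1e-3)),
      evaluable = TRUE
    )
  }))
  bc <- bicluster_logp(tbl)
  pos <- match(c(within_pairs, between_pairs), bc$col_order)
  within_pos <- sort(pos[1:3])
  expect_equal(within_pos, seq(within_pos[1], within_pos[1] + 2))
  # row permutation: same column order, same row cluster structure
  perm_tbl <- tbl[sample(nrow(tbl)), ]
  bc2 <- bicluster_logp(perm_tbl)
  expect_identical(bc$col_order, bc2$col_order)
  ct1 <- stats::cutree(bc$row_hclust, k = 3)
  ct2 <- stats::cutree(bc2$row_hclust, k = 3)[names(ct1)]
  expect_equal(length(unique(paste(ct1, ct2))), 3L)
  # 2x2 is the smallest legal input
  tiny <- tbl[tbl$gene_id %in% genes[1:2] & tbl$pair %in% c("A|B", "A|D"), ]
  bc3 <- bicluster_logp(tiny)
  expect_length(bc3$row_order, 2L)
  expect_error(bicluster_logp(tiny[tiny$gene_id == genes[1], ]), "2 x 2")
})

test_that("violin summary truncates for plotting but keeps raw values", {
  meta <- six_group_meta()
  tbl <- tibble::tibble(
    gene_id = "g", group1 = c("SKCM", "SKCM"), group2 = c("STAD", "BRCA"),
    pair = c("SKCM|STAD", "BRCA|SKCM"), p = c(1, 1e-5), evaluable = TRUE
  )
  out <- pairwise_violin_summary(tbl, meta)
  expect_equal(out$neglog10p, c(0, 5))
  expect_equal(out$neglog10p_plot, c(0, 2.5))
  expect_equal(out$pair_type, c("within-center", "between-center"))
})

test_that("a strong shift separates between-center from within-center p-values", {
  coh <- shifted_cohort()
  ann <- annotated_calls(coh)
  coll <- build_location_collections(ann, coh$metadata)
  ks_tbl <- pairwise_ks(coll, groups = sort(unique(coh$metadata$group)))
  out <- pairwise_violin_summary(ks_tbl, coh$metadata)
  # restrict to pairs involving the reference center, where the shift acts
  ref_groups <- c("SKCM", "STAD", "THCA")
  crossing <- xor(out$group1 %in% ref_groups, out$group2 %in% ref_groups)
  aff <- coh$truth$genes$gene_id[coh$truth$genes$affected]
  sel <- out$gene_id %in% aff
  med_between <- stats::median(out$neglog10p[sel & crossing])
  med_within <- stats::median(out$neglog10p[sel & !crossing &
                                              out$pair_type == "within-center"])
  expect_gt(med_between, med_within)
})
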