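genes <- sprintf("g%02d", 1:5)

test_that("round-1 applies the triple criterion and direction labels", {
  # g1 passes everything (up); g2 fails day-0 equivalence by significance;
  # g3 fails it on fold change; g4 lacks a significant drought contrast;
  # g5 has conflicting cross signs on the two days -> ambiguous
  de_day0 <- fake_de(genes,
                     p_value = c(0.8, 0.01, 0.9, 0.7, 0.9),
                     log2fc = c(0.1, 0.2, 1.5, 0.0, 0.1))
  de_tol <- list(
    "6" = fake_de(genes, q_value = c(0.001, 0.001, 0.001, 0.5, 0.001),
                  log2fc = 2),
    "10" = fake_de(genes, q_value = 0.5, log2fc = 0.2))
  de_cross <- list(
    "6" = fake_de(genes, q_value = c(0.001, 0.001, 0.001, 0.001, 0.001),
                  log2fc = c(2, 2, 2, 2, 2)),
    "10" = fake_de(genes, q_value = c(0.5, 0.5, 0.5, 0.5, 0.001),
                   log2fc = c(2, 2, 2, 2, -2)))
  r1 <- round1_filter(de_day0, de_tol, de_cross)
  expect_identical(r1$up, "g01")
  expect_identical(r1$down, character(0))
  expect_identical(r1$ambiguous, "g05")

  # day-0-significant genes are excluded no matter what
  expect_false("g02" %in% c(r1$up, r1$down))

  bad <- fake_de(c(genes[-1], "gXX"))
  expect_error(round1_filter(bad, de_tol, de_cross), "universe")
})

test_that("stable-gene window is strict and applied in every cultivar", {
  design <- study_design(n_pairs = 1, days = c(0, 6), reps = 2)
  mk <- function(day0, day6_tol, day6_sen = day6_tol) {
    vapply(design$sample_id, function(s) {
      r <- design[design$sample_id == s, ]
      if (r$day == 0) day0
      else if (r$tolerance_class == "tolerant") day6_tol else day6_sen
    }, numeric(1))
  }
  vals <- rbind(flat = mk(99.5, 99.5),          # ratio exactly 1 -> stable
                edge = mk(99.5, 119.5),         # ratio exactly 1.2 -> out
                inside = mk(100, 109),          # within (0.9, 1.1) -> stable
                zero0 = mk(0, 50))              # zero day-0 mean -> out
  colnames(vals) <- design$sample_id
  m <- expr_matrix(vals, "gene", normalized = TRUE, norm_method = "cpm")
  stable <- select_stable_genes(m, design)
  expect_true(all(c("flat", "inside") %in% stable))
  expect_false("edge" %in% stable)   # strict upper bound
  expect_false("zero0" %in% stable)

  # a gene stable in the tolerant cultivar but shifted in the sensitive one
  # is not stable
  vals2 <- rbind(halfstable = mk(100, 100, 200))
  colnames(vals2) <- design$sample_id
  m2 <- expr_matrix(vals2, "gene", normalized = TRUE, norm_method = "cpm")
  expect_identical(select_stable_genes(m2, design), character(0))
})

test_that("round-2 ranks by max |log2fc| with q then id tie-breaks", {
  de_cross <- list(
    "6" = fake_de(c("g1", "g2", "g3"), q_value = c(0.01, 0.02, 0.01),
                  log2fc = c(4, 1, 4)),
    "10" = fake_de(c("g1", "g2", "g3"), q_value = c(0.02, 0.01, 0.005),
                   log2fc = c(1, 0.5, 2)))
  top1 <- round2_rank(c("g1", "g2"), de_cross, k = 1)
  expect_identical(top1$gene_id, "g1")

  all3 <- round2_rank(c("g1", "g2", "g3"), de_cross, k = 10)
  expect_identical(all3$gene_id, c("g3", "g1", "g2"))  # tie g1/g3 -> smaller q first
  expect_equal(all3$rank, 1:3)

  expect_error(round2_rank("g1", de_cross, k = 0), "positive")
  expect_equal(nrow(round2_rank(character(), de_cross, k = 3)), 0L)
})

test_that("round-3 requires sign agreement on every drought day", {
  prof <- function(gene, d6, d10)
    data.frame(gene_id = gene, day = c(6, 10), direction = c(d6, d10))
  rnaseq <- rbind(prof("g1", "up", "up"), prof("g2", "up", "up"),
                  prof("g3", "up", "up"))
  ortho <- rbind(prof("g1", "up", "up"), prof("g2", "up", "down"),
                 prof("g3", "none", "none"))
  r3 <- round3_confirm(c("g1", "g2", "g3"), rnaseq, ortho)
  expect_identical(r3$confirmed, "g1")

  expect_warning(
    r3b <- round3_confirm(c("g1", "g4"), rnaseq, ortho),
    "g4")
  expect_identical(r3b$dropped_missing, "g4")
  expect_identical(r3b$confirmed, "g1")
})

test_that("pipeline rounds nest, partition by direction, and union counts shared genes once", {
  cfg <- sim_config(n_genes = 300, n_responsive = 10, n_stable = 4,
                    n_shared = 1, seed = 77)
  sim <- simulate_experiment(cfg)
  ortho <- simulate_orthogonal(sim$truth, concordance_rate = 1, seed = 78)
  rep <- drought_select(sim$counts, sim$design, sim$map, ortho)

  per_pair_r3 <- list()
  for (pr in rep$pairs) {
    r1 <- c(pr$round1$up, pr$round1$down)
    expect_length(intersect(pr$round1$up, pr$round1$down), 0L)
    expect_equal(length(pr$round1$up) + length(pr$round1$down),
                 sum(pr$round1$audit$selected))
    expect_true(all(pr$round2$gene_id %in% r1))
    expect_true(all(pr$round3$gene_id %in% pr$round2$gene_id))
    # stable set and round-1 set disjoint (planted effects are 8-fold)
    expect_length(intersect(r1, rep$stable_genes), 0L)
    per_pair_r3[[pr$pair_id]] <- pr$round3$gene_id
  }
  expect_setequal(rep$overall, unique(unlist(per_pair_r3)))
  expect_equal(length(rep$overall),
               sum(lengths(per_pair_r3)) - length(rep$shared_genes))
})

test_that("pipeline is deterministic and invariant to sample order", {
  cfg <- sim_config(n_genes = 200, n_responsive = 6, n_stable = 2, seed = 5)
  sim <- simulate_experiment(cfg)
  rep1 <- drought_select(sim$counts, sim$design, sim$map)
  rep2 <- drought_select(sim$counts, sim$design, sim$map)
  expect_identical(rep1[names(rep1) != "design"],
                   rep2[names(rep2) != "design"])

  set.seed(1)
  perm <- sample(nrow(sim$design))
  design_p <- as_sample_design(as.data.frame(sim$design)[perm, ])
  counts_p <- expr_matrix(sim$counts$values[, design_p$sample_id],
                          level = "transcript")
  rep3 <- drought_select(counts_p, design_p, sim$map)
  for (p in names(rep1$pairs)) {
    expect_identical(rep1$pairs[[p]]$round1$up, rep3$pairs[[p]]$round1$up)
    expect_identical(rep1$pairs[[p]]$round1$down, rep3$pairs[[p]]$round1$down)
    expect_identical(rep1$pairs[[p]]$round3$gene_id,
                     rep3$pairs[[p]]$round3$gene_id)
  }
  expect_identical(rep1$stable_genes, rep3$stable_genes)
  expect_identical(rep1$overall, rep3$overall)
})

test_that("planted 8-fold responders are recovered with few false positives", {
  cfg <- sim_config(n_genes = 500, n_pairs = 1, n_responsive = 20,
                    n_shared = 0, n_stable = 0, seed = 1)
  sim <- simulate_experiment(cfg)
  rep <- drought_select(sim$counts, sim$design, sim$map)
  planted <- sim$truth$gene_id[grepl("responsive", sim$truth$class)]
  r1 <- c(rep$pairs[[1]]$round1$up, rep$pairs[[1]]$round1$down)
  expect_gte(sum(planted %in% r1), 18)
  expect_lte(sum(!r1 %in% planted), 2)
})
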