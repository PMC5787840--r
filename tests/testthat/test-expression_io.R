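test_that("count TSVs parse to the written values and round-trip exactly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "t1\t0\t1", "t2\t2\t3"), path)
  m <- read_counts(path)
  expect_identical(m$values,
                   matrix(c(0, 2, 1, 3), 2,
                          dimnames = list(c("t1", "t2"), c("s1", "s2"))))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_counts(m, out)
  expect_identical(read_counts(out)$values, m$values)
})

test_that("malformed count files are rejected with explicit errors", {
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "t1\t1\t2", "t1\t3\t4"), dup)
  expect_error(read_counts(dup), "duplicate feature ids")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("feature_id\ts1", empty)
  expect_error(read_counts(empty), "empty")

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "t1\t-1\t2"), neg)
  expect_error(read_counts(neg), "non-negative")

  txt <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "t1\tfoo\t2"), txt)
  expect_error(read_counts(txt), "non-numeric")
})

test_that("study-shaped designs validate; malformed designs are rejected", {
  d <- study_design()
  expect_s3_class(d, "sample_design")
  expect_equal(nrow(d), 36L)  # 4 cultivars x 3 days x 3 reps

  two_tol <- as.data.frame(d)
  two_tol$tolerance_class[two_tol$pair_id == "P1"] <- "tolerant"
  expect_error(as_sample_design(two_tol), "exactly one tolerant")

  bad_class <- as.data.frame(d)
  bad_class$tolerance_class[1] <- "hardy"
  expect_error(as_sample_design(bad_class), "unknown tolerance_class")

  neg_day <- as.data.frame(d)
  neg_day$day[1] <- -1L
  expect_error(as_sample_design(neg_day), "non-negative")

  single_rep <- as.data.frame(d)[!(d$cultivar == "TOL1" & d$day == 0 &
                                     d$replicate > 1), ]
  expect_error(as_sample_design(single_rep), ">= 2 replicates")
})

test_that("isoform aggregation sums transcripts and conserves totals", {
  m <- tiny_matrix(c(3, 4, 1, 2), features = c("t1a", "t1b"))
  map <- data.frame(transcript_id = c("t1a", "t1b"), gene_id = "g1")
  g <- aggregate_isoforms(m, map)
  expect_equal(g$values["g1", ], c(s1 = 4, s2 = 6))
  expect_identical(g$level, "gene")

  # single-isoform genes pass through unchanged; totals conserved on
  # random matrices
  set.seed(3)
  for (i in 1:5) {
    nt <- sample(5:15, 1)
    vals <- matrix(rpois(nt * 3, 20), nt,
                   dimnames = list(paste0("t", seq_len(nt)),
                                   paste0("s", 1:3)))
    mm <- expr_matrix(vals, "transcript")
    mp <- data.frame(transcript_id = rownames(vals),
                     gene_id = paste0("g", sample(1:4, nt, replace = TRUE)))
    gg <- aggregate_isoforms(mm, mp)
    expect_equal(colSums(gg$values), colSums(vals))
  }
  single <- tiny_matrix(c(5, 7), features = "tx")
  gs <- aggregate_isoforms(single,
                           data.frame(transcript_id = "tx", gene_id = "gX"))
  expect_equal(unname(gs$values["gX", ]), c(5, 7))

  expect_error(
    aggregate_isoforms(m, data.frame(transcript_id = "t1a", gene_id = "g1")),
    "t1b")
})

test_that("cpm normalization matches its definition and is scale-equivariant", {
  vals <- matrix(c(10, 999990, 20, 999980), 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  m <- expr_matrix(vals, "gene")
  n <- normalize_counts(m, "cpm")
  expect_equal(n$values["g1", "s1"], 10)
  expect_identical(n$norm_method, "cpm")
  expect_true(n$normalized)

  # identical samples get identical factors and values
  same <- expr_matrix(matrix(c(5, 10, 5, 10), 2,
                             dimnames = list(c("a", "b"), c("x", "y"))),
                      "gene")
  ns <- normalize_counts(same, "cpm")
  expect_equal(ns$values[, "x"], ns$values[, "y"])

  # multiplying one sample's counts by c leaves its cpm values unchanged
  set.seed(9)
  vals2 <- matrix(rpois(20, 50) + 1, 5,
                  dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  scaled <- vals2
  scaled[, 2] <- scaled[, 2] * 7
  a <- normalize_counts(expr_matrix(vals2, "gene"), "cpm")
  b <- normalize_counts(expr_matrix(scaled, "gene"), "cpm")
  expect_equal(a$values[, 2], b$values[, 2])

  zero <- expr_matrix(matrix(c(0, 0, 1, 2), 2,
                             dimnames = list(c("a", "b"), c("x", "y"))),
                      "gene")
  expect_error(normalize_counts(zero, "cpm"), "zero total")
})

test_that("median-of-ratios factors follow the closed form and match DESeq2", {
  # sample B exactly 2x sample A: factors in ratio 1:2, normalized equal
  vals <- matrix(c(10, 20, 30, 20, 40, 60), 3,
                 dimnames = list(paste0("g", 1:3), c("A", "B")))
  m <- expr_matrix(vals, "gene")
  n <- normalize_counts(m, "median_of_ratios")
  sf <- attr(n, "size_factors")
  expect_equal(unname(sf[["B"]] / sf[["A"]]), 2)
  expect_equal(n$values[, "A"], n$values[, "B"])

  set.seed(11)
  big <- matrix(rnbinom(600, mu = 100, size = 10) + 1, 100,
                dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  ours <- size_factors(big, "median_of_ratios")
  ref <- DESeq2::estimateSizeFactorsForMatrix(big)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})
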