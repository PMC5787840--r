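# shared builders and independent oracles

tiny_matrix <- function(values = 0:3, features = c("t1", "t2"),
                        samples = c("s1", "s2"), level = "transcript") {
  m <- matrix(values, nrow = length(features), byrow = TRUE,
              dimnames = list(features, samples))
  expr_matrix(m, level = level)
}

# full study-shaped design: pairs x (tolerant, sensitive) x days x reps
study_design <- function(n_pairs = 2, days = c(0, 6, 10), reps = 3) {
  rows <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
    g <- expand.grid(day = days, replicate = seq_len(reps),
                     tolerance_class = c("tolerant", "sensitive"),
                     stringsAsFactors = FALSE)
    g$cultivar <- ifelse(g$tolerance_class == "tolerant",
                         paste0("TOL", i), paste0("SEN", i))
    g$pair_id <- paste0("P", i)
    g$sample_id <- sprintf("%s_d%d_r%d", g$cultivar, g$day, g$replicate)
    g
  }))
  as_sample_design(rows)
}

# hand-built DE table for exercising the selection logic directly
fake_de <- function(gene_id, p_value = 1, q_value = NULL, log2fc = 0,
                    alpha = 0.05) {
  n <- length(gene_id)
  p_value <- rep_len(p_value, n)
  log2fc <- rep_len(log2fc, n)
  if (is.null(q_value)) q_value <- p_value
  q_value <- rep_len(q_value, n)
  direction <- ifelse(q_value < alpha & log2fc > 0, "up",
                      ifelse(q_value < alpha & log2fc < 0, "down", "none"))
  structure(data.frame(gene_id = gene_id, mean_a = 10, mean_b = 10,
                       log2fc = log2fc, p_value = p_value, q_value = q_value,
                       direction = direction, stringsAsFactors = FALSE),
            class = c("de_result", "data.frame"))
}

# brute-force Benjamini-Hochberg step-up, straight from the definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  # step-up: q_(i) = min_{j >= i} p_(j) * m / j
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# exact two-group permutation p-value for the log-mean difference
permutation_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  obs <- abs(log(mean(a) + 0.5) - log(mean(b) + 0.5))
  splits <- utils::combn(length(pooled), n)
  stats <- apply(splits, 2, function(ix)
    abs(log(mean(pooled[ix]) + 0.5) - log(mean(pooled[-ix]) + 0.5)))
  mean(stats >= obs - 1e-12)
}
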