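#' Configuration for the synthetic drought experiment
#'
#' Emulates the study design behind the pipeline: pairs of
#' drought-tolerant/drought-sensitive cultivars sampled at day 0 and on
#' drought days, three biological replicates, negative-binomial gene counts
#' emitted as 1-3 splicing isoforms per gene, with planted drought-responsive
#' genes (effect in the tolerant cultivar only, on drought days only),
#' planted stable reference genes (high, tightly dispersed expression) and
#' optional genes planted as responsive in every pair.
#'
#' @param n_genes Total genes.
#' @param n_pairs Cultivar pairs (default 2).
#' @param days Sampling days; the first is the well-watered control
#'   (default 0/6/10).
#' @param replicates Biological replicates per (cultivar, day) (default 3).
#' @param library_size Expected reads per sample (default 1e6, a desk-scale
#'   stand-in for tens of millions of reads; the selection logic is
#'   depth-invariant under cpm).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   gene means before scaling to `library_size`.
#' @param dispersion NB dispersion alpha (`Var = mu + alpha mu^2`) for
#'   regular genes; 0 gives Poisson counts.
#' @param n_responsive Planted drought-responsive genes per pair (includes
#'   the shared ones).
#' @param responsive_log2fc Planted |log2 fold change| on the first drought
#'   day; later drought days get the effect scaled by `late_day_factor`
#'   per step (default 0.6, echoing the weaker late-drought marker
#'   response).
#' @param late_day_factor Multiplier on the log2 effect per subsequent
#'   drought day.
#' @param prop_up Fraction of responsive genes planted up-regulated.
#' @param tolerant_only Apply the effect only in the tolerant cultivar
#'   (default `TRUE`; `FALSE` plants it in both cultivars of the pair).
#' @param n_stable Planted stable reference genes (default 8).
#' @param stable_mean,stable_dispersion Mean and dispersion of stable genes
#'   (housekeeping-like: high and tightly regulated).
#' @param n_shared Responsive genes planted in every pair (default 1).
#' @param max_isoforms Isoforms per gene drawn uniformly from
#'   `1:max_isoforms`.
#' @param depth_sdlog Log-normal sd of per-sample depth jitter (default
#'   0.05, mimicking modest library-depth spread).
#' @param seed RNG seed recorded in the output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_pairs = 2, days = c(0, 6, 10),
                       replicates = 3, library_size = 1e6,
                       baseline_meanlog = log(100), baseline_sdlog = 1,
                       dispersion = 0.05, n_responsive = 20,
                       responsive_log2fc = 3, late_day_factor = 0.6,
                       prop_up = 0.5, tolerant_only = TRUE, n_stable = 8,
                       stable_mean = 1000, stable_dispersion = 0.005,
                       n_shared = 1, max_isoforms = 3, depth_sdlog = 0.05,
                       seed = 1) {
  if (length(days) < 2L || days[1L] != min(days))
    stop("'days' must start with the control day")
  if (n_shared > n_responsive)
    stop("'n_shared' cannot exceed 'n_responsive'")
  total_responsive <- n_pairs * (n_responsive - n_shared) + n_shared
  if (total_responsive + n_stable > n_genes)
    stop("planted gene counts exceed 'n_genes'")
  if (replicates < 2L) stop("need >= 2 replicates")
  if (!is.finite(responsive_log2fc)) stop("effects must be finite")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a drought RNA-seq experiment with ground truth
#'
#' Counts are drawn per gene and sample from
#' `NB(mean = baseline x effect(cultivar, day) x depth factor, dispersion)`;
#' responsive genes get the multiplicative effect `2^(+-log2fc)` in the
#' tolerant cultivar on drought days only. Each gene's count is then split
#' multinomially over its 1-3 isoforms with fixed per-gene proportions, so
#' isoform aggregation recovers the gene-level NB counts exactly.
#' Deterministic given the config's seed.
#'
#' @param cfg A [sim_config()].
#' @return List: `counts` (transcript-level raw [expr_matrix()]), `map`
#'   (transcript-to-gene), `design` (`sample_design`), `truth` (per gene:
#'   `class` in responsive_up/responsive_down/stable/null, `pair_id`,
#'   `shared`, `log2fc`), and `seed`.
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ng <- cfg$n_genes
  gene_ids <- sprintf("G%05d", seq_len(ng))

  # ground-truth classes
  cls <- rep("null", ng)
  pair_ids <- paste0("P", seq_len(cfg$n_pairs))
  membership <- rep(NA_character_, ng)
  shared_flag <- rep(FALSE, ng)
  idx <- 1L
  take <- function(k) { out <- idx:(idx + k - 1L); idx <<- idx + k; out }
  shared_idx <- if (cfg$n_shared > 0) take(cfg$n_shared) else integer()
  per_pair_idx <- lapply(pair_ids, function(p)
    c(shared_idx, if (cfg$n_responsive - cfg$n_shared > 0)
      take(cfg$n_responsive - cfg$n_shared) else integer()))
  names(per_pair_idx) <- pair_ids
  responsive_idx <- sort(unique(unlist(per_pair_idx)))
  stable_idx <- if (cfg$n_stable > 0) take(cfg$n_stable) else integer()
  shared_flag[shared_idx] <- TRUE
  for (p in pair_ids)
    membership[per_pair_idx[[p]]] <- ifelse(
      is.na(membership[per_pair_idx[[p]]]), p,
      paste(membership[per_pair_idx[[p]]], p, sep = ","))
  up <- rep(FALSE, ng)
  up[responsive_idx] <- stats::runif(length(responsive_idx)) < cfg$prop_up
  cls[responsive_idx] <- ifelse(up[responsive_idx], "responsive_up",
                                "responsive_down")
  cls[stable_idx] <- "stable"

  # baseline means, scaled to the target library size
  base <- stats::rlnorm(ng, cfg$baseline_meanlog, cfg$baseline_sdlog)
  base[stable_idx] <- stats::rlnorm(length(stable_idx),
                                    log(cfg$stable_mean), 0.2)
  base <- base * cfg$library_size / sum(base)
  alpha <- rep(cfg$dispersion, ng)
  alpha[stable_idx] <- cfg$stable_dispersion

  # design
  design <- do.call(rbind, lapply(seq_len(cfg$n_pairs), function(i) {
    expand <- expand.grid(day = cfg$days, replicate = seq_len(cfg$replicates),
                          tolerance_class = c("tolerant", "sensitive"),
                          stringsAsFactors = FALSE)
    expand$cultivar <- ifelse(expand$tolerance_class == "tolerant",
                              paste0("TOL", i), paste0("SEN", i))
    expand$pair_id <- pair_ids[i]
    expand$sample_id <- sprintf("%s_d%d_r%d", expand$cultivar, expand$day,
                                expand$replicate)
    expand
  }))
  design <- as_sample_design(design)

  drought_days <- cfg$days[-1L]
  lfc_by_day <- cfg$responsive_log2fc *
    cfg$late_day_factor^(seq_along(drought_days) - 1L)
  names(lfc_by_day) <- as.character(drought_days)
  true_lfc <- ifelse(cls %in% c("responsive_up", "responsive_down"),
                     ifelse(up, cfg$responsive_log2fc, -cfg$responsive_log2fc),
                     0)

  depth <- stats::rlnorm(nrow(design), 0, cfg$depth_sdlog)
  gene_counts <- matrix(0L, ng, nrow(design),
                        dimnames = list(gene_ids, design$sample_id))
  for (j in seq_len(nrow(design))) {
    mu <- base * depth[j]
    d <- design$day[j]
    if (d != cfg$days[1L]) {
      affected <- per_pair_idx[[design$pair_id[j]]]
      if (cfg$tolerant_only)
        affected <- if (design$tolerance_class[j] == "tolerant") affected
                    else integer()
      if (length(affected)) {
        eff <- 2^(ifelse(up[affected], 1, -1) * lfc_by_day[[as.character(d)]])
        mu[affected] <- mu[affected] * eff
      }
    }
    k <- ifelse(alpha > 0,
                stats::rnbinom(ng, mu = mu, size = 1 / pmax(alpha, 1e-12)),
                stats::rpois(ng, mu))
    gene_counts[, j] <- k
  }

  # emit each gene as 1..max_isoforms isoforms: multinomial split with fixed
  # per-gene proportions, so summation recovers the gene counts exactly
  n_iso <- sample.int(cfg$max_isoforms, ng, replace = TRUE)
  tx_rows <- vector("list", ng)
  map_rows <- vector("list", ng)
  for (g in seq_len(ng)) {
    ni <- n_iso[g]
    tx_ids <- if (ni == 1L) gene_ids[g] else
      paste0(gene_ids[g], ".", seq_len(ni))
    map_rows[[g]] <- data.frame(transcript_id = tx_ids,
                                gene_id = gene_ids[g],
                                stringsAsFactors = FALSE)
    if (ni == 1L) {
      tx_rows[[g]] <- matrix(gene_counts[g, ], nrow = 1,
                             dimnames = list(tx_ids, design$sample_id))
    } else {
      props <- stats::rexp(ni); props <- props / sum(props)
      split_counts <- vapply(gene_counts[g, ], function(tot)
        as.numeric(stats::rmultinom(1L, tot, props)), numeric(ni))
      dimnames(split_counts) <- list(tx_ids, design$sample_id)
      tx_rows[[g]] <- split_counts
    }
  }
  tx_mat <- do.call(rbind, tx_rows)
  map <- do.call(rbind, map_rows)

  truth <- data.frame(gene_id = gene_ids, class = cls,
                      pair_id = membership, shared = shared_flag,
                      log2fc = true_lfc, stringsAsFactors = FALSE)
  list(counts = expr_matrix(tx_mat, level = "transcript"),
       map = map, design = design, truth = truth, seed = cfg$seed)
}

#' Simulate orthogonal-platform direction profiles
#'
#' Emulates RT-PCR-style confirmation: for every planted responsive gene and
#' every drought day, the true direction is reproduced with probability
#' `concordance_rate`; otherwise it is flipped or zeroed with equal
#' probability.
#'
#' @param truth Ground-truth data.frame from [simulate_experiment()].
#' @param concordance_rate Per-day probability of reproducing the true
#'   direction, in `[0, 1]`.
#' @param days Drought days profiled (default 6 and 10).
#' @param seed RNG seed.
#' @return Data frame `gene_id`, `day`, `direction`.
#' @export
simulate_orthogonal <- function(truth, concordance_rate = 1,
                                days = c(6, 10), seed = 1) {
  if (concordance_rate < 0 || concordance_rate > 1)
    stop("'concordance_rate' must lie in [0, 1]")
  set.seed(seed)
  resp <- truth[truth$class %in% c("responsive_up", "responsive_down"), ]
  if (nrow(resp) == 0L)
    return(data.frame(gene_id = character(), day = integer(),
                      direction = character(), stringsAsFactors = FALSE))
  grid <- expand.grid(gene_id = resp$gene_id, day = days,
                      stringsAsFactors = FALSE)
  true_dir <- ifelse(resp$class[match(grid$gene_id, resp$gene_id)] ==
                       "responsive_up", "up", "down")
  keep <- stats::runif(nrow(grid)) < concordance_rate
  flip <- stats::runif(nrow(grid)) < 0.5
  grid$direction <- ifelse(keep, true_dir,
                           ifelse(flip,
                                  ifelse(true_dir == "up", "down", "up"),
                                  "none"))
  grid
}

#' Simulate leaf-weight records with a target RWC structure
#'
#' Draws per-sample RWC values around each group's mean, then constructs
#' FW/SW/DW triples whose implied RWC equals the draw; the weight ordering
#' `DW <= FW <= SW` holds by construction (draws outside `[0, 100]` percent
#' are rejected and redrawn).
#'
#' @param group_means Named numeric vector of target mean RWC (percent) per
#'   group.
#' @param n_per_group Samples per group (default 3).
#' @param noise_sd Between-sample RWC sd in percentage points (> 0).
#' @param seed RNG seed.
#' @return Data frame `sample_id`, `group`, `fw`, `sw`, `dw`, `rwc_target`.
#' @export
simulate_rwc <- function(group_means, n_per_group = 3, noise_sd = 3,
                         seed = 1) {
  if (noise_sd <= 0) stop("'noise_sd' must be > 0")
  if (is.null(names(group_means)))
    names(group_means) <- paste0("group", seq_along(group_means))
  set.seed(seed)
  rows <- lapply(names(group_means), function(g) {
    rwc <- numeric(n_per_group)
    for (i in seq_len(n_per_group)) {
      repeat {
        v <- stats::rnorm(1, group_means[[g]], noise_sd)
        if (v > 0 && v < 100) { rwc[i] <- v; break }
      }
    }
    dw <- stats::runif(n_per_group, 0.15, 0.25)
    sw <- dw + stats::runif(n_per_group, 0.7, 0.9)
    fw <- dw + rwc / 100 * (sw - dw)
    data.frame(sample_id = sprintf("%s_%d", g, seq_len(n_per_group)),
               group = g, fw = fw, sw = sw, dw = dw, rwc_target = rwc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
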