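#' Configuration of the selection cascade
#'
#' Bundles every tunable threshold of the three-round selection:
#'
#' * `alpha` — significance level applied to BH-adjusted q-values in the
#'   drought contrasts (round 1 criteria ii and iii).
#' * `equiv_log2fc` — day-0 equivalence guard: a gene counts as "same level
#'   at day 0" when the cross-cultivar day-0 contrast is non-significant at
#'   the unadjusted `alpha` AND `|log2fc| < equiv_log2fc`. The fold-change
#'   guard prevents low-power pass-through of genes that plainly differ.
#' * `stable_low`, `stable_high` — strict fold-change window for stable
#'   reference genes, default `(0.8, 1.2)` exclusive at both ends.
#' * `round2_k`, `round2_frac` — round 2 keeps the top `k` genes by the
#'   largest absolute tolerant-vs-sensitive log2 fold change over the drought
#'   days; if `round2_k` is `NULL`, `k = ceiling(round2_frac * n_round1)`
#'   (default fraction 0.25).
#' * `profile_min_log2fc` — minimum |log2fc| vs day 0 for a per-day direction
#'   call (`up`/`down`) in an expression profile; smaller changes are `none`.
#' * `pseudocount` — pseudocount used in every fold change.
#' * `norm_method`, `normalize_order` — library-size normalization method and
#'   whether it is applied before or after isoform aggregation (both orders
#'   are supported and recorded in the report).
#'
#' @param alpha Significance level in (0, 1).
#' @param equiv_log2fc Day-0 equivalence |log2fc| bound.
#' @param stable_low,stable_high Stability window, `stable_low < 1 < stable_high`.
#' @param round2_k Integer or `NULL`.
#' @param round2_frac Fraction in (0, 1] used when `round2_k` is `NULL`.
#' @param profile_min_log2fc Direction-call threshold.
#' @param pseudocount Fold-change pseudocount.
#' @param norm_method `"cpm"` or `"median_of_ratios"`.
#' @param normalize_order `"normalize_then_aggregate"` or
#'   `"aggregate_then_normalize"`.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(alpha = 0.05, equiv_log2fc = 1,
                             stable_low = 0.8, stable_high = 1.2,
                             round2_k = NULL, round2_frac = 0.25,
                             profile_min_log2fc = 0.25, pseudocount = 0.5,
                             norm_method = c("cpm", "median_of_ratios"),
                             normalize_order = c("normalize_then_aggregate",
                                                 "aggregate_then_normalize")) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  if (!(stable_low < 1 && 1 < stable_high))
    stop("stability window must satisfy low < 1 < high")
  if (!is.null(round2_k) && round2_k <= 0) stop("'round2_k' must be positive")
  if (round2_frac <= 0 || round2_frac > 1)
    stop("'round2_frac' must lie in (0, 1]")
  structure(list(alpha = alpha, equiv_log2fc = equiv_log2fc,
                 stable_low = stable_low, stable_high = stable_high,
                 round2_k = round2_k, round2_frac = round2_frac,
                 profile_min_log2fc = profile_min_log2fc,
                 pseudocount = pseudocount,
                 norm_method = match.arg(norm_method),
                 normalize_order = match.arg(normalize_order)),
            class = "selection_config")
}

check_universe <- function(tables) {
  ids <- lapply(tables, function(t) sort(t$gene_id))
  if (!all(vapply(ids[-1], identical, logical(1), ids[[1]])))
    stop("DE tables cover mismatched gene universes")
  invisible(TRUE)
}

de_col <- function(de, col, universe) {
  de[[col]][match(universe, de$gene_id)]
}

#' Round-1 triple filter
#'
#' A gene passes round 1 of the cascade iff:
#' (i) the tolerant-vs-sensitive contrast at day 0 is *equivalent*
#' (unadjusted `p >= alpha` and `|log2fc| < equiv_log2fc`);
#' (ii) the temporal contrast in the tolerant cultivar (day 0 vs any drought
#' day) is significant (`q < alpha`);
#' (iii) the tolerant-vs-sensitive contrast on any drought day is significant
#' (`q < alpha`).
#' Its direction label (`up`/`down`) is the sign of the tolerant-vs-sensitive
#' log2 fold change on the significant drought day(s); genes whose
#' significant days disagree in sign are flagged ambiguous and excluded.
#'
#' @param de_day0 `de_result` for tolerant vs sensitive at day 0.
#' @param de_tolerant Named list of `de_result`s, one per drought day, for
#'   the tolerant cultivar's drought-day-vs-day-0 contrast.
#' @param de_cross Named list of `de_result`s, one per drought day, for the
#'   tolerant-vs-sensitive contrast on that day (log2fc tolerant over
#'   sensitive).
#' @param config A [selection_config()].
#' @return List: `up`, `down` (character vectors of gene ids), `ambiguous`,
#'   and `audit`, a per-gene data.frame of each criterion's outcome.
#' @export
round1_filter <- function(de_day0, de_tolerant, de_cross, config = selection_config()) {
  check_universe(c(list(de_day0), de_tolerant, de_cross))
  universe <- sort(de_day0$gene_id)
  a <- config$alpha

  equiv <- de_col(de_day0, "p_value", universe) >= a &
    abs(de_col(de_day0, "log2fc", universe)) < config$equiv_log2fc
  temporal <- Reduce(`|`, lapply(de_tolerant, function(de)
    de_col(de, "q_value", universe) < a))
  cross_sig <- lapply(de_cross, function(de) de_col(de, "q_value", universe) < a)
  cross_any <- Reduce(`|`, cross_sig)

  sign_mat <- mapply(function(sig, de) {
    s <- sign(de_col(de, "log2fc", universe))
    ifelse(sig, s, NA_real_)
  }, cross_sig, de_cross)
  sign_mat <- matrix(sign_mat, nrow = length(universe))
  pos <- rowSums(sign_mat > 0, na.rm = TRUE)
  neg <- rowSums(sign_mat < 0, na.rm = TRUE)

  pass <- equiv & temporal & cross_any
  ambiguous <- pass & ((pos > 0 & neg > 0) | (pos == 0 & neg == 0))
  up <- universe[pass & !ambiguous & pos > 0]
  down <- universe[pass & !ambiguous & neg > 0]

  audit <- data.frame(gene_id = universe, day0_equivalent = equiv,
                      temporal_significant = temporal,
                      cross_significant = cross_any,
                      n_days_up = pos, n_days_down = neg,
                      selected = pass & !ambiguous,
                      ambiguous = ambiguous,
                      direction = ifelse(universe %in% up, "up",
                                         ifelse(universe %in% down, "down", "none")),
                      stringsAsFactors = FALSE)
  list(up = up, down = down, ambiguous = universe[ambiguous], audit = audit)
}

#' Stable reference-gene selection
#'
#' A gene is a stable-expression candidate iff, in *every* cultivar and for
#' *every* drought day d, the pseudocounted fold change
#' `mean(day d) / mean(day 0)` lies strictly inside the window
#' `(stable_low, stable_high)`. Genes whose day-0 mean is zero in any
#' cultivar are excluded outright.
#'
#' @param x Gene-level normalized [expr_matrix()].
#' @param design A `sample_design` covering the matrix's samples.
#' @param config A [selection_config()].
#' @return Character vector of stable gene ids.
#' @export
select_stable_genes <- function(x, design, config = selection_config()) {
  stopifnot(inherits(x, "expr_matrix"))
  values <- x$values
  days <- sort(unique(design$day))
  day0 <- days[1L]
  drought <- days[-1L]
  keep <- rep(TRUE, nrow(values))
  for (cv in unique(design$cultivar)) {
    s0 <- design$sample_id[design$cultivar == cv & design$day == day0]
    m0 <- rowMeans(values[, s0, drop = FALSE])
    keep <- keep & m0 > 0
    for (d in drought) {
      sd_ <- design$sample_id[design$cultivar == cv & design$day == d]
      md <- rowMeans(values[, sd_, drop = FALSE])
      fc <- fold_change(md, m0, config$pseudocount)$fc
      keep <- keep & fc > config$stable_low & fc < config$stable_high
    }
  }
  rownames(values)[keep]
}

#' Round-2 effect-size ranking
#'
#' Scores each round-1 gene by the largest absolute tolerant-vs-sensitive
#' log2 fold change over the drought days and keeps the top k. Ties are
#' broken by the smaller q-value (minimum over drought days), then by gene
#' id.
#'
#' @param round1_genes Character vector (round-1 up and down sets combined).
#' @param de_cross Named list of cross-cultivar `de_result`s per drought day.
#' @param config A [selection_config()].
#' @param k Number of genes to keep; default from `config`
#'   (`round2_k`, else `ceiling(round2_frac * length(round1_genes))`).
#' @return Data frame `gene_id`, `score`, `q_min`, `rank`, in rank order.
#' @export
round2_rank <- function(round1_genes, de_cross, config = selection_config(),
                        k = NULL) {
  if (length(round1_genes) == 0L)
    return(data.frame(gene_id = character(), score = numeric(),
                      q_min = numeric(), rank = integer(),
                      stringsAsFactors = FALSE))
  if (is.null(k))
    k <- if (!is.null(config$round2_k)) config$round2_k
         else ceiling(config$round2_frac * length(round1_genes))
  if (k <= 0) stop("'k' must be positive")
  score_mat <- sapply(de_cross, function(de)
    abs(de_col(de, "log2fc", round1_genes)))
  q_mat <- sapply(de_cross, function(de)
    de_col(de, "q_value", round1_genes))
  score_mat <- matrix(score_mat, nrow = length(round1_genes))
  q_mat <- matrix(q_mat, nrow = length(round1_genes))
  score <- apply(score_mat, 1L, max)
  q_min <- apply(q_mat, 1L, min)
  ord <- order(-score, q_min, round1_genes)
  out <- data.frame(gene_id = round1_genes[ord], score = score[ord],
                    q_min = q_min[ord], stringsAsFactors = FALSE)
  out <- utils::head(out, k)
  out$rank <- seq_len(nrow(out))
  out
}

#' Per-day expression-direction profiles
#'
#' For one cultivar, calls each gene `up`/`down`/`none` on each drought day
#' from the pseudocounted log2 fold change of the day's mean over the day-0
#' mean; |log2fc| below `profile_min_log2fc` is `none`.
#'
#' @param x Gene-level normalized [expr_matrix()].
#' @param design A `sample_design`.
#' @param cultivar Cultivar whose profile is wanted.
#' @param config A [selection_config()].
#' @return Data frame `gene_id`, `day`, `direction`.
#' @export
direction_profiles <- function(x, design, cultivar,
                               config = selection_config()) {
  values <- x$values
  sub <- design[design$cultivar == cultivar, ]
  if (nrow(sub) == 0L) stop("cultivar not in design: ", cultivar)
  days <- sort(unique(sub$day))
  day0 <- days[1L]
  m0 <- rowMeans(values[, sub$sample_id[sub$day == day0], drop = FALSE])
  out <- lapply(days[-1L], function(d) {
    md <- rowMeans(values[, sub$sample_id[sub$day == d], drop = FALSE])
    l2 <- fold_change(md, m0, config$pseudocount)$log2fc
    dir <- ifelse(l2 > config$profile_min_log2fc, "up",
                  ifelse(l2 < -config$profile_min_log2fc, "down", "none"))
    data.frame(gene_id = rownames(values), day = d, direction = dir,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

profile_vector <- function(profiles, gene) {
  sub <- profiles[profiles$gene_id == gene, ]
  stats::setNames(sub$direction, as.character(sub$day))[order(sub$day)]
}

#' Round-3 orthogonal-platform confirmation
#'
#' A round-2 gene is confirmed iff its RNA-seq direction profile and its
#' orthogonal-platform (RT-PCR-like) profile agree — same non-`none`
#' direction on *both* (all) drought days. Candidates without an orthogonal
#' profile are dropped with a warning and recorded in the audit trail.
#'
#' @param round2_genes Character vector of candidate gene ids.
#' @param rnaseq_profiles,orthogonal_profiles Data frames from
#'   [direction_profiles()] / [simulate_orthogonal()] (`gene_id`, `day`,
#'   `direction`).
#' @return List: `confirmed` gene ids, `dropped_missing`, and `audit`.
#' @export
round3_confirm <- function(round2_genes, rnaseq_profiles,
                           orthogonal_profiles) {
  if (length(round2_genes) == 0L)
    return(list(confirmed = character(), dropped_missing = character(),
                audit = data.frame(gene_id = character(),
                                   status = character(),
                                   stringsAsFactors = FALSE)))
  status <- vapply(round2_genes, function(g) {
    a <- profile_vector(rnaseq_profiles, g)
    b <- profile_vector(orthogonal_profiles, g)
    if (length(b) == 0L) return("missing_orthogonal")
    if (platform_concordant(a, b)) "confirmed" else "discordant"
  }, character(1))
  dropped <- round2_genes[status == "missing_orthogonal"]
  if (length(dropped))
    warning("no orthogonal profile for: ", paste(dropped, collapse = ", "),
            "; dropped from round 3")
  list(confirmed = round2_genes[status == "confirmed"],
       dropped_missing = dropped,
       audit = data.frame(gene_id = round2_genes, status = unname(status),
                          stringsAsFactors = FALSE))
}

#' Run the full drought-gene selection pipeline
#'
#' Executes, per cultivar pair: isoform aggregation and library-size
#' normalization; the five per-pair differential-expression contrasts
#' (day-0 cross-cultivar; tolerant day 0 vs each drought day; cross-cultivar
#' on each drought day); the round-1 triple filter; round-2 effect-size
#' ranking; round-3 orthogonal confirmation (skipped, with round 3 = round 2,
#' if no orthogonal profiles are supplied). Stable reference genes are
#' selected across all cultivars, and the overall candidate set is the union
#' of the per-pair round-3 sets, counting genes shared between pairs once.
#'
#' @param counts Transcript- or gene-level raw-count [expr_matrix()], or a
#'   path to a counts TSV.
#' @param design A `sample_design` (or path).
#' @param map Transcript-to-gene map (or path); required for
#'   transcript-level counts.
#' @param orthogonal Optional orthogonal-platform direction profiles
#'   (`gene_id`, `day`, `direction`), e.g. from [simulate_orthogonal()].
#' @param config A [selection_config()].
#' @return An object of class `selection_report`.
#' @export
drought_select <- function(counts, design, map = NULL, orthogonal = NULL,
                           config = selection_config()) {
  if (is.character(counts)) counts <- read_counts(counts)
  if (is.character(design) || !inherits(design, "sample_design"))
    design <- read_design(design)
  if (is.character(map)) map <- read_gene_map(map)
  stopifnot(inherits(counts, "expr_matrix"))
  missing_s <- setdiff(design$sample_id, sample_ids(counts))
  if (length(missing_s))
    stop("design samples absent from counts: ",
         paste(missing_s, collapse = ", "))
  counts$values <- counts$values[, design$sample_id, drop = FALSE]

  # gene-level raw counts + size factors; order of normalization vs
  # aggregation is configurable and recorded (identical for per-sample
  # scalar methods such as cpm)
  if (counts$level == "transcript") {
    if (is.null(map))
      stop("transcript-level counts need a transcript-to-gene map")
    gene_raw <- aggregate_isoforms(counts, map)
  } else {
    gene_raw <- counts
  }
  sf <- if (config$normalize_order == "normalize_then_aggregate")
    size_factors(counts$values, config$norm_method)
  else size_factors(gene_raw$values, config$norm_method)
  gene_norm <- expr_matrix(sweep(gene_raw$values, 2L, sf, "/"),
                           level = "gene", normalized = TRUE,
                           norm_method = config$norm_method)

  days <- sort(unique(design$day))
  day0 <- days[1L]
  drought_days <- days[-1L]
  sel <- function(cv, d) design$sample_id[design$cultivar == cv & design$day == d]

  pairs <- sort(unique(design$pair_id))
  pair_results <- lapply(pairs, function(p) {
    sub <- design[design$pair_id == p, ]
    tol <- unique(sub$cultivar[sub$tolerance_class == "tolerant"])
    sen <- unique(sub$cultivar[sub$tolerance_class == "sensitive"])
    de <- function(a, b) test_two_groups(gene_raw, a, b, size_factors = sf,
                                         alpha = config$alpha,
                                         pseudocount = config$pseudocount)
    de_day0 <- de(sel(tol, day0), sel(sen, day0))
    de_tol <- stats::setNames(lapply(drought_days, function(d)
      de(sel(tol, d), sel(tol, day0))), drought_days)
    de_cross <- stats::setNames(lapply(drought_days, function(d)
      de(sel(tol, d), sel(sen, d))), drought_days)

    r1 <- round1_filter(de_day0, de_tol, de_cross, config)
    r1_genes <- sort(c(r1$up, r1$down))
    r2 <- round2_rank(r1_genes, de_cross, config)
    if (!is.null(orthogonal)) {
      prof <- direction_profiles(gene_norm, sub, tol, config)
      r3 <- round3_confirm(r2$gene_id, prof, orthogonal)
      round3 <- r3$confirmed
      r3_audit <- r3$audit
    } else {
      round3 <- r2$gene_id
      r3_audit <- data.frame(gene_id = r2$gene_id,
                             status = rep("skipped_no_orthogonal",
                                          length(r2$gene_id)),
                             stringsAsFactors = FALSE)
    }
    dir_of <- function(g) r1$audit$direction[match(g, r1$audit$gene_id)]
    list(pair_id = p, tolerant = tol, sensitive = sen,
         de_day0 = de_day0, de_tolerant = de_tol, de_cross = de_cross,
         round1 = r1, round2 = r2,
         round3 = data.frame(gene_id = round3, direction = dir_of(round3),
                             stringsAsFactors = FALSE),
         round3_audit = r3_audit)
  })
  names(pair_results) <- pairs

  stable <- select_stable_genes(gene_norm, design, config)
  all_r3 <- lapply(pair_results, function(pr) pr$round3$gene_id)
  overall <- sort(unique(unlist(all_r3)))
  shared <- if (length(all_r3) >= 2L)
    sort(unique(unlist(all_r3)[duplicated(unlist(all_r3))])) else character()

  structure(list(pairs = pair_results, stable_genes = stable,
                 overall = overall, shared_genes = shared,
                 days = days, config = config,
                 normalize_order = config$normalize_order,
                 gene_norm = gene_norm, design = design),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Drought-responsive gene selection\n")
  cat(sprintf("  days: %s; normalization: %s (%s)\n",
              paste(x$days, collapse = "/"), x$config$norm_method,
              x$normalize_order))
  for (pr in x$pairs) {
    n1u <- length(pr$round1$up); n1d <- length(pr$round1$down)
    cat(sprintf("  pair %s (%s vs %s): round1 %d (%d up / %d down) -> round2 %d -> round3 %d\n",
                pr$pair_id, pr$tolerant, pr$sensitive, n1u + n1d, n1u, n1d,
                nrow(pr$round2), nrow(pr$round3)))
  }
  per_pair <- vapply(x$pairs, function(pr) nrow(pr$round3), integer(1))
  cat(sprintf("  overall: %s - %d shared = %d genes; %d stable reference gene(s)\n",
              paste(per_pair, collapse = " + "), length(x$shared_genes),
              length(x$overall), length(x$stable_genes)))
  invisible(x)
}

#' @export
summary.selection_report <- function(object, ...) {
  print(object)
  for (pr in object$pairs) {
    cat(sprintf("\npair %s round-3 genes:\n", pr$pair_id))
    if (nrow(pr$round3)) print.data.frame(pr$round3, row.names = FALSE)
    else cat("  (none)\n")
  }
  if (length(object$stable_genes)) {
    cat("\nstable reference genes:\n ",
        paste(object$stable_genes, collapse = ", "), "\n")
  }
  invisible(object)
}

#' Serialize a selection report
#'
#' Writes `report.json` (rounds, config, audit) plus per-round TSV gene
#' lists under `dir`.
#'
#' @param report A `selection_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_selection_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (pr in report$pairs) {
    base <- file.path(dir, paste0("pair_", pr$pair_id))
    p1 <- paste0(base, "_round1.tsv")
    write_tsv_strict(pr$round1$audit[pr$round1$audit$selected, ], p1)
    p2 <- paste0(base, "_round2.tsv")
    write_tsv_strict(pr$round2, p2)
    p3 <- paste0(base, "_round3.tsv")
    write_tsv_strict(pr$round3, p3)
    paths <- c(paths, p1, p2, p3)
  }
  pstable <- file.path(dir, "stable_genes.tsv")
  write_tsv_strict(data.frame(gene_id = report$stable_genes), pstable)
  pjson <- file.path(dir, "report.json")
  payload <- list(
    days = report$days,
    config = unclass(report$config),
    pairs = lapply(report$pairs, function(pr) list(
      pair_id = pr$pair_id, tolerant = pr$tolerant, sensitive = pr$sensitive,
      round1_up = pr$round1$up, round1_down = pr$round1$down,
      round1_ambiguous = pr$round1$ambiguous,
      round2 = pr$round2$gene_id, round3 = pr$round3$gene_id,
      round3_audit = pr$round3_audit)),
    stable_genes = report$stable_genes,
    shared_genes = report$shared_genes,
    overall = report$overall)
  jsonlite::write_json(payload, pjson, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, pstable, pjson))
}
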