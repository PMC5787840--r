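#' Cross-platform direction concordance
#'
#' Two per-gene expression-direction profiles (e.g. RNA-seq vs RT-PCR) are
#' concordant iff on *every* drought day both call a direction (not `none`)
#' and the calls agree.
#'
#' @param a,b Named character vectors of `up`/`down`/`none`, names being the
#'   drought days; both must cover the same day set.
#' @return Logical scalar.
#' @export
platform_concordant <- function(a, b) {
  if (!setequal(names(a), names(b)))
    stop("day sets differ between profiles: ",
         paste(names(a), collapse = ","), " vs ",
         paste(names(b), collapse = ","))
  b <- b[names(a)]
  all(a != "none" & b != "none" & a == b)
}

# closed symbol alphabet for cross-species direction calls, relative to the
# potato gene's drought response
.symbol_levels <- c("same_up", "same_down", "no_change", "no_data",
                    "no_homologue", "opposite")

#' Parse cross-species direction symbols
#'
#' Accepts the publication symbol alphabet (UTF-8) and ASCII aliases:
#' up-arrow / `"up"` -> `same_up`; down-arrow / `"down"` -> `same_down`;
#' en dash or `"-"` -> `no_change`; `"nd"` -> `no_data`;
#' `"No homologue"` -> `no_homologue`; not-equal sign / `"opp"` -> `opposite`.
#'
#' @param x Character vector of symbols.
#' @return Character vector over the closed enum; unknown symbols are an
#'   error naming the offending entry.
#' @export
parse_direction_symbol <- function(x) {
  x <- trimws(as.character(x))
  lookup <- c("↗" = "same_up", "up" = "same_up", "same_up" = "same_up",
              "↘" = "same_down", "down" = "same_down",
              "same_down" = "same_down",
              "–" = "no_change", "-" = "no_change",
              "no_change" = "no_change",
              "nd" = "no_data", "no_data" = "no_data",
              "no homologue" = "no_homologue",
              "no_homologue" = "no_homologue",
              "≠" = "opposite", "opp" = "opposite",
              "opposite" = "opposite")
  key <- ifelse(tolower(x) %in% names(lookup), tolower(x), x)
  out <- lookup[key]
  if (any(is.na(out))) {
    bad <- which(is.na(out))
    stop("unknown direction symbol '", x[bad[1L]], "' in row ", bad[1L])
  }
  unname(out)
}

#' Classify one cross-species direction call
#'
#' Given the direction of change of the Arabidopsis and rice homologues
#' relative to the potato gene's drought response, assigns one of the
#' mutually exclusive primary categories:
#' `conserved_all_three` (both homologues change in the potato direction),
#' `conserved_rice_only`, `conserved_arabidopsis_only`, or
#' `no_data_or_none`. Separately reports whether either symbol is
#' `opposite` — a gene opposite in one species and conserved in the other
#' belongs to both its conserved_*_only category and the `opposite_any`
#' tally.
#'
#' @param arabidopsis,rice Symbols from the closed enum (see
#'   [parse_direction_symbol()]).
#' @return List: `category` (character) and `opposite_any` (logical).
#' @export
classify_species_concordance <- function(arabidopsis, rice) {
  arabidopsis <- parse_direction_symbol(arabidopsis)
  rice <- parse_direction_symbol(rice)
  conserved <- function(s) s %in% c("same_up", "same_down")
  category <- if (conserved(arabidopsis) && conserved(rice))
    "conserved_all_three"
  else if (conserved(rice)) "conserved_rice_only"
  else if (conserved(arabidopsis)) "conserved_arabidopsis_only"
  else "no_data_or_none"
  list(category = category,
       opposite_any = arabidopsis == "opposite" | rice == "opposite")
}

#' Read cross-species direction calls from TSV
#'
#' Columns `potato_gene`, `arabidopsis_symbol`, `rice_symbol`; symbols in
#' the publication alphabet or ASCII aliases.
#'
#' @param path TSV path.
#' @return Data frame with parsed enum symbols.
#' @export
read_direction_calls <- function(path) {
  df <- read_tsv_strict(path)
  req <- c("potato_gene", "arabidopsis_symbol", "rice_symbol")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("direction-call table missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (any(!nzchar(df$potato_gene)))
    stop("empty potato gene id in direction-call table")
  df$arabidopsis_symbol <- parse_direction_symbol(df$arabidopsis_symbol)
  df$rice_symbol <- parse_direction_symbol(df$rice_symbol)
  df[, req]
}

#' Tabulate cross-species concordance categories
#'
#' Applies [classify_species_concordance()] to every call and tallies the
#' mutually exclusive primary categories (which sum to the number of calls)
#' plus the overlapping `opposite_any` count.
#'
#' @param calls Data frame with columns `potato_gene`,
#'   `arabidopsis_symbol`, `rice_symbol` (or a path to such a TSV).
#' @return Object of class `concordance_table`: `counts` (named integer
#'   vector) and `assignments` (per-gene data.frame).
#' @export
tabulate_concordance <- function(calls) {
  if (is.character(calls)) calls <- read_direction_calls(calls)
  if (nrow(calls) == 0L) stop("empty direction-call table")
  cls <- mapply(function(a, r) classify_species_concordance(a, r),
                calls$arabidopsis_symbol, calls$rice_symbol,
                SIMPLIFY = FALSE)
  category <- vapply(cls, `[[`, character(1), "category")
  opp <- vapply(cls, `[[`, logical(1), "opposite_any")
  cats <- c("conserved_all_three", "conserved_rice_only",
            "conserved_arabidopsis_only", "no_data_or_none")
  counts <- c(vapply(cats, function(k) sum(category == k), integer(1)),
              opposite_any = sum(opp))
  structure(list(counts = counts,
                 assignments = data.frame(
                   potato_gene = calls$potato_gene,
                   arabidopsis_symbol = calls$arabidopsis_symbol,
                   rice_symbol = calls$rice_symbol,
                   category = category, opposite_any = opp,
                   stringsAsFactors = FALSE)),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Cross-species direction concordance (", nrow(x$assignments),
      " genes)\n", sep = "")
  for (k in names(x$counts))
    cat(sprintf("  %-28s %d\n", k, x$counts[[k]]))
  invisible(x)
}

#' Write a concordance table
#'
#' Per-gene assignments as TSV and category counts as JSON.
#'
#' @param x A `concordance_table`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_concordance <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "concordance_assignments.tsv")
  write_tsv_strict(x$assignments, p1)
  p2 <- file.path(dir, "concordance_counts.json")
  jsonlite::write_json(as.list(x$counts), p2, auto_unbox = TRUE)
  invisible(c(p1, p2))
}
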