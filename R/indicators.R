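#' Internal-validation performance indicators
#'
#' Summarizes a collection of ranked substitute lists with the ten
#' indicators used for internal validation: the share of returned
#' candidates in each DS band (exactly 100; 90-99; 80-89; below 80,
#' evaluated on the one-decimal display-rounded DS, with 90-99 read as
#' \[90, 100)); the share of candidates with the same basic dose form as
#' their reference; and, per reference item, whether all its candidates
#' differ by at most k Standard Terms, for k = 1..5 (cumulative
#' percentages). References that return no candidate are counted in
#' `n_no_alternative` and excluded from the percentage denominators.
#' Equivalents (DS = 100) are included among the counted candidates and
#' also reported separately, so indicator readings restricted to
#' alternatives can be recovered.
#'
#' @param lists A list of `ranked_list` objects from [find_substitutes()].
#' @return An object of class `indicator_panel`: a list with
#'   `ds100_pct`, `ds90_99_pct`, `ds80_89_pct`, `ds_lt80_pct`,
#'   `same_bdf_pct`, `max1st_pct` .. `max5st_pct`, `n_references`,
#'   `n_no_alternative`, `n_candidates`, `n_equivalents`.
#' @examples
#' path <- system.file("extdata", "risperidone_catalog.csv",
#'                     package = "pharmsub")
#' cat <- read_catalog(path, quiet = TRUE)
#' compute_indicators(list(find_substitutes(cat, "037599230")))
#' @export
compute_indicators <- function(lists) {
  if (!is.list(lists) || !length(lists)) {
    stop("need a non-empty list of ranked lists", call. = FALSE)
  }
  if (inherits(lists, "ranked_list")) lists <- list(lists)
  ok <- vapply(lists, inherits, logical(1), "ranked_list")
  if (!all(ok)) stop("all elements must be ranked_list objects", call. = FALSE)

  has_cand <- vapply(lists, function(l) nrow(l$results) > 0, logical(1))
  n_no_alt <- sum(!has_cand)
  active <- lists[has_cand]
  if (!length(active)) {
    stop("no reference item returned any candidate", call. = FALSE)
  }

  ds <- unlist(lapply(active, function(l) l$results$ds_display))
  same_bdf <- unlist(lapply(active, function(l) {
    l$results$bdf == l$reference$bdf
  }))
  max_diff <- vapply(active, function(l) max(l$results$n_st_diff),
                     numeric(1))
  n_cand <- length(ds)

  panel <- list(
    ds100_pct   = mean(ds == 100) * 100,
    ds90_99_pct = mean(ds >= 90 & ds < 100) * 100,
    ds80_89_pct = mean(ds >= 80 & ds < 90) * 100,
    ds_lt80_pct = mean(ds < 80) * 100,
    same_bdf_pct = mean(same_bdf) * 100,
    n_references = length(lists),
    n_no_alternative = n_no_alt,
    n_candidates = n_cand,
    n_equivalents = sum(unlist(lapply(active, function(l) {
      l$results$classification == "equivalent"
    })))
  )
  for (k in 1:5) {
    panel[[sprintf("max%dst_pct", k)]] <- mean(max_diff <= k) * 100
  }
  structure(panel, class = "indicator_panel")
}

#' @export
print.indicator_panel <- function(x, ...) {
  cat("Indicator panel over", x$n_references, "reference items (",
      x$n_candidates, "candidates;", x$n_no_alternative,
      "with no alternative)\n")
  cat(sprintf("  DS bands: =100 %.1f%% | 90-99 %.1f%% | 80-89 %.1f%% | <80 %.1f%%\n",
              x$ds100_pct, x$ds90_99_pct, x$ds80_89_pct, x$ds_lt80_pct))
  cat(sprintf("  Same BDF as reference: %.1f%%\n", x$same_bdf_pct))
  cat(sprintf("  References with all candidates within k STs: %s\n",
              paste(sprintf("k=%d: %.1f%%", 1:5,
                            unlist(x[sprintf("max%dst_pct", 1:5)])),
                    collapse = ", ")))
  invisible(x)
}

#' Stratified indicator panels by first ATC level
#'
#' Groups the ranked lists by the first character of the reference ATC
#' (the anatomical main group) and computes one indicator panel per group.
#' Strata whose references all return no candidate are dropped with a
#' warning.
#'
#' @inheritParams compute_indicators
#' @return A named list of `indicator_panel` objects, keyed by ATC first
#'   letter.
#' @export
compute_indicators_by_atc1 <- function(lists) {
  if (!is.list(lists) || !length(lists)) {
    stop("need a non-empty list of ranked lists", call. = FALSE)
  }
  atc1 <- vapply(lists, function(l) substr(l$reference$atc, 1, 1),
                 character(1))
  out <- list()
  for (g in sort(unique(atc1))) {
    panel <- tryCatch(compute_indicators(lists[atc1 == g]),
                      error = function(e) NULL)
    if (is.null(panel)) {
      warning("stratum ", g, " omitted: no reference returned a candidate",
              call. = FALSE)
    } else {
      out[[g]] <- panel
    }
  }
  out
}

#' Export indicator panels
#'
#' Writes one row/object per stratum with all indicator fields.
#'
#' @param panels A single `indicator_panel` or a named list of them
#'   (stratum key; a single panel is keyed `"all"`).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_indicators <- function(panels, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(panels, "indicator_panel")) panels <- list(all = panels)
  rows <- do.call(rbind, lapply(names(panels), function(k) {
    cbind(data.frame(stratum = k, stringsAsFactors = FALSE),
          as.data.frame(unclass(panels[[k]])))
  }))
  if (format == "csv") {
    utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(rows, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
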