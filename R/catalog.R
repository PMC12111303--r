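.catalog_columns <- c("ma_number", "name", "atc", "bdf", "ame", "isi",
                      "rca", "trn", "ndxup")

#' Read a product catalog from CSV
#'
#' The catalog is the searchable market snapshot: one row per
#' marketing-authorization (MA) number, carrying the product's combined
#' code (ATC, five Standard-Term IDs, NDXUP) plus descriptive metadata.
#' Expected columns: `ma_number`, `name`, `atc`, `bdf`, `ame`, `isi`,
#' `rca`, `trn`, `ndxup` and optionally `pack_metadata`. A malformed header
#' is a hard error; malformed rows are skipped with per-row, per-field
#' diagnostics collected on the returned object, and a summary of
#' accepted/rejected counts is reported.
#'
#' @param path Path to a UTF-8, comma-separated catalog file.
#' @param vocab An [st_vocabulary()] used to validate the Standard-Term
#'   IDs of every row.
#' @param quiet Suppress the accepted/rejected summary message.
#' @return An object of class `catalog`: a data frame of validated entries
#'   with a `rejects` attribute (data frame with columns `row`,
#'   `ma_number`, `message`).
#' @export
read_catalog <- function(path, vocab = st_vocabulary(), quiet = FALSE) {
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(.catalog_columns, names(raw))
  if (length(missing)) {
    stop("catalog header is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"pack_metadata" %in% names(raw)) raw$pack_metadata <- ""
  out <- as_catalog(raw, vocab = vocab, quiet = quiet)
  # restore generator provenance written as a comment header, if any
  first <- readLines(path, n = 1L)
  if (grepl("^#.*seed=[0-9]+", first)) {
    attr(out, "seed") <- as.integer(sub(".*seed=([0-9]+).*", "\\1", first))
  }
  out
}

#' Build a validated catalog from a data frame
#'
#' @param df Data frame with the catalog columns (character or numeric
#'   `ndxup`).
#' @inheritParams read_catalog
#' @return A `catalog` object; invalid rows are dropped and recorded in the
#'   `rejects` attribute.
#' @export
as_catalog <- function(df, vocab = st_vocabulary(), quiet = FALSE) {
  stopifnot(is.data.frame(df))
  missing <- setdiff(.catalog_columns, names(df))
  if (length(missing)) {
    stop("catalog is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"pack_metadata" %in% names(df)) df$pack_metadata <- ""
  df <- df[c(.catalog_columns, "pack_metadata")]
  df$ndxup <- suppressWarnings(as.numeric(df$ndxup))

  rejects <- data.frame(row = integer(0), ma_number = character(0),
                        message = character(0), stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    msg <- tryCatch({
      if (!nzchar(row$ma_number)) stop("ma_number: empty", call. = FALSE)
      if (is.na(row$ndxup)) stop("ndxup: not a number", call. = FALSE)
      validate_mp_code(
        mp_code(row$atc, row$bdf, row$ame, row$isi, row$rca, row$trn,
                row$ndxup),
        vocab
      )
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(msg)) {
      keep[i] <- FALSE
      rejects <- rbind(rejects, data.frame(
        row = i, ma_number = row$ma_number, message = msg,
        stringsAsFactors = FALSE))
    }
  }
  out <- df[keep, , drop = FALSE]
  dup <- duplicated(out$ma_number)
  if (any(dup)) {
    stop("duplicate ma_number in catalog: ",
         paste(unique(out$ma_number[dup]), collapse = ", "), call. = FALSE)
  }
  rownames(out) <- NULL
  if (!quiet) {
    message("catalog: ", nrow(out), " entries accepted, ",
            nrow(rejects), " rows rejected")
    if (nrow(rejects)) {
      for (i in seq_len(nrow(rejects))) {
        message("  row ", rejects$row[i], " (", rejects$ma_number[i], "): ",
                gsub("\n", " ", rejects$message[i]))
      }
    }
  }
  structure(out, rejects = rejects, class = c("catalog", "data.frame"))
}

#' Write a catalog to CSV
#'
#' @param catalog A `catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "catalog"))
  out <- as.data.frame(catalog)
  out$ndxup <- vapply(out$ndxup, format, character(1), digits = 15)
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(catalog, "seed")
  if (!is.null(seed)) {
    # provenance for synthetic catalogs; skipped on read (comment.char)
    writeLines(paste0("# pharmsub synthetic catalog, seed=", seed), con)
  }
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.catalog <- function(x, ...) {
  cat("Product catalog:", nrow(x), "entries,",
      length(unique(x$atc)), "distinct ATC codes\n")
  rej <- attr(x, "rejects")
  if (!is.null(rej) && nrow(rej)) cat("  (", nrow(rej), "rows rejected at load)\n")
  NextMethod()
}

.entry_code <- function(entry) {
  mp_code(entry$atc, entry$bdf, entry$ame, entry$isi, entry$rca, entry$trn,
          entry$ndxup)
}

#' Classify a candidate as pharmaceutical equivalent or alternative
#'
#' A candidate is a pharmaceutical equivalent when its full digital string
#' matches the reference — all five Standard-Term IDs and NDXUP equal —
#' which is exactly the DS = 100 case; anything else (same ATC, some
#' difference in the string) is a pharmaceutical alternative.
#'
#' @param reference,candidate [mp_code()]s sharing the same ATC.
#' @param breakdown Optional precomputed [ds_score()] result for the pair.
#' @return `"equivalent"` or `"alternative"`.
#' @export
classify_substitute <- function(reference, candidate, breakdown = NULL) {
  same_st <- all(vapply(tolower(ST_CATEGORIES), function(f) {
    identical(reference[[f]], candidate[[f]])
  }, logical(1)))
  same_ndxup <- isTRUE(all.equal(reference$ndxup, candidate$ndxup,
                                 tolerance = 1e-9))
  if (same_st && same_ndxup) "equivalent" else "alternative"
}

#' Find ranked substitutes for a lacking product
#'
#' The central query: given the MA number of a lacking product, every other
#' catalog entry with the identical full 5-level ATC code is scored with
#' [ds_score()] and returned in a deterministic total order — DS
#' descending, then number of differing Standard Terms ascending, then
#' absolute NDXUP difference ascending, then MA number — so repeated runs
#' on shuffled input give identical output. Candidates with DS = 100 are
#' pharmaceutical equivalents; the rest are alternatives. A DS above 90
#' conventionally marks a strong substitution candidate; by default nothing
#' is filtered out (`min_ds = 0`).
#'
#' @param catalog A [read_catalog()] result.
#' @param ma_number MA number of the lacking product (must be in the
#'   catalog).
#' @param exclude_ma Character vector of MA numbers to exclude from the
#'   candidate pool (e.g. products themselves in shortage).
#' @param min_ds Keep only candidates whose unrounded DS is at least this
#'   value; applied after ranks are assigned over the full candidate set.
#' @param weights,schedule,vocab Scoring configuration; defaults are the
#'   standard weights, penalty schedule and bundled vocabulary.
#' @return An object of class `ranked_list`: a list with `reference` (the
#'   catalog row) and `results`, a data frame with one row per candidate
#'   (rank, identification, code fields, `n_st_diff`, penalties, `ds`,
#'   `ds_display`, `classification`).
#' @examples
#' path <- system.file("extdata", "risperidone_catalog.csv",
#'                     package = "pharmsub")
#' cat <- read_catalog(path, quiet = TRUE)
#' rl <- find_substitutes(cat, "037599230")
#' head(rl$results[, c("rank", "name", "ds_display", "classification")])
#' @export
find_substitutes <- function(catalog, ma_number,
                             exclude_ma = character(0), min_ds = 0,
                             weights = weight_factors(),
                             schedule = penalty_schedule(),
                             vocab = st_vocabulary()) {
  stopifnot(inherits(catalog, "catalog"))
  idx <- which(catalog$ma_number == ma_number)
  if (!length(idx)) {
    near <- utils::head(
      catalog$ma_number[order(utils::adist(catalog$ma_number, ma_number))], 3)
    stop("MA number '", ma_number, "' not in catalog; nearest keys: ",
         paste(near, collapse = ", "), call. = FALSE)
  }
  ref <- as.data.frame(catalog)[idx, ]
  ref_code <- .entry_code(ref)
  cand <- as.data.frame(catalog)[
    catalog$atc == ref$atc &
      catalog$ma_number != ma_number &
      !(catalog$ma_number %in% exclude_ma), , drop = FALSE]

  n <- nrow(cand)
  if (n == 0L) {
    results <- data.frame(rank = integer(0), ma_number = character(0),
                          name = character(0), atc = character(0),
                          bdf = character(0), ame = character(0),
                          isi = character(0), rca = character(0),
                          trn = character(0), ndxup = numeric(0),
                          n_st_diff = integer(0), ndxup_penalty = numeric(0),
                          st_penalty = numeric(0), ds = numeric(0),
                          ds_display = numeric(0),
                          classification = character(0),
                          stringsAsFactors = FALSE)
    return(structure(list(reference = ref, results = results),
                     class = "ranked_list"))
  }

  st_fields <- tolower(ST_CATEGORIES)
  scored <- lapply(seq_len(n), function(i) {
    row <- cand[i, ]
    code <- .entry_code(row)
    br <- ds_score(ref_code, code, weights, schedule, vocab)
    data.frame(
      ma_number = row$ma_number, name = row$name, atc = row$atc,
      bdf = row$bdf, ame = row$ame, isi = row$isi, rca = row$rca,
      trn = row$trn, ndxup = row$ndxup,
      n_st_diff = sum(vapply(st_fields, function(f) {
        !identical(ref[[f]], row[[f]])
      }, logical(1))),
      ndxup_penalty = br$ndxup_penalty, st_penalty = br$st_penalty,
      ds = br$ds, ds_display = br$ds_display,
      classification = classify_substitute(ref_code, code),
      stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, scored)
  ord <- order(-results$ds, results$n_st_diff,
               abs(results$ndxup - ref$ndxup), results$ma_number)
  results <- results[ord, , drop = FALSE]
  results <- cbind(rank = seq_len(nrow(results)), results)
  results <- results[results$ds >= min_ds, , drop = FALSE]
  rownames(results) <- NULL
  structure(list(reference = ref, results = results), class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, max_rows = 15, ...) {
  cat("Substitutes for ", x$reference$ma_number, " (", x$reference$name,
      ", ATC ", x$reference$atc, "):\n", sep = "")
  n_eq <- sum(x$results$classification == "equivalent")
  cat("  ", nrow(x$results), " candidates (", n_eq, " equivalents, ",
      nrow(x$results) - n_eq, " alternatives)\n", sep = "")
  show <- utils::head(x$results[, c("rank", "ma_number", "name", "ndxup",
                                    "n_st_diff", "ds_display",
                                    "classification")], max_rows)
  print(show, row.names = FALSE)
  if (nrow(x$results) > max_rows) {
    cat("  ... and", nrow(x$results) - max_rows, "more rows\n")
  }
  invisible(x)
}

#' Export a ranked substitute list
#'
#' @param ranked A `ranked_list`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(ranked, path, format = c("csv", "json")) {
  stopifnot(inherits(ranked, "ranked_list"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(ranked$results, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(
      list(reference = ranked$reference, results = ranked$results),
      path, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a shortage list
#'
#' A CSV with column `ma_number` and optionally `note`, one row per product
#' reported in shortage.
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `ma_number` and `note`.
#' @export
read_shortage_list <- function(path) {
  if (!file.exists(path)) {
    stop("shortage list not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE, comment.char = "#")
  if (!"ma_number" %in% names(df)) {
    stop("shortage list must have a 'ma_number' column", call. = FALSE)
  }
  if (!"note" %in% names(df)) df$note <- ""
  df[c("ma_number", "note")]
}
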