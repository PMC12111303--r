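#' EDQM Standard-Term categories
#'
#' The five controlled vocabularies used to describe a dosage form:
#' basic dose form (BDF), administration method (AME), intended site (ISI),
#' release characteristic (RCA) and transformation (TRN).
#'
#' @format A character vector of length five.
#' @export
ST_CATEGORIES <- c("BDF", "AME", "ISI", "RCA", "TRN")

#' Load a Standard-Terms vocabulary
#'
#' Reads a vocabulary file mapping each 4-digit Standard-Term identifier to
#' its label and its relative position (RP) on the category's similarity
#' scale. The bundled default transcribes EDQM Standard Terms version 1.2.0
#' (28 January 2019) for the five categories used by the substitution score;
#' a user-supplied file in the same format can be loaded instead so future
#' EDQM revisions can be swapped in.
#'
#' RP values may be fractional (e.g. 3.5, 7.2); they are kept exactly as
#' written and only divided by the scale span when a normalized relative
#' distance is computed, so no rounding is introduced at load time.
#'
#' @param path Path to a CSV file with columns `category`, `st_id`, `label`,
#'   `rp`. `NULL` (the default) loads the bundled vocabulary.
#' @return An object of class `st_vocabulary`: a data frame with the four
#'   columns above, carrying the per-category scale spans
#'   (`max(rp) - min(rp)`) as the `"spans"` attribute.
#' @examples
#' vocab <- st_vocabulary()
#' st_lookup(vocab, "BDF", "0069")
#' @export
st_vocabulary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "standard_terms_1.2.0.csv",
                        package = "pharmsub", mustWork = TRUE)
  }
  if (!file.exists(path)) {
    stop("vocabulary file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = c(
    category = "character", st_id = "character",
    label = "character", rp = "numeric"
  ), stringsAsFactors = FALSE)
  required <- c("category", "st_id", "label", "rp")
  if (!identical(names(df)[seq_along(required)], required)) {
    stop("vocabulary file must have columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  as_st_vocabulary(df[required])
}

#' Build a vocabulary object from a data frame
#'
#' @param df Data frame with columns `category`, `st_id`, `label`, `rp`.
#' @return An `st_vocabulary` object.
#' @export
as_st_vocabulary <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("category", "st_id", "label", "rp") %in% names(df)))
  bad_cat <- setdiff(unique(df$category), ST_CATEGORIES)
  if (length(bad_cat)) {
    stop("unknown Standard-Term categories: ",
         paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  if (!all(grepl("^[0-9]{4}$", df$st_id))) {
    stop("st_id must be a 4-digit zero-padded string", call. = FALSE)
  }
  dup <- duplicated(df[c("category", "st_id")])
  if (any(dup)) {
    stop("duplicated st_id within category: ",
         paste(unique(paste(df$category[dup], df$st_id[dup])), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(df$rp) | df$rp < 0)) {
    stop("rp must be a non-negative finite number", call. = FALSE)
  }
  spans <- vapply(split(df$rp, df$category),
                  function(rp) max(rp) - min(rp), numeric(1))
  if (any(spans[unique(df$category)] <= 0)) {
    stop("each category needs a positive RP span", call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, spans = spans, class = c("st_vocabulary", "data.frame"))
}

#' Write a vocabulary back to CSV
#'
#' The written file round-trips: reading it back with [st_vocabulary()]
#' reproduces the object bit-exactly (RPs are formatted at full precision).
#'
#' @param vocab An `st_vocabulary`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_st_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "st_vocabulary"))
  out <- as.data.frame(vocab)
  # rp stays numeric: write.csv prints it unquoted at full short-decimal
  # precision, so the value survives a read back unchanged
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Scale span of a Standard-Term category
#'
#' The span is the full range of the category's relative-position scale,
#' `max(rp) - min(rp)`; it is the denominator of the normalized relative
#' distance.
#'
#' @param vocab An `st_vocabulary`.
#' @param category One of `"BDF"`, `"AME"`, `"ISI"`, `"RCA"`, `"TRN"`.
#' @return A positive number.
#' @export
st_scale_span <- function(vocab, category) {
  stopifnot(inherits(vocab, "st_vocabulary"))
  category <- match.arg(category, ST_CATEGORIES)
  span <- attr(vocab, "spans")[[category]]
  if (is.null(span)) {
    stop("category ", category, " absent from vocabulary", call. = FALSE)
  }
  span
}

#' Look up a Standard Term by category and ID
#'
#' @inheritParams st_scale_span
#' @param st_id 4-digit term identifier.
#' @return A one-row data frame (`category`, `st_id`, `label`, `rp`).
#' @export
st_lookup <- function(vocab, category, st_id) {
  stopifnot(inherits(vocab, "st_vocabulary"))
  category <- match.arg(category, ST_CATEGORIES)
  hit <- which(vocab$category == category & vocab$st_id == st_id)
  if (length(hit) != 1L) {
    stop("unknown Standard-Term ID '", st_id, "' in category ", category,
         call. = FALSE)
  }
  as.data.frame(vocab)[hit, , drop = FALSE]
}

#' Normalized relative distance between two Standard Terms
#'
#' The absolute difference of the two terms' relative positions, divided by
#' the category's scale span and scaled to 0-100. Two identical terms are at
#' distance 0; the two extremes of a category's scale are at distance 100.
#'
#' @inheritParams st_scale_span
#' @param st_id_a,st_id_b 4-digit term identifiers within `category`.
#' @return A number in \[0, 100\], symmetric in its two term arguments.
#' @examples
#' vocab <- st_vocabulary()
#' st_nrd(vocab, "BDF", "0069", "0086") # Tablet vs Syrup: 41.30...
#' @export
st_nrd <- function(vocab, category, st_id_a, st_id_b) {
  rp_a <- st_lookup(vocab, category, st_id_a)$rp
  rp_b <- st_lookup(vocab, category, st_id_b)$rp
  abs(rp_a - rp_b) / st_scale_span(vocab, category) * 100
}

#' @export
print.st_vocabulary <- function(x, ...) {
  spans <- attr(x, "spans")
  cat("Standard-Terms vocabulary:", nrow(x), "terms in",
      length(unique(x$category)), "categories\n")
  cat("Scale spans:",
      paste(sprintf("%s=%g", names(spans), spans), collapse = ", "), "\n")
  NextMethod()
}
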