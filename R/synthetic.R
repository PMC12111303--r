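#' Configuration for the synthetic catalog generator
#'
#' The generator emulates the structure of a national market snapshot that
#' the scoring engine consumes: families of products under a shared ATC
#' code, laddered strengths as multiples of a base strength, a mix of
#' dosage-form families drawn from the Standard-Terms vocabulary, exact
#' duplicate codes under distinct MA numbers (pharmaceutical equivalents),
#' and a shortage list sampled from the catalog. It makes no attempt to
#' mirror the real ATC consumption distribution of any market.
#'
#' @param n_atc_codes Number of distinct ATC codes (active ingredients).
#' @param products_per_code Integer range `c(min, max)`: products drawn per
#'   ATC code.
#' @param dosage_ladder Multipliers of the base strength used for laddered
#'   dosages (default 0.5x, 1x, 2x, 3x, the ladder typical of oral solid
#'   ranges).
#' @param form_families Named probabilities for the dosage-form family of
#'   each product; names must be among `"tablet"`, `"oral_solution"`,
#'   `"oral_drops"`, `"parenteral"` and probabilities must sum to 1.
#' @param n_equivalents Number of exact code duplicates (distinct MA
#'   numbers) per ATC code, capped at the family size minus one.
#' @param shortage_fraction Fraction of catalog entries sampled into a
#'   shortage list by [generate_shortage_list()].
#' @param seed Integer seed making every generated artifact reproducible.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_atc_codes = 20,
                         products_per_code = c(3, 8),
                         dosage_ladder = c(0.5, 1, 2, 3),
                         form_families = c(tablet = 0.55,
                                           oral_solution = 0.20,
                                           oral_drops = 0.10,
                                           parenteral = 0.15),
                         n_equivalents = 1,
                         shortage_fraction = 0.1,
                         seed = 1L) {
  stopifnot(length(products_per_code) == 2)
  if (n_atc_codes < 1 || any(products_per_code < 1) ||
      products_per_code[1] > products_per_code[2]) {
    stop("counts must be positive and the range ordered", call. = FALSE)
  }
  if (!length(dosage_ladder) || any(dosage_ladder <= 0)) {
    stop("dosage_ladder must contain positive multipliers", call. = FALSE)
  }
  known <- c("tablet", "oral_solution", "oral_drops", "parenteral")
  if (is.null(names(form_families)) ||
      !all(names(form_families) %in% known)) {
    stop("form_families names must be among: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(form_families) - 1) > 1e-9 || any(form_families < 0)) {
    stop("form_families probabilities must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (shortage_fraction <= 0 || shortage_fraction >= 1) {
    stop("shortage_fraction must lie strictly between 0 and 1",
         call. = FALSE)
  }
  if (n_equivalents < 0) stop("n_equivalents must be >= 0", call. = FALSE)
  structure(list(n_atc_codes = as.integer(n_atc_codes),
                 products_per_code = as.integer(products_per_code),
                 dosage_ladder = dosage_ladder,
                 form_families = form_families,
                 n_equivalents = as.integer(n_equivalents),
                 shortage_fraction = shortage_fraction,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Standard-Term tuples of the generator's dosage-form families.
.form_family_codes <- list(
  tablet        = c(bdf = "0069", ame = "0019", isi = "0031",
                    rca = "0047", trn = "0042"),
  oral_solution = c(bdf = "0083", ame = "0019", isi = "0031",
                    rca = "0047", trn = "0042"),
  oral_drops    = c(bdf = "0090", ame = "0019", isi = "0031",
                    rca = "0047", trn = "0042"),
  parenteral    = c(bdf = "0083", ame = "0011", isi = "0033",
                    rca = "0047", trn = "0042")
)

.with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic product catalog
#'
#' Deterministic for a fixed seed: the same configuration always yields the
#' same catalog. Every generated entry passes [validate_mp_code()];
#' pharmaceutical equivalents are exact code duplicates under distinct MA
#' numbers; generated NDXUP values are short decimals (at most 3 places) so
#' the exact-equality rules of the penalty schedule apply as they do to
#' real DDD ratios.
#'
#' @param config A [synth_config()].
#' @param vocab An [st_vocabulary()] used to validate the output.
#' @return A `catalog` object carrying the generating seed as the `"seed"`
#'   attribute.
#' @export
generate_catalog <- function(config = synth_config(),
                             vocab = st_vocabulary()) {
  stopifnot(inherits(config, "synth_config"))
  .with_local_seed(config$seed, {
    atcs <- character(0)
    while (length(atcs) < config$n_atc_codes) {
      atcs <- unique(c(atcs, paste0(
        sample(LETTERS, 1), sprintf("%02d", sample(0:99, 1)),
        paste(sample(LETTERS, 2, replace = TRUE), collapse = ""),
        sprintf("%02d", sample(1:79, 1)))))
    }
    rows <- list()
    ma_pool <- sprintf("%09d", sample.int(999999999,
                                          config$n_atc_codes *
                                            config$products_per_code[2] + 10))
    ma_i <- 0L
    next_ma <- function() {
      ma_i <<- ma_i + 1L
      ma_pool[ma_i]
    }
    resample <- function(x, ...) x[sample.int(length(x), 1, ...)]
    for (atc in atcs) {
      k <- resample(seq(config$products_per_code[1],
                        config$products_per_code[2]))
      base_ndxup <- resample(c(0.1, 0.2, 0.25, 0.4, 0.5, 1))
      base_family <- resample(names(config$form_families),
                              prob = config$form_families)
      n_dup <- min(config$n_equivalents, k - 1L)
      for (j in seq_len(k)) {
        if (j <= n_dup + 1L) {
          # the equivalence family: identical full digital string
          family <- base_family
          mult <- 1
        } else {
          family <- resample(names(config$form_families),
                             prob = config$form_families)
          mult <- resample(config$dosage_ladder)
        }
        st <- .form_family_codes[[family]]
        rows[[length(rows) + 1L]] <- data.frame(
          ma_number = next_ma(),
          name = sprintf("SYNTH %s %s %gX", atc, toupper(family), mult),
          atc = atc,
          bdf = st[["bdf"]], ame = st[["ame"]], isi = st[["isi"]],
          rca = st[["rca"]], trn = st[["trn"]],
          ndxup = round(base_ndxup * mult, 3),
          pack_metadata = "synthetic",
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    out <- as_catalog(df, vocab = vocab, quiet = TRUE)
    attr(out, "seed") <- config$seed
    out
  })
}

#' Sample a shortage list from a catalog
#'
#' @param catalog A `catalog`.
#' @param fraction Fraction of entries to sample, strictly between 0 and 1;
#'   the list size is `round(fraction * nrow(catalog))`.
#' @param seed Integer seed; the same seed always yields the same sample.
#' @return A data frame with columns `ma_number` and `note`.
#' @export
generate_shortage_list <- function(catalog, fraction = 0.1, seed = 1L) {
  stopifnot(inherits(catalog, "catalog"))
  if (nrow(catalog) == 0L) stop("catalog is empty", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- round(fraction * nrow(catalog))
  .with_local_seed(seed, {
    picks <- sort(sample(catalog$ma_number, n))
    data.frame(ma_number = picks, note = "synthetic shortage",
               stringsAsFactors = FALSE)
  })
}

#' Write a shortage list to CSV
#'
#' @param shortage Data frame with columns `ma_number` and `note`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shortage_list <- function(shortage, path) {
  utils::write.csv(shortage[c("ma_number", "note")], path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}
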