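#' @keywords internal
#' Unit table: value gives the factor to the dimension's base unit
#' (mg for mass, mL for volume; unit doses are dimensionless counts).
.unit_table <- list(
  mass   = c(mcg = 1e-3, ug = 1e-3, "µg" = 1e-3,
             mg = 1, g = 1e3, kg = 1e6),
  volume = c(ml = 1, mL = 1, l = 1e3, L = 1e3),
  unit   = c(tab = 1, tablet = 1, cap = 1, capsule = 1,
             unit = 1, dose = 1, puff = 1)
)

.unit_dimension <- function(unit) {
  for (dim in names(.unit_table)) {
    if (unit %in% names(.unit_table[[dim]])) return(dim)
  }
  stop("unknown unit '", unit, "'; known units: ",
       paste(unlist(lapply(.unit_table, names)), collapse = ", "),
       call. = FALSE)
}

.to_base <- function(value, unit) {
  dim <- .unit_dimension(unit)
  value * .unit_table[[dim]][[unit]]
}

#' Number of DDDs per presentation unit for a single-ingredient product
#'
#' NDXUP is the strength of one presentation unit (one tablet or capsule, or
#' one mL / one g for liquids and bulk solids) expressed in Defined Daily
#' Doses: `dosage / DDD` after converting both to a common unit. The dosage
#' and the DDD must share a dimension; mass units (mcg/mg/g/kg) convert
#' automatically, but a unit-dose DDD ("1 tab") is a distinct dimension and
#' mixing it with a mass dosage is an error rather than a silent division of
#' raw numbers.
#'
#' @param dosage Positive amount of active ingredient per presentation unit.
#' @param ddd Positive Defined Daily Dose.
#' @param dosage_unit,ddd_unit Units of the two amounts (default `"mg"`).
#' @return A positive number of DDDs per presentation unit.
#' @examples
#' ndxup_single(3, 5)                 # 3 mg tablet, DDD 5 mg -> 0.6
#' ndxup_single(1, 5)                 # 1 mg per mL, DDD 5 mg -> 0.2
#' @export
ndxup_single <- function(dosage, ddd, dosage_unit = "mg", ddd_unit = "mg") {
  if (!is.numeric(dosage) || length(dosage) != 1L || !is.finite(dosage) ||
      dosage <= 0) {
    stop("dosage must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(ddd) || length(ddd) != 1L || !is.finite(ddd) || ddd <= 0) {
    stop("ddd must be a single positive number", call. = FALSE)
  }
  dim_dos <- .unit_dimension(dosage_unit)
  dim_ddd <- .unit_dimension(ddd_unit)
  if (dim_dos != dim_ddd) {
    stop("incompatible units: dosage in ", dosage_unit, " (", dim_dos,
         ") but DDD in ", ddd_unit, " (", dim_ddd, ")", call. = FALSE)
  }
  .to_base(dosage, dosage_unit) / .to_base(ddd, ddd_unit)
}

#' NDXUP of a fixed combination
#'
#' A fixed combination (FC) has no official DDD; its NDXUP is taken as the
#' sum over components of `dosage / DDD`, each ratio computed with the same
#' unit handling as [ndxup_single()]. The result is invariant under
#' reordering of the component list, and a one-component list reduces to the
#' single-ingredient case.
#'
#' @param components A data frame with columns `api_name`, `dosage`,
#'   `dosage_unit`, `ddd`, `ddd_unit`, one row per active ingredient.
#' @return A positive number: the summed DDDs per presentation unit.
#' @examples
#' fc <- data.frame(
#'   api_name = c("scopolamine butylbromide", "paracetamol"),
#'   dosage = c(10, 800), dosage_unit = "mg",
#'   ddd = c(60, 3), ddd_unit = c("mg", "g")
#' )
#' ndxup_fixed_combination(fc) # 10/60 + 800/3000 = 0.4333...
#' @export
ndxup_fixed_combination <- function(components) {
  stopifnot(is.data.frame(components))
  required <- c("api_name", "dosage", "dosage_unit", "ddd", "ddd_unit")
  missing <- setdiff(required, names(components))
  if (length(missing)) {
    stop("components is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(components) < 1L) {
    stop("at least one component is required", call. = FALSE)
  }
  ratios <- vapply(seq_len(nrow(components)), function(i) {
    row <- components[i, ]
    tryCatch(
      ndxup_single(row$dosage, row$ddd, row$dosage_unit, row$ddd_unit),
      error = function(e) {
        stop("component '", row$api_name, "': ", conditionMessage(e),
             call. = FALSE)
      }
    )
  }, numeric(1))
  sum(ratios)
}

#' Validate an ATC code string
#'
#' Standard WHO ATC codes are 7 characters, pattern
#' letter-digit-digit-letter-letter-digit-digit. Fictitious codes assigned
#' to ambiguous fixed combinations keep the standard first four levels
#' (5 characters) but may carry a letter+digit or digit+letter fifth level.
#'
#' @param atc Candidate code string.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_atc <- function(atc) {
  if (!is.character(atc) || length(atc) != 1L || is.na(atc)) return(FALSE)
  if (nchar(atc) != 7L) return(FALSE)
  if (!grepl("^[A-Z][0-9]{2}[A-Z]{2}", atc)) return(FALSE)
  fifth <- substr(atc, 6, 7)
  grepl("^[0-9]{2}$|^[A-Z][0-9]$|^[0-9][A-Z]$", fifth)
}

#' Construct a combined medicinal-product code
#'
#' The combined code identifies a product by its active ingredient (ATC),
#' its dosage form (five EDQM Standard-Term IDs) and its strength in Defined
#' Daily Doses per presentation unit (NDXUP). It is the unit of comparison
#' for the substitutability score.
#'
#' @param atc 7-character ATC code (standard or fictitious fifth level).
#' @param bdf,ame,isi,rca,trn 4-digit Standard-Term IDs for basic dose form,
#'   administration method, intended site, release characteristic and
#'   transformation.
#' @param ndxup Positive number of DDDs per presentation unit.
#' @return An object of class `mp_code`.
#' @examples
#' mp_code("N05AX08", "0069", "0019", "0031", "0047", "0042", 0.6)
#' @export
mp_code <- function(atc, bdf, ame, isi, rca, trn, ndxup) {
  structure(
    list(atc = as.character(atc), bdf = as.character(bdf),
         ame = as.character(ame), isi = as.character(isi),
         rca = as.character(rca), trn = as.character(trn),
         ndxup = as.numeric(ndxup)),
    class = "mp_code"
  )
}

#' Validate a combined medicinal-product code
#'
#' Checks the ATC is well formed, each of the five Standard-Term IDs
#' resolves in its vocabulary, and NDXUP is strictly positive. All failures
#' are collected and reported together, naming the offending field.
#'
#' @param code An [mp_code()].
#' @param vocab An [st_vocabulary()].
#' @return `code`, unchanged, if valid; otherwise an error.
#' @export
validate_mp_code <- function(code, vocab) {
  stopifnot(inherits(code, "mp_code"), inherits(vocab, "st_vocabulary"))
  problems <- character(0)
  if (!is_valid_atc(code$atc)) {
    problems <- c(problems, paste0("atc: '", code$atc,
                                   "' is not a valid 7-character ATC code"))
  }
  for (cat in ST_CATEGORIES) {
    field <- tolower(cat)
    id <- code[[field]]
    ok <- tryCatch({ st_lookup(vocab, cat, id); TRUE },
                   error = function(e) FALSE)
    if (!ok) {
      problems <- c(problems, paste0(field, ": ID '", id,
                                     "' not in ", cat, " vocabulary"))
    }
  }
  if (!is.numeric(code$ndxup) || length(code$ndxup) != 1L ||
      !is.finite(code$ndxup) || code$ndxup <= 0) {
    problems <- c(problems, "ndxup: must be a single positive number")
  }
  if (length(problems)) {
    stop("invalid MP code:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  code
}

#' @export
print.mp_code <- function(x, ...) {
  cat(sprintf("<mp_code> %s | BDF %s AME %s ISI %s RCA %s TRN %s | NDXUP %g\n",
              x$atc, x$bdf, x$ame, x$isi, x$rca, x$trn, x$ndxup))
  invisible(x)
}

#' @export
format.mp_code <- function(x, ...) {
  paste(x$atc, x$bdf, x$ame, x$isi, x$rca, x$trn, format(x$ndxup), sep = "-")
}

# Fifth-level code sequences for fictitious fixed-combination ATCs:
# numeric 99 down to 80, then A0..A9, B0..B9, ..., Z9, then 0A..0Z, ..., 9Z.
.fc_fifth_levels <- function() {
  numeric <- sprintf("%02d", 99:80)
  letter_digit <- as.vector(t(outer(LETTERS, 0:9, paste0)))
  digit_letter <- as.vector(t(outer(0:9, LETTERS, paste0)))
  c(numeric, letter_digit, digit_letter)
}

#' Assign a fictitious ATC fifth level to a fixed combination
#'
#' Fixed combinations whose official ATC does not identify the component
#' active ingredients unambiguously receive a fictitious code: the first
#' four ATC levels of the component with the main therapeutic effect, plus
#' a fifth level drawn from 99 down to 80, a range essentially never used by
#' official assignments. When all twenty numeric codes are taken, the scheme
#' widens to letter+digit fifth levels (A0..Z9, 260 codes) and then
#' digit+letter (0A..9Z, 260 more); those also mark the code as fictitious,
#' since official fifth levels are purely numeric.
#'
#' Existing assignments (official or user-made) are supplied in
#' `already_used_fifth_levels` and are never reused; the generator only
#' fills gaps.
#'
#' @param base_first_four_levels 5-character string: the standard first four
#'   ATC levels (e.g. `"A03DB"`).
#' @param already_used_fifth_levels Character vector of 2-character fifth
#'   levels already taken under this base.
#' @return A 7-character fictitious ATC code.
#' @examples
#' make_fictitious_fc_atc("A03DB", c("04", "95"))
#' @export
make_fictitious_fc_atc <- function(base_first_four_levels,
                                   already_used_fifth_levels = character(0)) {
  base <- base_first_four_levels
  if (!is.character(base) || length(base) != 1L ||
      !grepl("^[A-Z][0-9]{2}[A-Z]{2}$", base)) {
    stop("base_first_four_levels must be a 5-character string matching the ",
         "standard ATC level-1..4 pattern (e.g. 'A03DB')", call. = FALSE)
  }
  candidates <- .fc_fifth_levels()
  free <- setdiff(candidates, already_used_fifth_levels)
  if (!length(free)) {
    stop("all ", length(candidates),
         " fictitious fifth-level codes are exhausted under base ", base,
         call. = FALSE)
  }
  paste0(base, free[[1L]])
}

#' Fictitious ATC code and NDXUP for an electrolyte solution
#'
#' Electrolyte solutions have no meaningful single-ingredient DDD, and their
#' shared official ATC classes do not separate distinct qualitative and
#' quantitative compositions. Each distinct composition therefore receives a
#' deterministic fictitious ATC derived from a stable hash of its normalized
#' composition key, and NDXUP is fixed at the formal value 1 so that
#' products with the same composition compare as exact matches.
#'
#' The fictitious code uses the reserved base `B05X` (the blood-substitute /
#' electrolyte neighbourhood) with a hashed letter as level 4 and a hashed
#' letter+digit or digit+letter fifth level, so re-importing the same
#' composition always yields the same code. Distinct compositions map to
#' distinct codes up to hash collisions (13,520 available codes).
#'
#' @param composition_key Text uniquely identifying the qualitative and
#'   quantitative formula (whitespace and case are normalized).
#' @return A list with elements `atc` (7-character code) and `ndxup` (always
#'   1).
#' @examples
#' electrolyte_code("NaCl 0.9%")
#' @export
electrolyte_code <- function(composition_key) {
  stopifnot(is.character(composition_key), length(composition_key) == 1L,
            nzchar(composition_key))
  key <- tolower(gsub("\\s+", " ", trimws(composition_key)))
  h <- .fnv1a32(key)
  level4 <- LETTERS[(h %% 26) + 1L]
  fifth_codes <- c(as.vector(t(outer(LETTERS, 0:9, paste0))),
                   as.vector(t(outer(0:9, LETTERS, paste0))))
  fifth <- fifth_codes[((h %/% 26) %% length(fifth_codes)) + 1L]
  list(atc = paste0("B05X", level4, fifth), ndxup = 1)
}

# 32-bit FNV-1a over UTF-8 bytes, kept in double precision via modular
# multiplication (R has no native unsigned 32-bit integer).
.fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor2_32(h, b %% 256)
    h <- mulmod32(h, 16777619)
  }
  h
}

bitwXor2_32 <- function(a, b) {
  # xor of doubles holding 32-bit values, 16 bits at a time
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor((a %/% 65536) %% 65536, (b %/% 65536) %% 65536)
  hi * 65536 + lo
}

mulmod32 <- function(a, b) {
  # (a * b) mod 2^32 without losing precision: split a into 16-bit halves
  lo <- (a %% 65536) * b
  hi <- ((a %/% 65536) %% 65536) * b %% 65536
  (lo + hi * 65536) %% 4294967296
}
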