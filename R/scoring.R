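#' Round half away from zero
#'
#' Display rounding for DS scores: exact halves round up (92.05 -> 92.1),
#' unlike [round()]'s round-half-to-even. Comparison and sorting always use
#' unrounded values; this is applied only when a score is reported.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # nudge by one ulp so values sitting a hair below .5 from float error
  # still round as the exact rational would
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Standard-Term weight factors
#'
#' One weight per Standard-Term category, balancing the leverage of the
#' short RCA and TRN scales against the long BDF/AME/ISI scales while still
#' letting dose-form identity (BDF), administration method and intended
#' site dominate the choice of an alternative. The defaults sum to 1.
#'
#' @param bdf,ame,isi,rca,trn Positive weights (defaults 0.46, 0.18, 0.20,
#'   0.09, 0.07).
#' @param allow_unnormalized If `FALSE` (default), weights that do not sum
#'   to 1 (within 1e-9) are refused.
#' @return A named numeric vector of class `weight_factors`.
#' @export
weight_factors <- function(bdf = 0.46, ame = 0.18, isi = 0.20,
                           rca = 0.09, trn = 0.07,
                           allow_unnormalized = FALSE) {
  w <- c(BDF = bdf, AME = ame, ISI = isi, RCA = rca, TRN = trn)
  if (any(!is.finite(w) | w <= 0)) {
    stop("all weight factors must be positive", call. = FALSE)
  }
  if (!allow_unnormalized && abs(sum(w) - 1) > 1e-9) {
    stop("weight factors must sum to 1 (got ", format(sum(w)),
         "); pass allow_unnormalized = TRUE to override", call. = FALSE)
  }
  structure(w, class = "weight_factors")
}

#' Penalty schedule for NDXUP differences
#'
#' Ordered rules comparing the candidate's DDDs-per-presentation-unit
#' (`sub`) with the lacking product's (`lak`): exact equality costs nothing;
#' exactly half costs 2 (double intake); exactly double costs 4 (symmetric
#' division of the unit); strictly between half and equal costs 6; strictly
#' between equal and double costs 8; anything below half or above double
#' takes the class maximum of 10. Equality rules are evaluated before the
#' interval rules, with a relative tolerance, so catalog NDXUPs written as
#' short decimals hit them exactly.
#'
#' @param equal,half,double,between_half_and_equal,between_equal_and_double,outside
#'   Penalty points for each rule (defaults 0, 2, 4, 6, 8, 10).
#' @param max_ndxup_penalty Maximum deduction for the NDXUP class (10).
#' @param max_st_penalty Maximum deduction for the Standard-Term class (80).
#' @param tol Relative tolerance for the equality rules (1e-9).
#' @return A list of class `penalty_schedule`.
#' @export
penalty_schedule <- function(equal = 0, half = 2, double = 4,
                             between_half_and_equal = 6,
                             between_equal_and_double = 8,
                             outside = 10,
                             max_ndxup_penalty = 10,
                             max_st_penalty = 80,
                             tol = 1e-9) {
  pts <- c(equal, half, double, between_half_and_equal,
           between_equal_and_double, outside)
  if (any(!is.finite(pts) | pts < 0)) {
    stop("penalty points must be non-negative", call. = FALSE)
  }
  if (any(pts > max_ndxup_penalty)) {
    stop("penalty points may not exceed max_ndxup_penalty (",
         max_ndxup_penalty, ")", call. = FALSE)
  }
  structure(list(equal = equal, half = half, double = double,
                 between_half_and_equal = between_half_and_equal,
                 between_equal_and_double = between_equal_and_double,
                 outside = outside,
                 max_ndxup_penalty = max_ndxup_penalty,
                 max_st_penalty = max_st_penalty,
                 tol = tol),
            class = "penalty_schedule")
}

#' NDXUP penalty between a lacking product and a candidate
#'
#' @param ndxup_lak,ndxup_sub Positive DDDs per presentation unit of the
#'   lacking product and the candidate substitute.
#' @param schedule A [penalty_schedule()].
#' @return Penalty points (0, 2, 4, 6, 8 or 10 under the defaults). The
#'   rules are asymmetric: a candidate at half the reference strength is
#'   penalized less than one at double.
#' @examples
#' ndxup_penalty(0.4, 0.2) # exactly half -> 2
#' ndxup_penalty(0.4, 0.6) # between equal and double -> 8
#' @export
ndxup_penalty <- function(ndxup_lak, ndxup_sub,
                          schedule = penalty_schedule()) {
  stopifnot(inherits(schedule, "penalty_schedule"))
  for (x in c(ndxup_lak, ndxup_sub)) {
    if (!is.numeric(x) || !is.finite(x) || x <= 0) {
      stop("NDXUP values must be positive finite numbers", call. = FALSE)
    }
  }
  releq <- function(a, b) abs(a - b) <= schedule$tol * max(abs(a), abs(b))
  if (releq(ndxup_sub, ndxup_lak))        return(schedule$equal)
  if (releq(ndxup_sub, 0.5 * ndxup_lak))  return(schedule$half)
  if (releq(ndxup_sub, 2 * ndxup_lak))    return(schedule$double)
  if (ndxup_sub > 0.5 * ndxup_lak && ndxup_sub < ndxup_lak) {
    return(schedule$between_half_and_equal)
  }
  if (ndxup_sub > ndxup_lak && ndxup_sub < 2 * ndxup_lak) {
    return(schedule$between_equal_and_double)
  }
  schedule$outside
}

#' Standard-Term class penalty between two product codes
#'
#' Sums the weighted normalized relative distances over the five
#' Standard-Term categories and rescales the total (a weighted mean on the
#' 0-100 distance scale) to the class maximum of `max_st_penalty` points.
#'
#' @param code_lak,code_sub [mp_code()]s of the lacking product and the
#'   candidate.
#' @param weights A [weight_factors()].
#' @param vocab An [st_vocabulary()].
#' @param max_st_penalty Class maximum (default 80).
#' @return A list: `per_st_nrd` and `per_st_weighted` (named over the five
#'   categories) and `st_penalty` in \[0, `max_st_penalty`\].
#' @export
st_penalty <- function(code_lak, code_sub, weights = weight_factors(),
                       vocab = st_vocabulary(), max_st_penalty = 80) {
  stopifnot(inherits(code_lak, "mp_code"), inherits(code_sub, "mp_code"),
            inherits(weights, "weight_factors"),
            inherits(vocab, "st_vocabulary"))
  nrd <- vapply(ST_CATEGORIES, function(cat) {
    field <- tolower(cat)
    st_nrd(vocab, cat, code_lak[[field]], code_sub[[field]])
  }, numeric(1))
  weighted <- nrd * unclass(weights)[ST_CATEGORIES]
  list(per_st_nrd = nrd,
       per_st_weighted = weighted,
       st_penalty = sum(weighted) / 100 * max_st_penalty)
}

#' Degree of substitutability between two product codes
#'
#' The DS score starts at 100 (a pharmaceutical equivalent) and deducts the
#' NDXUP penalty (at most 10 points) and the Standard-Term class penalty
#' (at most 80 points), so DS always lies in \[10, 100\]. Callers are
#' expected to compare products sharing the same full ATC code; the score
#' itself does not inspect the ATCs.
#'
#' @inheritParams st_penalty
#' @param schedule A [penalty_schedule()].
#' @return An object of class `score_breakdown`: a list with
#'   `ndxup_penalty`, `per_st_nrd`, `per_st_weighted`, `st_penalty`, `ds`
#'   (full working precision) and `ds_display` (rounded half-up to one
#'   decimal, the reporting convention).
#' @examples
#' vocab <- st_vocabulary()
#' ref <- mp_code("N05AX08", "0069", "0019", "0031", "0047", "0042", 0.4)
#' alt <- mp_code("N05AX08", "0083", "0019", "0031", "0047", "0042", 0.2)
#' ds_score(ref, alt, vocab = vocab)$ds_display # 83.2
#' @export
ds_score <- function(code_lak, code_sub, weights = weight_factors(),
                     schedule = penalty_schedule(),
                     vocab = st_vocabulary()) {
  np <- ndxup_penalty(code_lak$ndxup, code_sub$ndxup, schedule)
  sp <- st_penalty(code_lak, code_sub, weights, vocab,
                   max_st_penalty = schedule$max_st_penalty)
  ds <- 100 - np - sp$st_penalty
  structure(list(ndxup_penalty = np,
                 per_st_nrd = sp$per_st_nrd,
                 per_st_weighted = sp$per_st_weighted,
                 st_penalty = sp$st_penalty,
                 ds = ds,
                 ds_display = round_half_up(ds, 1)),
            class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("DS = %.1f  (NDXUP penalty %.1f, ST penalty %.2f)\n",
              x$ds_display, x$ndxup_penalty, x$st_penalty))
  contrib <- sprintf("%s: NRD %.2f x wf -> %.3f", names(x$per_st_nrd),
                     x$per_st_nrd, x$per_st_weighted)
  cat("  ", paste(contrib, collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Read a scoring configuration file
#'
#' A YAML key-value file may override the weight factors (`weights:` with
#' keys bdf/ame/isi/rca/trn), the penalty-schedule points (`penalties:`
#' with keys equal/half/double/between_half_and_equal/
#' between_equal_and_double/outside), the class maxima
#' (`max_ndxup_penalty`, `max_st_penalty`) and `allow_unnormalized_weights`.
#' Weights not summing to 1 are refused unless that flag is set.
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @return A list with elements `weights` and `schedule`.
#' @export
scoring_config <- function(path = NULL) {
  if (is.null(path)) {
    return(list(weights = weight_factors(), schedule = penalty_schedule()))
  }
  cfg <- yaml::read_yaml(path)
  wdef <- formals(weight_factors)
  w <- cfg$weights %||% list()
  weights <- weight_factors(
    bdf = w$bdf %||% wdef$bdf, ame = w$ame %||% wdef$ame,
    isi = w$isi %||% wdef$isi, rca = w$rca %||% wdef$rca,
    trn = w$trn %||% wdef$trn,
    allow_unnormalized = isTRUE(cfg$allow_unnormalized_weights)
  )
  p <- cfg$penalties %||% list()
  pdef <- formals(penalty_schedule)
  schedule <- penalty_schedule(
    equal = p$equal %||% pdef$equal,
    half = p$half %||% pdef$half,
    double = p$double %||% pdef$double,
    between_half_and_equal =
      p$between_half_and_equal %||% pdef$between_half_and_equal,
    between_equal_and_double =
      p$between_equal_and_double %||% pdef$between_equal_and_double,
    outside = p$outside %||% pdef$outside,
    max_ndxup_penalty = cfg$max_ndxup_penalty %||% pdef$max_ndxup_penalty,
    max_st_penalty = cfg$max_st_penalty %||% pdef$max_st_penalty
  )
  list(weights = weights, schedule = schedule)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
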