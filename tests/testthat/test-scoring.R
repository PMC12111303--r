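test_that("default weight factors are the standard set and sum to 1", {
  w <- weight_factors()
  expect_equal(unclass(w),
               c(BDF = 0.46, AME = 0.18, ISI = 0.20, RCA = 0.09, TRN = 0.07))
  expect_equal(sum(w), 1)
  expect_error(weight_factors(bdf = 0.5), "sum to 1")
  expect_silent(weight_factors(bdf = 0.5, allow_unnormalized = TRUE))
  expect_error(weight_factors(trn = -0.07, allow_unnormalized = TRUE),
               "positive")
})

test_that("NDXUP penalty applies the ordered rules", {
  expect_equal(ndxup_penalty(0.4, 0.4), 0)
  expect_equal(ndxup_penalty(0.4, 0.2), 2)    # exactly half
  expect_equal(ndxup_penalty(0.4, 0.8), 4)    # exactly double
  expect_equal(ndxup_penalty(0.4, 0.3), 6)    # between half and equal
  expect_equal(ndxup_penalty(0.4, 0.6), 8)    # between equal and double
  expect_equal(ndxup_penalty(0.4, 0.1), 10)   # below half
  expect_equal(ndxup_penalty(0.4, 13.9), 10)  # far above double
  expect_error(ndxup_penalty(0, 1), "positive")
  expect_error(ndxup_penalty(1, -2), "positive")
})

test_that("equality rules tolerate float noise but intervals stay strict", {
  expect_equal(ndxup_penalty(0.3, 0.1 + 0.2), 0)  # 0.1+0.2 != 0.3 in floats
  expect_equal(ndxup_penalty(0.6, 0.3), 2)
  expect_equal(ndxup_penalty(0.1 + 0.2, 0.6), 4)
  expect_equal(ndxup_penalty(1, 1 + 1e-6), 8)     # outside tolerance
})

test_that("penalty rules are exhaustive over random positive pairs", {
  set.seed(7)
  for (i in 1:500) {
    lak <- stats::runif(1, 1e-3, 50)
    sub <- stats::runif(1, 1e-3, 50)
    p <- ndxup_penalty(lak, sub)
    expect_true(p %in% c(0, 2, 4, 6, 8, 10))
  }
})

test_that("ST penalty reproduces the hand-derived worked values", {
  ref <- risperidone_ref()
  same <- st_penalty(ref, ref, vocab = the_vocab)
  expect_equal(same$st_penalty, 0)

  # only BDF differs: tablet -> oral solution (RP 1 -> 19.5)
  sol <- mp_code("N05AX08", "0083", "0019", "0031", "0047", "0042", 0.2)
  got <- st_penalty(ref, sol, vocab = the_vocab)
  expect_equal(round(got$st_penalty, 1), 14.8)
  expect_equal(got$per_st_nrd[["AME"]], 0)

  # four STs differ: prolonged-release IM suspension
  okedi <- mp_code("N05AX08", "0085", "0011", "0033", "0045", "0042", 13.9)
  got2 <- st_penalty(ref, okedi, vocab = the_vocab)
  expect_equal(round(got2$st_penalty, 1), 31.8)
})

test_that("DS scores reproduce the published risperidone worked example", {
  ref <- risperidone_ref()
  variant <- function(bdf = "0069", ame = "0019", isi = "0031",
                      rca = "0047", trn = "0042", ndxup = 0.4) {
    mp_code("N05AX08", bdf, ame, isi, rca, trn, ndxup)
  }
  ds <- function(sub) ds_score(ref, sub, vocab = the_vocab)$ds_display
  expect_equal(ds(variant()), 100)                       # equivalent
  expect_equal(ds(variant(ndxup = 0.2)), 98.0)           # 1 mg tablet
  expect_equal(ds(variant(ndxup = 0.8)), 96.0)           # 4 mg tablet
  expect_equal(ds(variant(ndxup = 0.6)), 92.0)           # 3 mg tablet
  expect_equal(ds(variant(bdf = "0090", ndxup = 0.2)), 84.4)  # oral drops
  expect_equal(ds(variant(bdf = "0083", ndxup = 0.2)), 83.2)  # oral solution
  okedi <- variant(bdf = "0085", ame = "0011", isi = "0033", rca = "0045",
                   ndxup = 13.9)
  expect_equal(ds(okedi), 58.2)              # prolonged-release IM suspension
  # IM depot with reconstitution by dispersion (TRN 0039): the vocabulary's
  # RP for Dispersion yields 54.5 here
  depot <- variant(bdf = "0085", ame = "0011", isi = "0033", rca = "0045",
                   trn = "0039", ndxup = 4.6)
  expect_equal(ds(depot), 54.5)
})

test_that("breakdown fields are internally consistent", {
  ref <- risperidone_ref()
  sub <- mp_code("N05AX08", "0085", "0011", "0033", "0045", "0039", 4.6)
  br <- ds_score(ref, sub, vocab = the_vocab)
  expect_equal(br$ds, 100 - br$ndxup_penalty - br$st_penalty)
  expect_equal(br$st_penalty, sum(br$per_st_weighted) / 100 * 80)
  expect_true(all(br$per_st_nrd >= 0 & br$per_st_nrd <= 100))
  expect_gte(br$ndxup_penalty, 0); expect_lte(br$ndxup_penalty, 10)
})

test_that("DS stays in [10, 100]; 100 iff identical digital string", {
  set.seed(11)
  for (i in 1:200) {
    lak <- random_code(); sub <- random_code()
    br <- ds_score(lak, sub, vocab = the_vocab)
    expect_gte(br$ds, 10); expect_lte(br$ds, 100)
    identical_string <- all(vapply(
      c("bdf", "ame", "isi", "rca", "trn"),
      function(f) identical(lak[[f]], sub[[f]]), logical(1))) &&
      lak$ndxup == sub$ndxup
    expect_equal(br$ds == 100, identical_string)
  }
})

test_that("increasing one ST's RP distance never increases DS", {
  ref <- risperidone_ref()
  bdf_ids <- the_vocab$st_id[the_vocab$category == "BDF"]
  rps <- the_vocab$rp[the_vocab$category == "BDF"]
  ord <- order(abs(rps - 1))  # distance from Tablet (RP 1)
  ds_seq <- vapply(bdf_ids[ord], function(id) {
    sub <- mp_code("N05AX08", id, "0019", "0031", "0047", "0042", 0.4)
    ds_score(ref, sub, vocab = the_vocab)$ds
  }, numeric(1))
  expect_true(all(diff(ds_seq) <= 1e-12))
})

test_that("the documented asymmetry of the penalty schedule shows in DS", {
  a <- mp_code("N05AX08", "0069", "0019", "0031", "0047", "0042", 0.4)
  b <- mp_code("N05AX08", "0069", "0019", "0031", "0047", "0042", 0.2)
  ds_ab <- ds_score(a, b, vocab = the_vocab)$ds  # half:   penalty 2
  ds_ba <- ds_score(b, a, vocab = the_vocab)$ds  # double: penalty 4
  expect_equal(ds_ab, 98)
  expect_equal(ds_ba, 96)
  expect_false(ds_ab == ds_ba)
})

test_that("engine agrees with the independent brute-force oracle", {
  set.seed(123)
  for (i in 1:1000) {
    lak <- random_code(); sub <- random_code()
    expect_equal(ds_score(lak, sub, vocab = the_vocab)$ds,
                 oracle_ds(lak, sub), tolerance = 1e-9)
  }
})

test_that("display rounding is half-up to one decimal", {
  expect_equal(round_half_up(92.05, 1), 92.1)
  expect_equal(round_half_up(84.44, 1), 84.4)
  expect_equal(round_half_up(55.75, 1), 55.8)
  expect_equal(round_half_up(-1.25, 1), -1.3)  # away from zero
})

test_that("scoring configuration files override weights and penalties", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("weights:", "  bdf: 0.50", "  isi: 0.16",
               "penalties:", "  half: 3"), path)
  cfg <- scoring_config(path)
  expect_equal(cfg$weights[["BDF"]], 0.50)
  expect_equal(cfg$weights[["ISI"]], 0.16)
  expect_equal(cfg$schedule$half, 3)
  expect_equal(cfg$schedule$double, 4)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("weights:", "  bdf: 0.99"), bad)
  expect_error(scoring_config(bad), "sum to 1")
  ok <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("weights:", "  bdf: 0.99",
               "allow_unnormalized_weights: true"), ok)
  expect_equal(scoring_config(ok)$weights[["BDF"]], 0.99)
})
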