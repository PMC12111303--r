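test_that("the bundled risperidone catalog loads with all 33 entries", {
  ct <- risperidone_catalog()
  expect_s3_class(ct, "catalog")
  expect_equal(nrow(ct), 33)
  expect_equal(nrow(attr(ct, "rejects")), 0)
  expect_true("037599230" %in% ct$ma_number)
})

test_that("header problems are fatal; bad rows are skipped with diagnostics", {
  bad_header <- withr::local_tempfile(fileext = ".csv")
  writeLines("ma_number,name,atc", bad_header)
  expect_error(read_catalog(bad_header, the_vocab, quiet = TRUE),
               "missing required columns")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste("ma_number,name,atc,bdf,ame,isi,rca,trn,ndxup,",
                   "pack_metadata", sep = ""), empty)
  ct <- read_catalog(empty, the_vocab, quiet = TRUE)
  expect_equal(nrow(ct), 0)

  mixed <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "ma_number,name,atc,bdf,ame,isi,rca,trn,ndxup,pack_metadata",
    "000000001,GOOD,N05AX08,0069,0019,0031,0047,0042,0.4,",
    "000000002,BAD BDF,N05AX08,069,0019,0031,0047,0042,0.4,",
    "000000003,BAD NDXUP,N05AX08,0069,0019,0031,0047,0042,zero,"), mixed)
  expect_message(ct2 <- read_catalog(mixed, the_vocab),
                 "1 entries accepted, 2 rows rejected")
  expect_equal(ct2$ma_number, "000000001")
  rej <- attr(ct2, "rejects")
  expect_equal(rej$row, c(2L, 3L))
  expect_match(rej$message[1], "bdf")
  expect_match(rej$message[2], "ndxup")
})

test_that("querying the lacking tablet returns the published ranked list", {
  ct <- risperidone_catalog()
  rl <- find_substitutes(ct, "037599230", vocab = the_vocab)
  expect_s3_class(rl, "ranked_list")
  expect_equal(nrow(rl$results), 32)
  expect_equal(rl$results$rank, 1:32)
  expect_equal(rl$results$ds_display[1:4], rep(100, 4))
  expect_equal(rl$results$classification[1:4], rep("equivalent", 4))
  expect_equal(rl$results$ds_display[5:9], rep(98.0, 5))
  expect_equal(rl$results$ds_display[10:14], rep(96.0, 5))
  expect_equal(rl$results$ds_display[15:19], rep(92.0, 5))
  expect_equal(rl$results$ds_display[20:22], rep(84.4, 3))
  expect_equal(rl$results$ds_display[23:24], rep(83.2, 2))
  expect_equal(rl$results$ds_display[25:26], rep(58.2, 2))
  expect_equal(rl$results$ds_display[27:32], rep(54.5, 6))
  expect_true(all(rl$results$classification[-(1:4)] == "alternative"))
  # non-increasing DS; every candidate shares the reference ATC
  expect_true(all(diff(rl$results$ds) <= 0))
  expect_true(all(rl$results$atc == rl$reference$atc))
  expect_false(rl$reference$ma_number %in% rl$results$ma_number)
})

test_that("min_ds and exclusions filter the candidate pool as documented", {
  ct <- risperidone_catalog()
  rl90 <- find_substitutes(ct, "037599230", min_ds = 90, vocab = the_vocab)
  expect_equal(nrow(rl90$results), 19)
  excl <- find_substitutes(ct, "037599230",
                           exclude_ma = c("028752069", "049966017"),
                           vocab = the_vocab)
  expect_equal(nrow(excl$results), 30)
  expect_false(any(c("028752069", "049966017") %in% excl$results$ma_number))
})

test_that("unknown MA numbers fail with nearest keys; unique ATC yields none", {
  ct <- risperidone_catalog()
  expect_error(find_substitutes(ct, "999999999", vocab = the_vocab),
               "not in catalog")
  lone <- as_catalog(rbind(
    as.data.frame(ct),
    data.frame(ma_number = "111111111", name = "LONELY", atc = "A01AA01",
               bdf = "0069", ame = "0019", isi = "0031", rca = "0047",
               trn = "0042", ndxup = 1, pack_metadata = "")),
    vocab = the_vocab, quiet = TRUE)
  rl <- find_substitutes(lone, "111111111", vocab = the_vocab)
  expect_equal(nrow(rl$results), 0)
})

test_that("ranking is deterministic under input shuffling", {
  ct <- risperidone_catalog()
  base <- find_substitutes(ct, "037599230", vocab = the_vocab)$results
  set.seed(99)
  for (i in 1:5) {
    shuffled <- as_catalog(as.data.frame(ct)[sample(nrow(ct)), ],
                           vocab = the_vocab, quiet = TRUE)
    again <- find_substitutes(shuffled, "037599230", vocab = the_vocab)$results
    rownames(again) <- NULL
    expect_identical(again, base)
  }
})

test_that("classification matches the identical-digital-string rule", {
  ref <- risperidone_ref()
  expect_equal(classify_substitute(ref, ref), "equivalent")
  one_mg <- mp_code("N05AX08", "0069", "0019", "0031", "0047", "0042", 0.2)
  expect_equal(classify_substitute(ref, one_mg), "alternative")
  drops <- mp_code("N05AX08", "0090", "0019", "0031", "0047", "0042", 0.4)
  expect_equal(classify_substitute(ref, drops), "alternative")
  # equivalence coincides with DS = 100 on random pairs
  set.seed(5)
  for (i in 1:100) {
    a <- random_code(); b <- random_code()
    br <- ds_score(a, b, vocab = the_vocab)
    expect_equal(classify_substitute(a, b) == "equivalent", br$ds == 100)
  }
})

test_that("results export round-trips through CSV and JSON", {
  ct <- risperidone_catalog()
  rl <- find_substitutes(ct, "037599230", vocab = the_vocab)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_results(rl, csv, "csv")
  back <- utils::read.csv(csv, colClasses = c(
    ma_number = "character", bdf = "character", ame = "character",
    isi = "character", rca = "character", trn = "character"))
  expect_equal(nrow(back), 32)
  expect_equal(back$ds_display, rl$results$ds_display)

  js <- withr::local_tempfile(fileext = ".json")
  write_results(rl, js, "json")
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(parsed$results), 32)
  expect_equal(parsed$results$ds, rl$results$ds)
})

test_that("shortage lists read with and without notes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ma_number,note", "037599230,urgent", "028752069,"), path)
  sl <- read_shortage_list(path)
  expect_equal(sl$ma_number, c("037599230", "028752069"))
  bare <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ma_number", "037599230"), bare)
  expect_equal(read_shortage_list(bare)$note, "")
  expect_error(read_shortage_list(withr::local_tempfile()), "not found")
})
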