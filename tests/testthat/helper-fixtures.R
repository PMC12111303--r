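# Shared fixtures and an independent oracle scorer.

the_vocab <- st_vocabulary()

risperidone_catalog <- function() {
  read_catalog(
    system.file("extdata", "risperidone_catalog.csv", package = "pharmsub"),
    vocab = the_vocab, quiet = TRUE
  )
}

# Reference code of the lacking 2 mg risperidone film tablet.
risperidone_ref <- function() {
  mp_code("N05AX08", "0069", "0019", "0031", "0047", "0042", 0.4)
}

# Independent brute-force scorer: a direct transcription of the scoring
# equations working from the raw vocabulary CSV, sharing no code with the
# engine. Used as the oracle in cross-checks.
oracle_ds <- function(lak, sub) {
  raw <- utils::read.csv(
    system.file("extdata", "standard_terms_1.2.0.csv", package = "pharmsub"),
    colClasses = c("character", "character", "character", "numeric")
  )
  rp_of <- function(cat, id) raw$rp[raw$category == cat & raw$st_id == id]
  span_of <- function(cat) {
    rps <- raw$rp[raw$category == cat]
    max(rps) - min(rps)
  }
  wf <- c(BDF = 0.46, AME = 0.18, ISI = 0.20, RCA = 0.09, TRN = 0.07)
  st_pen <- 0
  for (cat in c("BDF", "AME", "ISI", "RCA", "TRN")) {
    f <- tolower(cat)
    nrd <- abs(rp_of(cat, lak[[f]]) - rp_of(cat, sub[[f]])) / span_of(cat) * 100
    st_pen <- st_pen + nrd * wf[[cat]]
  }
  st_pen <- st_pen / 100 * 80
  a <- lak$ndxup; b <- sub$ndxup
  releq <- function(x, y) abs(x - y) <= 1e-9 * max(abs(x), abs(y))
  nd_pen <-
    if (releq(b, a)) 0
    else if (releq(b, 0.5 * a)) 2
    else if (releq(b, 2 * a)) 4
    else if (b > 0.5 * a && b < a) 6
    else if (b > a && b < 2 * a) 8
    else 10
  100 - nd_pen - st_pen
}

# Random full MP code drawn from the vocabulary; ndxup a short decimal.
random_code <- function(vocab = the_vocab) {
  pick <- function(cat) {
    ids <- vocab$st_id[vocab$category == cat]
    sample(ids, 1)
  }
  mp_code("N05AX08", pick("BDF"), pick("AME"), pick("ISI"), pick("RCA"),
          pick("TRN"), round(stats::runif(1, 0.05, 20), 3))
}
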