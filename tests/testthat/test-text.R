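test_that("preprocessing strips URLs, case, numbers, punctuation, stopwords", {
  tk <- preprocess_corpus("Visit https://x.co NOW!!! 123", stopwords = character(0))
  expect_equal(tk[[1]], c("visit", "now"))

  tk2 <- preprocess_corpus("Police POLICE police", stopwords = character(0))
  expect_equal(unique(tk2[[1]]), "polic")
  expect_equal(length(tk2[[1]]), 3)

  tk3 <- preprocess_corpus("The quick brown fox and the dog")
  expect_false(any(c("the", "and") %in% tk3[[1]]))

  tk4 <- preprocess_corpus("see www.example.com for more",
                           stopwords = character(0))
  expect_false(any(grepl("example", tk4[[1]])))

  expect_warning(preprocess_corpus(c("words here", "123 !!!"),
                                   stopwords = character(0)),
                 "became empty")
  expect_error(preprocess_corpus(character(0)), "empty corpus")
})

test_that("Porter stemmer matches the algorithm's published vocabulary", {
  # frozen oracle: worked examples published with the original algorithm
  pairs <- c(
    caresses = "caress", ponies = "poni", ties = "ti", caress = "caress",
    cats = "cat", feed = "feed", agreed = "agre", plastered = "plaster",
    bled = "bled", motoring = "motor", sing = "sing", conflated = "conflat",
    troubled = "troubl", sized = "size", hopping = "hop", tanned = "tan",
    falling = "fall", hissing = "hiss", fizzed = "fizz", failing = "fail",
    filing = "file", happy = "happi", sky = "sky", relational = "relat",
    conditional = "condit", rational = "ration", valenci = "valenc",
    hesitanci = "hesit", digitizer = "digit", conformabli = "conform",
    radicalli = "radic", differentli = "differ", vileli = "vile",
    analogousli = "analog", vietnamization = "vietnam",
    predication = "predic", operator = "oper", feudalism = "feudal",
    decisiveness = "decis", hopefulness = "hope", callousness = "callous",
    formaliti = "formal", sensitiviti = "sensit", sensibiliti = "sensibl",
    triplicate = "triplic", formative = "form", formalize = "formal",
    electriciti = "electr", electrical = "electr", hopeful = "hope",
    goodness = "good", revival = "reviv", allowance = "allow",
    inference = "infer", airliner = "airlin", gyroscopic = "gyroscop",
    adjustable = "adjust", defensible = "defens", irritant = "irrit",
    replacement = "replac", adjustment = "adjust", dependent = "depend",
    adoption = "adopt", homologou = "homolog", communism = "commun",
    activate = "activ", angulariti = "angular", homologous = "homolog",
    effective = "effect", bowdlerize = "bowdler", probate = "probat",
    rate = "rate", cease = "ceas", controll = "control", roll = "roll",
    generalizations = "gener", oscillators = "oscil")
  got <- porter_stem(names(pairs))
  expect_equal(got, unname(pairs))
  # short words pass through
  expect_equal(porter_stem(c("a", "is", "be")), c("a", "is", "be"))
})

test_that("document-term matrix respects the sparsity threshold", {
  # 1000 docs, term present in 5 -> sparsity 0.995 > 0.9935 -> removed
  tokens <- c(replicate(995, c("common"), simplify = FALSE),
              replicate(5, c("common", "rareword"), simplify = FALSE))
  dtm <- build_dtm(tokens, sparsity = 0.9935)
  expect_false("rareword" %in% colnames(dtm))
  expect_true("common" %in% colnames(dtm))
  # threshold 1 keeps everything
  dtm_all <- build_dtm(tokens, sparsity = 1)
  expect_true(all(c("common", "rareword") %in% colnames(dtm_all)))
  expect_error(build_dtm(tokens, sparsity = 0))
  expect_error(build_dtm(tokens, sparsity = 1.2))
})

test_that("sparsity filtering agrees with brute-force document frequencies", {
  set.seed(51)
  vocab <- letters[1:8]
  tokens <- replicate(10, sample(vocab, sample(2:5, 1)), simplify = FALSE)
  dtm <- build_dtm(tokens, sparsity = 0.70)
  # brute force: term survives iff present in >= 3 of 10 docs
  df <- vapply(vocab, function(w) {
    sum(vapply(tokens, function(tk) w %in% tk, logical(1)))
  }, numeric(1))
  expect_equal(colnames(dtm), sort(vocab[1 - df / 10 <= 0.70]))
  expect_equal(colnames(dtm), sort(vocab[df >= 3]))

  # conservation: column sums equal total corpus counts of surviving stems
  counts <- table(unlist(tokens))
  expect_equal(colSums(dtm), as.vector(counts[colnames(dtm)]),
               ignore_attr = TRUE)

  # lowering the threshold never increases the vocabulary
  k <- vapply(c(1, 0.8, 0.6, 0.4, 0.2),
              function(s) ncol(build_dtm(tokens, sparsity = s)), numeric(1))
  expect_true(all(diff(k) <= 0))
})

test_that("corpus reading and DTM export round-trip", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("id,date,text",
               "acc2,2016-01-02,\"Make America great again\"",
               "acc1,2016-01-03,\"black lives matter\"",
               "acc1,2016-01-01,\"police police brutality reports\""), tmp)
  corp <- read_corpus(tmp)
  expect_equal(corp$id, c("acc1", "acc1", "acc2"))
  expect_false(is.unsorted(corp$date[corp$id == "acc1"]))

  tokens <- preprocess_corpus(corp$text)
  dtm <- build_dtm(tokens, sparsity = 1)
  expect_true(all(dtm >= 0))
  expect_false(any(duplicated(colnames(dtm))))

  outdir <- tempfile()
  write_dtm(dtm, outdir, row_meta = corp[c("id", "date")])
  expect_true(file.exists(file.path(outdir, "counts.mtx")))
  back <- as.matrix(Matrix::readMM(file.path(outdir, "counts.mtx")))
  expect_equal(unname(back), unname(dtm), ignore_attr = TRUE)
  vocab <- read.delim(file.path(outdir, "vocabulary.tsv"))
  expect_equal(vocab$term, colnames(dtm))
})
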