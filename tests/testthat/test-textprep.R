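test_that("the Italian stemmer reduces inflected words to their roots", {
  # hand-traced through the algorithm's regions and suffix steps
  expect_equal(stem_italian(c("paziente", "pazienti")), c("pazient", "pazient"))
  expect_equal(stem_italian(c("glicemia", "glicemie")), c("glicem", "glicem"))
  expect_equal(stem_italian("terapia"), "terap")
  expect_equal(stem_italian("controllo"), "controll")
  expect_equal(stem_italian("ischemica"), "ischem")    # -ica removed in R2
  expect_equal(stem_italian("aderenza"), "aderent")    # -enza -> -ente
  expect_equal(stem_italian(c("modificato", "modificare", "modificavano")),
               rep("modific", 3))                      # verb suffixes in RV
  expect_equal(stem_italian("ricovero"), "ricover")
})

test_that("consonant-final stems are fixed points of the stemmer", {
  # Snowball stemming is not idempotent in general (a vowel-final stem such
  # as "corpore" loses its final vowel on a second pass), but stems ending
  # in a consonant carry no removable suffix and must pass through unchanged
  co <- generate_cohort(generator_config(n_patients = 60, seed = 8,
                                         spurious_mention_rate = 0.3))
  tokens <- unique(unlist(clean_and_stem(co$visits$text)))
  expect_gt(length(tokens), 30)
  # (also set aside -ar/-ir endings, which double as infinitive suffixes)
  cons_final <- tokens[!grepl("([aeiou]|ar|ir)$", tokens)]
  expect_gt(length(cons_final), 20)
  expect_equal(stem_italian(cons_final), cons_final)
})

test_that("cleaning lowercases, removes stop words before stemming, then stems", {
  out <- clean_and_stem("Il Paziente", stopwords = c("il"))
  expect_equal(out[[1]], "pazient")
  expect_equal(clean_and_stem("il la di", stopwords = c("il", "la", "di"))[[1]],
               character(0))
  # a word whose *stem* is a stop word survives, because removal precedes
  # stemming ("stare" stems to "star"; "sta" is a stop word, "star" is not)
  out <- clean_and_stem("stare", stopwords = italian_stopwords())
  expect_equal(out[[1]], "star")
})

test_that("vocabulary pruning drops the rarest 1% of distinct tokens", {
  # 200 distinct tokens with frequency = rank: 1% of 200 -> 2 types dropped
  corpus <- list(unlist(lapply(1:200, function(i) rep(sprintf("tok%03d", i), i))))
  v <- build_vocabulary(corpus, prune_fraction = 0.01)
  expect_equal(nrow(v), 198)
  expect_false(any(c("tok001", "tok002") %in% v$token))
  # prune 0 keeps everything
  v0 <- build_vocabulary(corpus, prune_fraction = 0)
  expect_equal(nrow(v0), 200)
  # indices contiguous from 2, ordered by descending frequency
  expect_equal(sort(v$index), 2:199)
  expect_equal(v$token[v$index == 2], "tok200")
})

test_that("pruning ties at the boundary resolve lexicographically", {
  # four singletons ("aa" "bb" "cc" "dd"), prune 2: the sort oracle says the
  # two lexicographically-first singletons go
  corpus <- list(c(rep("zz", 5), "dd", "cc", "bb", "aa"))
  v <- build_vocabulary(corpus, prune_fraction = 0.5)  # ceil(0.5 * 5) = 3
  ord <- order(c(5, 1, 1, 1, 1), c("zz", "dd", "cc", "bb", "aa"))
  dropped <- c("zz", "dd", "cc", "bb", "aa")[ord[1:3]]
  expect_setequal(v$token, setdiff(c("zz", "dd", "cc", "bb", "aa"), dropped))
  expect_setequal(dropped, c("aa", "bb", "cc"))
})

test_that("frequency accounting matches a brute-force counter", {
  set.seed(11)
  corpus <- replicate(300, sample(sprintf("w%02d", 1:40),
                                  sample(3:12, 1), replace = TRUE),
                      simplify = FALSE)
  v <- build_vocabulary(corpus, prune_fraction = 0)
  flat <- unlist(corpus)
  for (tok in sample(v$token, 10)) {
    expect_equal(v$freq[v$token == tok], sum(flat == tok))
    expect_equal(v$doc_freq[v$token == tok],
                 sum(vapply(corpus, function(d) tok %in% d, logical(1))))
  }
  expect_error(build_vocabulary(list(character(0))),
               class = "cvdnotes_config_error")
})

test_that("encoding maps unknown tokens to OOV, pads and truncates", {
  v <- build_vocabulary(list(c("alfa", "alfa", "beta", "gamma")),
                        prune_fraction = 0)
  enc <- encode_visits(list(c("alfa", "beta", "sconosciuto"),
                            c("beta", "gamma"),
                            rep("alfa", 10)),
                       v, max_len = 5)
  expect_equal(enc$ids[1, ], c(v$index[v$token == "alfa"],
                               v$index[v$token == "beta"], 1L, 0L, 0L))
  expect_false(enc$retained[2])          # fewer than 3 words
  expect_true(enc$retained[1])
  expect_equal(enc$lengths[3], 5L)       # truncated to max_len
  expect_true(all(enc$ids[3, ] == v$index[v$token == "alfa"]))
})

test_that("vocabulary is unchanged by encoding held-out splits", {
  co <- generate_cohort(generator_config(n_patients = 100, seed = 6))
  tokens <- clean_and_stem(co$visits$text)
  train <- tokens[1:300]
  heldout <- tokens[301:length(tokens)]
  v <- build_vocabulary(train)
  before <- vocab_checksum(v)
  invisible(encode_visits(heldout, v, max_len = 12))
  expect_identical(vocab_checksum(v), before)
  # no stop words survive into the vocabulary
  expect_length(intersect(v$token, italian_stopwords()), 0)
})

test_that("vocabulary TSV round trip preserves the token-index map", {
  v <- build_vocabulary(list(c("alfa", "alfa", "beta")), prune_fraction = 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_vocabulary(v, path)
  back <- read_vocabulary(path)
  expect_equal(back$token, v$token)
  expect_equal(back$index, v$index)
})

test_that("the default maximum length is the 99th percentile of training lengths", {
  lens <- c(rep(5, 98), 40, 60)
  corpus <- lapply(lens, function(l) rep("tok", l))
  expect_equal(default_max_len(corpus),
               as.integer(ceiling(quantile(lens, 0.99, names = FALSE))))
})
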