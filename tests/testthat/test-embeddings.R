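test_that("training yields vectors of the requested dimension", {
  m <- small_embedding()
  expect_identical(m$dim, 30L)
  v <- embed_name(m, c("chocolate cake", "fried chicken"))
  expect_identical(dim(v), c(2L, 30L))
  expect_true(all(is.finite(v)))
})

test_that("degenerate and invalid corpora are handled", {
  expect_error(train_embedding_model(character(0)), "empty_corpus")
  expect_error(train_embedding_model(c("", "  ")), "empty_corpus")
  m <- train_embedding_model(rep("butter sugar flour", 5), dim = 8,
                             epochs = 2, seed = 1)
  expect_setequal(m$vocab, c("butter", "sugar", "flour"))
})

test_that("name embedding is the mean of word vectors, order-invariant", {
  m <- small_embedding()
  one <- embed_name(m, "chocolate")[1, ]
  expect_equal(one, unname(word_vector(m, "chocolate")))
  two <- embed_name(m, "chocolate cake")[1, ]
  oracle <- (word_vector(m, "chocolate") + word_vector(m, "cake")) / 2
  expect_equal(two, unname(oracle), tolerance = 1e-12)
  expect_equal(embed_name(m, "cake chocolate")[1, ], two)
  expect_error(embed_name(m, " ,,, "), "empty_name")
})

test_that("out-of-vocabulary words compose from subword units", {
  m <- small_embedding()
  word <- "chocoburger"
  expect_false(word %in% m$vocab)
  v <- word_vector(m, word)
  expect_true(all(is.finite(v)))
  expect_gt(sqrt(sum(v^2)), 0)
  # oracle: mean over the hashed n-gram bucket rows of the input matrix
  grams <- mintr:::word_char_ngrams(word, m$minn, m$maxn)
  rows <- length(m$vocab) +
    vapply(grams, mintr:::hash_ngram, integer(1),
           n_buckets = m$n_buckets) + 1L
  expect_equal(v, colMeans(m$input[rows, , drop = FALSE]))
})

test_that("training is deterministic under a fixed seed", {
  docs <- generate_recipe_corpus(small_corpus())[1:80]
  a <- train_embedding_model(docs, dim = 16, epochs = 3, seed = 5)
  b <- train_embedding_model(docs, dim = 16, epochs = 3, seed = 5)
  expect_identical(a$input, b$input)
  d <- train_embedding_model(docs, dim = 16, epochs = 3, seed = 6)
  expect_false(identical(a$input, d$input))
})

test_that("within-category word pairs are closer than cross-category pairs", {
  # needs the benchmark-scale model; the tiny fixture corpus is too
  # small for the embedding space to separate categories
  m <- bench_fit()$embedding
  vocabs <- bench_corpus()$config$vocab
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  vecs <- lapply(vocabs, function(v) {
    v <- intersect(v, m$vocab)
    t(vapply(v, function(w) word_vector(m, w), numeric(m$dim)))
  })
  mean_pair_cos <- function(A, B, same) {
    s <- 0; n <- 0
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
      if (same && j <= i) next
      s <- s + cos(A[i, ], B[j, ]); n <- n + 1
    }
    s / n
  }
  within <- mean(c(mean_pair_cos(vecs[[1]], vecs[[1]], TRUE),
                   mean_pair_cos(vecs[[3]], vecs[[3]], TRUE)))
  cross <- mean_pair_cos(vecs[[1]], vecs[[3]], FALSE)
  expect_gt(within, cross)
})

test_that("context sentences follow the template", {
  expect_identical(
    build_context_sentence("Egg scrambled",
                           c("butter", "egg", "salt", "pepper")),
    "Egg scrambled made with butter, egg, salt, pepper")
  expect_identical(build_context_sentence("Plain rice"), "Plain rice")
  expect_identical(build_context_sentence("Toast", "butter"),
                   "Toast made with butter")
  expect_error(build_context_sentence(""), "empty_name")
})

test_that("context encoder backends are pluggable and deterministic", {
  m <- small_embedding()
  enc <- context_encoder(m)
  expect_error(context_encoder(m, "mpnet"), "unknown_backend")
  one <- embed_context(enc, "butter")
  expect_equal(one[1, ], unname(word_vector(m, "butter")))
  expect_identical(embed_context(enc, "fudge cake made with sugar"),
                   embed_context(enc, "fudge cake made with sugar"))
  register_context_backend("constant_test",
                           function(model) function(s)
                             matrix(1, length(s), 4))
  enc2 <- context_encoder(m, "constant_test")
  expect_identical(embed_context(enc2, c("a", "b")),
                   matrix(1, 2, 4))
})

test_that("shared names with different ingredient pools embed further apart", {
  m <- small_embedding()
  enc <- context_encoder(m)
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  s_dessert1 <- build_context_sentence("special cake",
                                       c("sugar", "butter", "cocoa"))
  s_dessert2 <- build_context_sentence("special pie",
                                       c("flour", "cream", "honey"))
  s_fried <- build_context_sentence("special basket",
                                    c("oil", "lard", "batter"))
  v <- embed_context(enc, c(s_dessert1, s_dessert2, s_fried))
  expect_gt(cos(v[1, ], v[2, ]), cos(v[1, ], v[3, ]))
})

test_that("word-vector export writes one parsable line per vocabulary word", {
  m <- small_embedding()
  path <- withr::local_tempfile(fileext = ".txt")
  write_word_vectors(m, path)
  lines <- readLines(path)
  expect_length(lines, length(m$vocab))
  first <- strsplit(lines[1], " ")[[1]]
  expect_identical(first[1], m$vocab[1])
  expect_length(first, m$dim + 1L)
  expect_false(any(is.na(as.numeric(first[-1]))))
})
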