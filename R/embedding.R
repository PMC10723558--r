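# Food-language word embeddings: subword-aware skip-gram trained on a
# recipe-style corpus; item names are embedded by averaging their word
# vectors, context sentences by a pluggable sentence-encoder backend.

# polynomial rolling hash of a string modulo n_buckets (subword bucket
# index, 0-based); stays within double-exact integer range
hash_ngram <- function(s, n_buckets) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h %% n_buckets)
}

# character n-grams (minn..maxn) of "<word>", fastText-style
word_char_ngrams <- function(word, minn, maxn) {
  w <- paste0("<", word, ">")
  n <- nchar(w)
  grams <- character(0)
  for (len in minn:maxn) {
    if (len > n) break
    starts <- seq_len(n - len + 1)
    g <- substring(w, starts, starts + len - 1)
    # the full "<word>" token duplicates the word vector itself
    g <- g[g != w | len < n]
    grams <- c(grams, g)
  }
  unique(grams)
}

#' Train a food-language embedding model
#'
#' Trains skip-gram-with-negative-sampling word vectors augmented with
#' hashed character n-gram subword vectors (so out-of-vocabulary words
#' still map to finite vectors) on a recipe-style corpus: one document
#' per food item containing its name, ingredients and preparation text.
#' Training is single-threaded and deterministic under `seed`.
#'
#' @param corpus character vector of text documents.
#' @param dim embedding dimension (default 300).
#' @param epochs training epochs.
#' @param window symmetric context window (dynamic, word2vec-style).
#' @param negative negative samples per positive pair.
#' @param lr initial learning rate (linear decay).
#' @param min_count minimum token frequency to enter the vocabulary.
#' @param minn,maxn character n-gram lengths for subword units.
#' @param n_buckets number of hashed subword buckets.
#' @param seed integer seed.
#' @return object of class `mint_embedding`.
#' @export
train_embedding_model <- function(corpus, dim = 300, epochs = 5,
                                  window = 5, negative = 5, lr = 0.05,
                                  min_count = 1, minn = 3, maxn = 5,
                                  n_buckets = 20000L, seed = 1L) {
  if (length(corpus) == 0 || all(trimws(corpus) == "")) {
    stop("empty_corpus: cannot train on an empty corpus", call. = FALSE)
  }
  stopifnot(dim > 0)
  toks <- tokenize_text(corpus)
  toks <- toks[lengths(toks) > 0]
  freq <- table(unlist(toks))
  vocab <- names(freq)[freq >= min_count]
  if (length(vocab) == 0) {
    stop("empty_corpus: no token reaches min_count", call. = FALSE)
  }
  vocab <- sort(vocab)  # deterministic ordering
  index <- stats::setNames(seq_along(vocab), vocab)
  counts <- as.numeric(freq[vocab])
  docs <- lapply(toks, function(tt) {
    ids <- index[tt]
    as.integer(ids[!is.na(ids)] - 1L)
  })
  docs <- docs[lengths(docs) > 0]
  ngrams <- lapply(vocab, function(w)
    vapply(word_char_ngrams(w, minn, maxn), hash_ngram,
           integer(1), n_buckets = n_buckets, USE.NAMES = FALSE))
  fit <- cpp_train_sgns(docs, length(vocab), ngrams, as.integer(n_buckets),
                        as.integer(dim), as.integer(window),
                        as.integer(epochs), as.integer(negative), lr,
                        counts^0.75, as.integer(seed))
  model <- structure(list(
    input = fit$input, output = fit$output, vocab = vocab, index = index,
    ngrams = ngrams, dim = as.integer(dim), minn = minn, maxn = maxn,
    n_buckets = as.integer(n_buckets),
    meta = list(n_docs = length(docs), n_tokens = sum(lengths(docs)),
                epochs = epochs, window = window, negative = negative,
                lr = lr, seed = seed)
  ), class = "mint_embedding")
  # cache composed in-vocabulary vectors for fast name averaging
  model$word_vecs <- t(vapply(seq_along(vocab), function(i) {
    rows <- c(i, length(vocab) + model$ngrams[[i]] + 1L)
    colMeans(model$input[rows, , drop = FALSE])
  }, numeric(dim)))
  rownames(model$word_vecs) <- vocab
  model
}

#' @export
print.mint_embedding <- function(x, ...) {
  cat("Food embedding model:", length(x$vocab), "words, dim", x$dim,
      sprintf("(%d docs, %d tokens, %d epochs, seed %d)\n",
              x$meta$n_docs, x$meta$n_tokens, x$meta$epochs, x$meta$seed))
  invisible(x)
}

#' Vector for a single word
#'
#' In-vocabulary words are represented by the mean of their word vector
#' and subword-bucket vectors (the composition used during training);
#' out-of-vocabulary words by the mean of their subword vectors alone.
#'
#' @param model [train_embedding_model()] output.
#' @param word single token (already normalized).
#' @return numeric vector of length `model$dim`.
#' @export
word_vector <- function(model, word) {
  stopifnot(inherits(model, "mint_embedding"))
  id <- model$index[word]
  if (!is.na(id)) {
    if (!is.null(model$word_vecs)) return(model$word_vecs[id, ])
    rows <- c(id, length(model$vocab) + model$ngrams[[id]] + 1L)
  } else {
    g <- vapply(word_char_ngrams(word, model$minn, model$maxn), hash_ngram,
                integer(1), n_buckets = model$n_buckets, USE.NAMES = FALSE)
    if (length(g) == 0) return(rep(0, model$dim))
    rows <- length(model$vocab) + g + 1L
  }
  colMeans(model$input[rows, , drop = FALSE])
}

#' Embed food-item names
#'
#' The vector for a name is the component-wise arithmetic mean of its
#' word vectors (order-invariant by construction).
#'
#' @param model [train_embedding_model()] output.
#' @param names character vector of item names.
#' @return matrix (length(names) x dim); for a single name, the matrix
#'   still has one row.
#' @export
embed_name <- function(model, names) {
  stopifnot(inherits(model, "mint_embedding"))
  toks <- tokenize_text(names)
  if (any(lengths(toks) == 0)) {
    stop("empty_name: name has no tokens after normalization",
         call. = FALSE)
  }
  out <- t(vapply(toks, function(tt) {
    vecs <- vapply(tt, function(w) word_vector(model, w),
                   numeric(model$dim))
    rowMeans(matrix(vecs, nrow = model$dim))
  }, numeric(model$dim)))
  rownames(out) <- NULL
  out
}

#' Build an ingredient-contextualized sentence
#'
#' `"<name> made with <ing1>, <ing2>, ..."`; with no ingredients, the
#' bare name is returned.
#'
#' @param name item name (non-empty).
#' @param ingredients character vector of ingredient words (possibly
#'   empty).
#' @return single string.
#' @export
#' @examples
#' build_context_sentence("Egg scrambled",
#'                        c("butter", "egg", "salt", "pepper"))
build_context_sentence <- function(name, ingredients = character(0)) {
  if (length(name) != 1 || is.na(name) || trimws(name) == "") {
    stop("empty_name: context sentence needs a non-empty name",
         call. = FALSE)
  }
  ingredients <- ingredients[!is.na(ingredients) & ingredients != ""]
  if (length(ingredients) == 0) return(name)
  paste0(name, " made with ", paste(ingredients, collapse = ", "))
}

# ---- sentence-encoder backend registry -------------------------------------

.context_backends <- new.env(parent = emptyenv())

#' Register a sentence-encoder backend
#'
#' A backend factory takes a fitted [train_embedding_model()] (may be
#' ignored) and returns a function mapping a character vector of
#' sentences to an embedding matrix. The default `"word_average"`
#' backend averages word vectors; a pretrained transformer encoder can
#' be plugged in behind the same contract.
#'
#' @param name backend name.
#' @param factory function(model) -> function(sentences) -> matrix.
#' @export
register_context_backend <- function(name, factory) {
  assign(name, factory, envir = .context_backends)
  invisible(name)
}

register_context_backend("word_average", function(model) {
  function(sentences) embed_name(model, sentences)
})

#' Create a context-sentence encoder
#'
#' @param model [train_embedding_model()] output (used by the default
#'   backend).
#' @param backend registered backend name.
#' @return object of class `mint_context_encoder`.
#' @export
context_encoder <- function(model, backend = "word_average") {
  if (!exists(backend, envir = .context_backends, inherits = FALSE)) {
    stop("unknown_backend: no context backend named '", backend, "'",
         call. = FALSE)
  }
  factory <- get(backend, envir = .context_backends)
  structure(list(encode = factory(model), backend = backend,
                 dim = model$dim),
            class = "mint_context_encoder")
}

#' Embed context sentences
#'
#' @param encoder [context_encoder()] output.
#' @param sentences character vector.
#' @return embedding matrix, one row per sentence.
#' @export
embed_context <- function(encoder, sentences) {
  stopifnot(inherits(encoder, "mint_context_encoder"))
  if (any(is.na(sentences) | trimws(sentences) == "")) {
    stop("empty_name: sentences must be non-empty", call. = FALSE)
  }
  encoder$encode(sentences)
}

# ---- persistence -----------------------------------------------------------

#' Save / load an embedding model
#'
#' `save_embedding_model()` writes the native serialized model;
#' `write_word_vectors()` exports a plain-text `word v1 v2 ...` table.
#'
#' @param model [train_embedding_model()] output.
#' @param path file path.
#' @export
save_embedding_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_embedding_model
#' @export
load_embedding_model <- function(path) readRDS(path)

#' @rdname save_embedding_model
#' @export
write_word_vectors <- function(model, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (w in model$vocab) {
    writeLines(paste(w, paste(sprintf("%.6g", word_vector(model, w)),
                              collapse = " ")), con)
  }
  invisible(path)
}
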