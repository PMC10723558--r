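stats_fixture <- function(tm) {
  structure(list(true_mean = tm, count = rep(10L, length(tm)),
                 n_categories = length(tm)),
            class = "mint_category_stats")
}

test_that("fcwm_predict matches hand-worked examples", {
  st <- stats_fixture(c(1.0, 0.5))
  expect_identical(fcwm_predict(c(1, 0), st), 1.0)
  expect_identical(fcwm_predict(c(0, 1), st), 0.5)
  expect_equal(fcwm_predict(c(0.7, 0.3), st), 0.85)
  st4 <- stats_fixture(c(0.2, 0.4, 0.9, 1.3))
  expect_equal(fcwm_predict(rep(0.25, 4), st4), mean(c(0.2, 0.4, 0.9, 1.3)))
  expect_error(fcwm_predict(c(0.5, 0.5), st4), "length_mismatch")
  expect_error(fcwm_predict(c(0.7, 0.7), st), "sum to 1")
})

test_that("fcwm_predict equals a brute-force dot product on random inputs", {
  set.seed(21)
  for (i in 1:200) {
    k <- sample(2:8, 1)
    p <- stats::rexp(k); p <- p / sum(p)
    tm <- stats::runif(k, 0, 3)
    brute <- sum(vapply(seq_len(k), function(j) p[j] * tm[j], numeric(1)))
    expect_equal(fcwm_predict(p, stats_fixture(tm)), brute,
                 tolerance = 1e-12)
  }
})

test_that("category_stats summarizes labels and ignores noise", {
  st <- category_stats(c(1, 2, 3, 10), c(1, 1, 2, 0), n_categories = 3)
  expect_equal(st$true_mean[1:2], c(1.5, 3))
  expect_identical(st$count, c(2L, 1L, 0L))
  # empty category falls back to the global mean of labeled items
  expect_equal(st$true_mean[3], 2)
})

test_that("global regressor contracts: size guard and determinism", {
  fit <- bench_fit()
  expect_error(train_global_regressor(fit$name_vectors[1:10, ],
                                      fit$scores[1:10]),
               "too_few_points")
  tr <- fit$train[1:200]
  cfg <- mlp_config(hidden = 16, n_layers = 3, max_epochs = 40, lr = 1e-2,
                    dropout = 0.1)
  a <- train_global_regressor(fit$name_vectors[tr, ], fit$scores[tr],
                              config = cfg, seed = 4)
  b <- train_global_regressor(fit$name_vectors[tr, ], fit$scores[tr],
                              config = cfg, seed = 4)
  te <- fit$test[1:100]
  pa <- predict_scores(a, fit$name_vectors[te, ])
  pb <- predict_scores(b, fit$name_vectors[te, ])
  expect_identical(pa, pb)
})

test_that("zero-epoch fine-tuning is a no-op and small categories fall back", {
  fit <- bench_fit()
  tr <- fit$train
  labs <- fit$pseudo_labels$hard_label[tr] * (!fit$pseudo_labels$is_noise[tr])
  ens0 <- finetune_per_category(fit$regressor, fit$name_vectors[tr, ],
                                fit$scores[tr], labs, epochs = 0, seed = 2)
  te <- fit$test[1:50]
  P <- predict_category(fit$predictor, fit$name_vectors[te, , drop = FALSE])
  expect_equal(predict_ensemble(ens0, fit$name_vectors[te, ], P),
               predict_scores(fit$regressor, fit$name_vectors[te, ]))
  # a category below the threshold falls back to the base model
  labs_small <- labs
  labs_small[labs_small == 1][-(1:5)] <- 2L
  ens_fb <- finetune_per_category(fit$regressor, fit$name_vectors[tr, ],
                                  fit$scores[tr], labs_small,
                                  epochs = 0, seed = 2)
  expect_true(ens_fb$fallback[1])
})

test_that("fine-tuning does not worsen per-category residuals", {
  fit <- bench_fit()
  tr <- fit$train
  labs <- fit$pseudo_labels$hard_label[tr] * (!fit$pseudo_labels$is_noise[tr])
  for (c_ in seq_len(fit$ensemble$n_categories)) {
    idx <- tr[labs == c_]
    if (length(idx) < 20) next
    base_mse <- mean((predict_scores(fit$regressor,
                                     fit$name_vectors[idx, ]) -
                        fit$scores[idx])^2)
    ft_mse <- mean((predict_scores(fit$ensemble$models[[c_]],
                                   fit$name_vectors[idx, ]) -
                      fit$scores[idx])^2)
    expect_lte(ft_mse, base_mse)
  }
})

test_that("MC-dropout intervals behave at the degenerate settings", {
  fit <- bench_fit()
  nms <- bench_corpus()$items$name[fit$test[1:10]]
  # dropout 0: all passes identical, zero-width interval
  ens0 <- fit$ensemble
  for (i in seq_along(ens0$models)) ens0$models[[i]]$net$config$dropout <- 0
  pr0 <- predict_with_uncertainty(ens0, fit$predictor, fit$embedding,
                                  nms, n_mc = 25, seed = 1)
  expect_equal(pr0$ci_high - pr0$ci_low, rep(0, 10))
  P <- predict_category(fit$predictor,
                        embed_name(fit$embedding, nms))
  det <- predict_ensemble(ens0, embed_name(fit$embedding, nms), P)
  expect_equal(pr0$score, det, tolerance = 1e-12)
  # n_mc = 1: interval degenerates to the single draw
  pr1 <- predict_with_uncertainty(fit$ensemble, fit$predictor,
                                  fit$embedding, nms, n_mc = 1, seed = 5)
  expect_equal(pr1$ci_low, pr1$score)
  expect_equal(pr1$ci_high, pr1$score)
  expect_error(predict_with_uncertainty(fit$ensemble, fit$predictor,
                                        fit$embedding, c("ok", " ")),
               "empty_name")
})

test_that("predictions are finite for arbitrary UTF-8 names and CIs bracket", {
  fit <- bench_fit()
  weird <- c("pâté de campagne", "møllehjul smørrebrød",
             "中文名字 kumpir", "zzzzqqq xylophone stew",
             "1000 island wrap")
  pr <- predict_with_uncertainty(fit$ensemble, fit$predictor,
                                 fit$embedding, weird, n_mc = 20, seed = 3)
  expect_true(all(is.finite(pr$score)))
  expect_true(all(is.finite(pr$ci_low) & is.finite(pr$ci_high)))
  expect_true(all(pr$ci_low <= pr$score & pr$score <= pr$ci_high))
  expect_true(all(pr$category_confidence > 0 & pr$category_confidence <= 1))
  # normal-approximation interval variant
  prn <- predict_with_uncertainty(fit$ensemble, fit$predictor,
                                  fit$embedding, weird, n_mc = 20,
                                  ci_method = "normal", seed = 3)
  expect_true(all(prn$ci_low <= prn$score & prn$score <= prn$ci_high))
  # soft routing variant stays finite
  prs <- predict_with_uncertainty(fit$ensemble, fit$predictor,
                                  fit$embedding, weird, n_mc = 5,
                                  routing = "soft", seed = 3)
  expect_true(all(is.finite(prs$score)))
})
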