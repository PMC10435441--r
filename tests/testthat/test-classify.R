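test_that("pair dataset: balance, placement rule, overlap stop", {
  recs <- lapply(1:4, function(i) short_run(seed = i))  # 600 s runs
  win <- window_spec(duration_s = 120, step_s = 20)
  ds <- build_pair_dataset(recs, gap_s = 480, window = win,
                           wavelengths = "970", include_freq = FALSE)
  expect_equal(nrow(ds$X), 8)
  expect_equal(sum(ds$y == 0), 4)
  expect_equal(ds$run, rep(1:4, each = 2))
  # one 20 s step closer: both windows move 10 s toward each other
  ds2 <- build_pair_dataset(recs, gap_s = 460, window = win,
                            wavelengths = "970", include_freq = FALSE)
  expect_false(identical(ds$X[1, ], ds2$X[1, ]))
  # overlapping request refused
  expect_error(build_pair_dataset(recs, gap_s = 100, window = win), "overlap")
  # short run skipped with a warning
  recs2 <- c(recs, list(generate_run(run_profile(duration_s = 200), seed = 9)))
  expect_warning(ds3 <- build_pair_dataset(recs2, gap_s = 480, window = win,
                                           wavelengths = "970",
                                           include_freq = FALSE), "skipped")
  expect_equal(nrow(ds3$X), 8)
})

test_that("sweep step count matches direct enumeration of the stop rule", {
  for (D in c(600, 860, 1320)) {
    recs <- lapply(1:8, function(i)
      generate_run(run_profile(duration_s = D), seed = i))
    win <- window_spec(duration_s = 210, step_s = 20)
    sw <- gap_sweep(recs, win, folds = 4, seed = 1,
                    wavelengths = "1450", include_freq = FALSE)
    # brute-force enumeration: gaps from D - w down by 20 while >= w
    gaps <- c(); gp <- D - 210
    while (gp >= 210) { gaps <- c(gaps, gp); gp <- gp - 20 }
    expect_equal(sw$steps$gap_s, gaps)
    expect_true(all(diff(sw$steps$gap_s) < 0))
    expect_true(all(sw$steps$accuracy >= 0 & sw$steps$accuracy <= 1))
  }
})

test_that("grouped folds keep runs intact and need enough runs", {
  f <- ppgsweat:::grouped_folds(rep(1:8, each = 2), 4, seed = 3)
  expect_length(f, 16)
  for (r in 1:8) expect_length(unique(f[rep(1:8, each = 2) == r]), 1)
  expect_equal(sort(unique(f)), 1:4)
  expect_error(ppgsweat:::grouped_folds(rep(1:3, each = 2), 4, 1), "at least")
})

test_that("boosting is deterministic and learns a separable feature", {
  set.seed(10)
  n <- 40
  X <- matrix(rnorm(n * 15), n, 15)
  y <- rep(c(0, 1), n / 2)
  X[, 4] <- y + rnorm(n, sd = 0.2)
  colnames(X) <- paste0("f", 1:15)
  m1 <- fit_gbt(X, y)
  m2 <- fit_gbt(X, y)
  expect_identical(predict_gbt(m1, X), predict_gbt(m2, X))
  expect_gt(mean((predict_gbt(m1, X) > 0) == (y == 1)), 0.95)
  cv1 <- cv_accuracy(X, y, rep(1:10, each = 4), folds = 4, seed = 5)
  cv2 <- cv_accuracy(X, y, rep(1:10, each = 4), folds = 4, seed = 5)
  expect_equal(cv1$accuracy, cv2$accuracy, tolerance = 1e-12)
})

test_that("label permutation calibrates to chance accuracy", {
  set.seed(11)
  n <- 48
  X <- matrix(rnorm(n * 30), n, 30)
  colnames(X) <- paste0("f", 1:30)
  y <- rep(c(0, 1), n / 2)
  run <- rep(1:24, each = 2)
  perm <- sample(y)
  acc <- cv_accuracy(X, perm, run, folds = 4, seed = 2)$accuracy
  band <- 1.96 * sqrt(0.25 / n)
  expect_gt(acc, 0.5 - band - 1e-9)
  expect_lt(acc, 0.5 + band + 1e-9)
})

test_that("accuracy rises with gap on strongly drifting runs", {
  recs <- lapply(1:8, function(i)
    generate_run(run_profile(duration_s = 860, film_onset_s = 60,
                             film_tau_s = 240), seed = 20 + i))
  sw <- gap_sweep(recs, window_spec(), folds = 4, seed = 1,
                  wavelengths = c("970", "1450"), include_freq = FALSE)
  rho <- suppressWarnings(
    cor(sw$steps$gap_s, sw$steps$accuracy, method = "spearman"))
  if (is.na(rho)) rho <- 0  # saturated accuracy at every gap
  expect_gte(rho, 0)
  expect_gt(sw$steps$accuracy[1], 0.7)  # widest separation is learnable
})

test_that("Shapley ranking: constructed informative feature wins every model", {
  set.seed(12)
  recs_n <- 8
  n <- 2 * recs_n
  mk <- function(shift) {
    X <- matrix(rnorm(n * 10), n, 10)
    y <- rep(c(0, 1), recs_n)
    X[, 6] <- y * shift + rnorm(n, sd = 0.1)
    colnames(X) <- paste0("f", 1:10)
    list(X = X, y = y)
  }
  models <- lapply(c(2, 2.5, 3), function(s) {
    d <- mk(s)
    m <- fit_gbt(d$X, d$y)
    m$train_X <- d$X
    m
  })
  sweep_like <- structure(list(models = models,
                               feature_names = paste0("f", 1:10),
                               steps = data.frame(gap_s = c(3, 2, 1) * 100)),
                          class = "gap_sweep")
  rk <- rank_features(sweep_like, top_k = 4)
  expect_equal(dim(rk$table), c(4, 3))
  for (j in 1:3)
    expect_identical(rownames(rk$importance)[which.max(rk$importance[, j])],
                     "f6")
  expect_identical(rownames(rk$table)[1], "f6")
  # k larger than the feature count clips with a warning
  expect_warning(rk2 <- rank_features(sweep_like, top_k = 99), "clipped")
  expect_equal(nrow(rk2$table), 10)
})

test_that("all-noise features give no stably top-ranked feature across seeds", {
  tops <- vapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(rnorm(24 * 12), 24, 12)
    colnames(X) <- paste0("f", 1:12)
    y <- rep(c(0, 1), 12)
    m <- fit_gbt(X, y)
    imp <- colMeans(abs(shap_values(m, X)))
    names(which.max(imp))
  }, "")
  expect_gt(length(unique(tops)), 1)
})

test_that("Shapley attributions reconstruct the margin (local accuracy)", {
  set.seed(13)
  X <- matrix(rnorm(30 * 6), 30, 6)
  colnames(X) <- paste0("f", 1:6)
  y <- rep(c(0, 1), 15)
  X[, 2] <- y + rnorm(30, sd = 0.3)
  m <- fit_gbt(X, y, gbt_params(nrounds = 50))
  phi <- shap_values(m, X)
  margin <- predict_gbt(m, X)
  # sum of attributions + base value = margin, per row
  base <- mean(margin - rowSums(phi))
  expect_lt(max(abs(rowSums(phi) + base - margin)), 1e-8)
})
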