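# Scaling, ANOVA ranking, wrapper selection, grid optimization, SVM modes.

test_that("scaler implements the linear map with degenerate handling", {
  m <- matrix(c(2, 4, 3, 7, 7, 7), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  ev <- event_list(rep(1L, 3), rep("c", 3), 1:3 / 10, rep(0.01, 3), rep("x", 3))
  ft <- feature_table(m, ev, "t")
  sc <- fit_scaler(ft, m = 0, M = 1)
  out <- apply_scaler(sc, ft)$values
  expect_equal(out[, "a"], c(0, 1, 0.5))      # x = 3 in [2, 4] -> 0.5
  expect_equal(out[, "b"], c(0, 0, 0))        # constant feature -> m
  # out-of-range values extrapolate linearly
  m2 <- matrix(c(6, 1), ncol = 2, dimnames = list(NULL, c("a", "b")))
  ft2 <- feature_table(m2, ev[1L, ], "t")
  expect_equal(unname(apply_scaler(sc, ft2)$values[, "a"]), 2)
  # scaling its own fitting data stays inside [m, M]
  expect_true(all(out >= 0 & out <= 1))
})

test_that("ANOVA F matches the sum-of-squares oracle and orders sanely", {
  set.seed(31)
  x <- matrix(stats::rnorm(60 * 5), ncol = 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  labels <- rep(c("a", "b", "c"), each = 20)
  x[, 2] <- x[, 2] + c(0, 5, 10)[match(labels, c("a", "b", "c"))]
  got <- anova_rank(x, labels)
  # oracle: direct between/within sum-of-squares evaluation
  oracle_f <- apply(x, 2L, function(v) {
    grand <- mean(v)
    ssb <- sum(tapply(v, labels, function(g) length(g) * (mean(g) - grand)^2))
    ssw <- sum(tapply(v, labels, function(g) sum((g - mean(g))^2)))
    (ssb / 2) / (ssw / 57)
  })
  expect_lt(max(abs(got$f_stat - oracle_f)), 1e-10)
  expect_equal(got$order[1L], 2L)
  # constant feature: F = 0, ranked last
  x[, 4] <- 1
  got2 <- anova_rank(x, labels)
  expect_equal(got2$f_stat[4L], 0)
  expect_equal(got2$order[5L], 4L)
  expect_error(anova_rank(x, rep("a", 60)), ">= 2 classes")
  expect_error(anova_rank(x[1:21, ], c(rep("a", 20), "b")), "< 2 samples")
})

test_that("SMO solver satisfies the KKT conditions", {
  set.seed(1)
  n <- 120
  x <- matrix(stats::rnorm(n * 2), ncol = 2)
  y <- ifelse(x[, 1] + x[, 2] + stats::rnorm(n, 0, 0.5) > 0, 1, -1)
  C <- 2; g <- 0.5
  fit <- hfokit:::svm_smo_train(x, y, C, g)
  K <- exp(-g * as.matrix(stats::dist(x))^2)
  f <- as.numeric(K %*% (fit$alpha * y) + fit$b)
  margins <- y * f
  tol <- 2e-2
  expect_true(all(margins[fit$alpha < 1e-6] >= 1 - tol))
  expect_true(all(margins[fit$alpha > C - 1e-6] <= 1 + tol))
  free <- fit$alpha > 1e-6 & fit$alpha < C - 1e-6
  if (any(free)) expect_true(all(abs(margins[free] - 1) <= tol))
  expect_equal(sum(fit$alpha * y), 0, tolerance = 1e-8)
})

test_that("greedy forward selection picks a perfect feature and stops", {
  # feature 1 alone separates the classes perfectly; oracle: no superset can
  # beat accuracy 1.0, so the subset must be {f01}-anchored and terminate
  set.seed(2)
  n_per <- 30
  x <- matrix(stats::rnorm(3 * n_per * 4, sd = 0.2), ncol = 4,
              dimnames = list(NULL, paste0("f0", 1:4)))
  x[, 1] <- x[, 1] + rep(c(0, 5, 10), each = n_per)
  labels <- rep(c("a", "b", "c"), each = n_per)
  idx <- sample(3 * n_per)
  tr <- idx[1:60]; va <- idx[61:90]
  sel <- greedy_forward_select(paste0("f0", 1:4), x[tr, ], labels[tr],
                               x[va, ], labels[va], C = 10, gamma = 1)
  expect_equal(sel$subset, "f01")
  expect_equal(sel$accuracy, 1.0)
})

test_that("greedy forward selection does not grow on pure noise", {
  worse <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    x <- matrix(stats::rnorm(90 * 5), ncol = 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    labels <- rep(c("a", "b", "c"), each = 30)
    idx <- sample(90)
    tr <- idx[1:60]; va <- idx[61:90]
    base <- hfokit:::majority_accuracy(labels[tr], labels[va])
    sel <- greedy_forward_select(paste0("f", 1:5), x[tr, ], labels[tr],
                                 x[va, ], labels[va])
    expect_lte(length(sel$subset), 5L)
    if (sel$accuracy < base) worse <- worse + 1L
  }
  expect_equal(worse, 0L)    # never ends below the majority-class baseline
})

test_that("outer-loop arithmetic is exact", {
  expect_equal(selection_plan(11434, 0.1),
               list(n_runs = 10L, n_validation = 1143L, n_training = 10291L))
  expect_equal(selection_plan(100, 0.25)$n_runs, 4L)
  expect_equal(selection_plan(99, 0.25)$n_validation, 24L)
  for (r in c(0.1, 0.2, 0.3, 0.5)) {
    expect_equal(selection_config(ratio = r, seed = 1)$n_outer, floor(1 / r))
  }
  expect_error(selection_config(ratio = 0.7), "0.5")
})

test_that("wrapper selection recovers planted informative features", {
  hits <- 0L; noise_kept <- integer()
  for (seed in 1:5) {
    d <- fix_class_data(n_per = 40, n_noise = 18, sep = 3, seed = seed)
    sel <- select_feature_subset(d$table, d$labels,
                                 selection_config(ratio = 0.2, seed = seed))
    if (all(c("f01", "f02") %in% sel$subset)) hits <- hits + 1L
    noise_kept <- c(noise_kept, sum(!sel$subset %in% c("f01", "f02")))
  }
  expect_gte(hits, 4L)
  expect_lte(mean(noise_kept), 2)
})

test_that("selection is deterministic for a fixed seed and histogram sane", {
  d <- fix_class_data(n_per = 30, n_noise = 8, seed = 3)
  cfg <- selection_config(ratio = 0.25, seed = 42)
  s1 <- select_feature_subset(d$table, d$labels, cfg)
  s2 <- select_feature_subset(d$table, d$labels, cfg)
  expect_identical(s1$subset, s2$subset)
  expect_identical(s1$histogram, s2$histogram)
  expect_true(all(s1$histogram <= cfg$n_outer))
  expect_true(all(s1$histogram[s1$subset] >= 2L))
})

test_that("grid search is exhaustive, tie-broken, and matches brute force", {
  d <- fix_class_data(n_per = 50, n_noise = 1, seed = 9)
  x <- apply_scaler(fit_scaler(d$table), d$table)$values[, 1:3]
  single <- grid_optimize(x, d$labels, C_grid = 4, gamma_grid = 0.25,
                          folds = 3, seed = 1)
  expect_equal(single$C, 4)
  expect_equal(single$gamma, 0.25)
  Cg <- c(0.5, 8); gg <- c(0.05, 0.5, 2)
  got <- grid_optimize(x, d$labels, Cg, gg, folds = 3, seed = 7)
  # oracle: independent double loop with identical folds
  fold_of <- hfokit:::stratified_folds(d$labels, 3, seed = 7)
  accs <- matrix(NA_real_, 2, 3)
  for (ci in 1:2) for (gi in 1:3) {
    correct <- 0L
    for (k in 1:3) {
      trn <- fold_of != k
      fit <- svm_fit(x[trn, ], d$labels[trn], C = Cg[ci], gamma = gg[gi])
      correct <- correct + sum(svm_predict(fit, x[!trn, ]) == d$labels[!trn])
    }
    accs[ci, gi] <- correct / length(d$labels)
  }
  expect_equal(unname(got$grid), accs)
  best <- which(accs == max(accs), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1L, ]
  expect_equal(got$C, Cg[best[[1]]])       # smallest C, then smallest gamma
  expect_equal(got$gamma, gg[best[[2]]])
  few <- c(1:10, 51:52)          # class F has only 2 samples < 3 folds
  expect_error(grid_optimize(x[few, ], d$labels[few], Cg, gg, folds = 3),
               "fewer folds")
})

test_that("train/validate/classify modes work end to end", {
  d <- fix_class_data(n_per = 40, n_noise = 6, seed = 4)
  cfg <- selection_config(ratio = 0.25, seed = 4,
                          C_grid = 2^c(-1, 3, 7), gamma_grid = 2^c(-7, -3, 1))
  mod <- train_model(d$table, d$labels, cfg)
  expect_s3_class(mod, "hfo_svm_model")
  # construction with 6-SD class separation guarantees separability
  dsep <- fix_class_data(n_per = 30, n_noise = 4, sep = 6, seed = 8)
  msep <- train_model(dsep$table, dsep$labels,
                      selection_config(ratio = 0.25, seed = 8,
                                       C_grid = 2^c(0, 4),
                                       gamma_grid = 2^c(-5, -1)))
  expect_gte(validate_model(msep, dsep$table, dsep$labels)$accuracy, 0.95)
  # fresh same-distribution sample (3-SD world: Bayes accuracy ~0.90)
  d2 <- fix_class_data(n_per = 30, n_noise = 6, seed = 104)
  vr <- validate_model(mod, d2$table, d2$labels)
  expect_gte(vr$accuracy, 0.8)
  expect_true(all(c("P_T", "P_F", "N_F") %in% names(vr$counters)))
  # classification mode rewrites labels
  out <- classify_events(mod, d2$table)
  expect_equal(sort(unique(out$label)), sort(unique(vr$predictions)))
  # single-class input errors
  expect_error(train_model(d$table, rep("R", length(d$labels)), cfg),
               ">= 2 classes")
  # missing features are listed
  small <- feature_table(d2$table$values[, 3:4], d2$table$events, "syn")
  expect_error(validate_model(mod, small, d2$labels), "missing feature")
})

test_that("models survive a save/load round trip bit-exactly", {
  d <- fix_class_data(n_per = 30, n_noise = 4, seed = 6)
  cfg <- selection_config(ratio = 0.25, seed = 6, C_grid = 2^c(0, 4),
                          gamma_grid = 2^c(-5, -1))
  mod <- train_model(d$table, d$labels, cfg)
  tf <- withr::local_tempfile(fileext = ".json")
  save_model(mod, tf)
  back <- load_model(tf)
  d2 <- fix_class_data(n_per = 34, n_noise = 4, seed = 106)
  expect_identical(hfokit:::predict_model(back, d2$table),
                   hfokit:::predict_model(mod, d2$table))
  notmodel <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "other"), notmodel, auto_unbox = TRUE)
  expect_error(load_model(notmodel), "not an hfokit model")
})

test_that("relabel_by_reference transfers labels and conserves counts", {
  ref <- event_list(c(1L, 1L), c("a", "a"), c(0.05, 0.50), c(0.10, 0.10),
                    c("R", "F"))
  det <- event_list(c(1L, 1L, 1L), c("a", "a", "a"), c(0.0, 0.52, 0.80),
                    c(0.10, 0.06, 0.05), rep("EOI", 3))
  out <- relabel_by_reference(det, ref, min_overlap_pct = 50)
  expect_equal(out$label, c("R", "F", "EOI"))
  expect_equal(nrow(out), nrow(det))          # conservation
  counts <- table(out$label)
  expect_equal(sum(counts), nrow(det))
  # detected [0, 100) vs reference [50, 150): overlap 50% of either event
  one <- relabel_by_reference(event_list(1L, "a", 0, 0.1, "EOI"),
                              event_list(1L, "a", 0.05, 0.1, "R"), 50)
  expect_equal(one$label, "R")
})
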