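# Preprocessing, network training/prediction, COD, classification metrics
# and model serialization.

test_that("preprocessing imputes medians then standardizes", {
  tab <- data.frame(a = c(1, 2, NA, 3), b = c(0, 1, 2, 3))
  pp <- preprocess_fit(tab)
  expect_equal(unname(pp$medians["a"]), 2)
  x <- preprocess_apply(tab, pp)
  expect_equal(unname(colMeans(x)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(colMeans(x^2)), c(1, 1), tolerance = 1e-9)
  # same params applied twice give identical output
  expect_identical(preprocess_apply(tab, pp), x)
  # all-missing row maps to (median - mean) / sd
  x2 <- preprocess_apply(data.frame(a = NA_real_, b = NA_real_), pp)
  expect_equal(as.numeric(x2[1, "a"]),
               (pp$medians[["a"]] - pp$means[["a"]]) / pp$sds[["a"]])
  # constant feature falls back to sd 1 with a warning
  expect_warning(pc <- preprocess_fit(data.frame(r = rep(2, 5))), "constant")
  expect_equal(unname(pc$sds["r"]), 1)
  expect_error(preprocess_fit(data.frame(a = c(NA_real_, NA_real_))),
               "entirely missing")
  expect_error(preprocess_apply(data.frame(z = 1), pp), "missing feature")
})

test_that("training is deterministic and rejects degenerate targets", {
  sim <- simulate_feature_table(300, seed = 1)
  tr <- split_structures(sim$structure, seed = 1)
  pp <- preprocess_fit(sim$features[tr, ])
  x <- preprocess_apply(sim$features[tr, ], pp)
  n1 <- train_network(x, sim$targets[tr], seed = 5, max_iter = 20)
  n2 <- train_network(x, sim$targets[tr], seed = 5, max_iter = 20)
  expect_identical(n1$W1, n2$W1)
  expect_identical(n1$w2, n2$w2)
  n3 <- train_network(x, sim$targets[tr], seed = 6, max_iter = 20)
  expect_false(identical(n1$W1, n3$W1))
  expect_error(train_network(x, rep(1, nrow(x)), seed = 0), "single value")
  expect_error(train_network(x[1:10, ], sim$targets[tr][1:10], seed = 0),
               "50 rows")
})

test_that("prediction implements the hidden-layer equation exactly", {
  params <- structure(list(
    feature_names = "f1",
    medians = c(f1 = 0), means = c(f1 = 0), sds = c(f1 = 1),
    W1 = matrix(c(2, rep(0, 9)), 1), b1 = c(0.5, rep(0, 9)),
    w2 = c(3, rep(0, 9)), b2 = -1, hidden = 10L, seed = 0L),
    class = "network_params")
  x <- matrix(c(-1, 0, 0.7), ncol = 1)
  expect_equal(predict_network(x, params),
               3 * tanh(2 * x[, 1] + 0.5) - 1, tolerance = 1e-12)
  # all-zero weights give the output intercept everywhere
  p0 <- params; p0$W1[] <- 0; p0$w2[] <- 0; p0$b1[] <- 0; p0$b2 <- 0.7
  expect_equal(predict_network(x, p0), rep(0.7, 3))
  # row order invariance
  set.seed(3)
  xs <- matrix(rnorm(20), ncol = 1)
  expect_equal(predict_network(xs, params)[c(3, 1)],
               predict_network(xs[c(3, 1), , drop = FALSE], params))
  expect_error(predict_network(cbind(xs, xs), params), "mismatch")
})

test_that("COD matches its definition", {
  expect_equal(cod(c(1, 2, 3), c(1, 2, 3)), 1)
  t <- c(0, 1, 0, 1, 1)
  expect_equal(cod(rep(mean(t), 5), t), 0)
  expect_equal(cod(c(0.25, 0.75, 0.25, 0.75), c(0, 1, 0, 1)), 0.75)
  expect_error(cod(c(1, 2), c(3, 3)), "constant")
  set.seed(4)
  for (k in 1:100) {
    tt <- rnorm(20); pp <- rnorm(20)
    expect_equal(cod(pp, tt), 1 - sum((tt - pp)^2) / sum((tt - mean(tt))^2),
                 tolerance = 1e-12)
  }
})

test_that("classification counts and metrics follow the definitions", {
  cc <- classify(rep(0.9, 5), rep(1, 5))
  expect_equal(cc, list(TP = 5L, TN = 0L, FP = 0L, FN = 0L))
  # a score of exactly 0.5 is predicted correct
  expect_equal(classify(0.5, 0)$FP, 1L)
  m <- classification_metrics(list(TP = 70, TN = 10, FP = 3, FN = 17))
  expect_equal(m$accuracy, 80)
  set.seed(5)
  for (k in 1:100) {
    cnt <- as.list(sample(1:50, 4)); names(cnt) <- c("TP", "TN", "FP", "FN")
    got <- unlist(classification_metrics(cnt))
    ref <- oracle_metrics(cnt$TP, cnt$TN, cnt$FP, cnt$FN)
    expect_equal(unname(got), unname(ref), tolerance = 1e-12)
    expect_equal(got[["sensitivity"]] + got[["false_negative_rate"]], 100)
    expect_equal(got[["specificity"]] + got[["false_positive_rate"]], 100)
  }
  # zero denominators yield missing markers
  expect_true(is.na(classification_metrics(list(TP = 0, TN = 3, FP = 0,
                                                FN = 0))$sensitivity))
})

test_that("networks survive a JSON round-trip bit-for-bit", {
  sim <- simulate_feature_table(200, seed = 2)
  pp <- preprocess_fit(sim$features)
  x <- preprocess_apply(sim$features, pp)
  net <- train_network(x, sim$targets, seed = 0, preprocess = pp,
                       max_iter = 15)
  path <- tempfile(fileext = ".json")
  save_network(net, path)
  net2 <- load_network(path)
  expect_identical(predict_network(x, net2), predict_network(x, net))
  expect_equal(net2$seed, 0L)
  # a JSON with the wrong schema or shape is rejected
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(schema = "other"), bad, auto_unbox = TRUE)
  expect_error(load_network(bad), "format")
  obj <- jsonlite::fromJSON(path)
  obj$feature_names <- obj$feature_names[-1]
  jsonlite::write_json(obj, bad, auto_unbox = TRUE, digits = NA)
  expect_error(load_network(bad), "dimensions|format")
})

test_that("the structure-level split is 4:1 and reproducible", {
  ids <- rep(paste0("S", 1:20), each = 10)
  s1 <- split_structures(ids, seed = 3)
  s2 <- split_structures(ids, seed = 3)
  expect_identical(s1, s2)
  expect_equal(length(unique(ids[s1])), 16L)
  expect_equal(length(unique(ids[!s1])), 4L)
  # never splits residues of one structure across sets
  tab <- table(ids, s1)
  expect_true(all(rowSums(tab > 0) == 1L))
})

test_that("ablation separates redundant from unique signal", {
  sim <- simulate_feature_table(600, signal_spec = list(f1 = 2),
                                seed = 0, n_features = 2,
                                link = "linear", binarize = FALSE)
  feats <- sim$features
  feats$f1_dup <- feats$f1
  ab <- ablation(feats, sim$targets, n_seeds = 3)
  expect_equal(nrow(ab), ncol(feats) + 1L)
  expect_equal(ab$drop[ab$feature == "(none)"], 0)
  expect_lt(abs(ab$drop[ab$feature == "f1_dup"]), 0.02)
  expect_lt(abs(ab$drop[ab$feature == "f1"]), 0.02)  # duplicate covers it
})
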