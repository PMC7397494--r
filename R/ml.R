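# Correctness regression: preprocessing, one-hidden-layer network training
# with Adam, prediction, the coefficient of determination and the
# classification metrics derived from a 0.5 threshold.
#
# The network is small by design: 10 tanh hidden units, a linear output,
# squared-error loss with an L2 penalty of 1e-4, trained with Adam for at
# most 200 epochs. Training is fully determined by its seed.

#' Fit preprocessing statistics on a training table
#'
#' Computes per-feature medians (for imputing missing values), then means
#' and standard deviations after imputation (population variance). A
#' constant feature gets a standard deviation of 1 with a warning, so its
#' scaled column is all zeros.
#'
#' @param rows Data frame or matrix of training features (NA = missing).
#' @return List with `medians`, `means`, `sds`, all named by feature.
#' @export
preprocess_fit <- function(rows) {
  x <- as.matrix(rows)
  if (nrow(x) == 0L) stop("preprocess_fit: empty table")
  if (any(colSums(!is.na(x)) == 0L))
    stop("preprocess_fit: feature(s) entirely missing: ",
         paste(colnames(x)[colSums(!is.na(x)) == 0L], collapse = ", "))
  medians <- apply(x, 2L, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- medians[j]
  means <- colMeans(x)
  sds <- sqrt(colMeans(sweep(x, 2L, means)^2))
  if (any(sds == 0)) {
    warning("preprocess_fit: constant feature(s) ",
            paste(colnames(x)[sds == 0], collapse = ", "),
            "; standard deviation set to 1")
    sds[sds == 0] <- 1
  }
  list(medians = medians, means = means, sds = sds)
}

#' Apply training preprocessing to a feature table
#'
#' Imputes missing entries with the training medians, then centres and
#' scales with the training means and standard deviations.
#'
#' @param rows Data frame or matrix of features.
#' @param params A `network_params` object or the list from
#'   [preprocess_fit()].
#' @return Numeric matrix of scaled features.
#' @export
preprocess_apply <- function(rows, params) {
  x <- as.matrix(rows)
  want <- names(params$medians)
  if (!is.null(colnames(x))) {
    if (!all(want %in% colnames(x)))
      stop("preprocess_apply: missing feature columns: ",
           paste(setdiff(want, colnames(x)), collapse = ", "))
    extra <- setdiff(colnames(x), want)
    if (length(extra))
      stop("preprocess_apply: unknown feature columns: ",
           paste(extra, collapse = ", "))
    x <- x[, want, drop = FALSE]
  } else if (ncol(x) != length(want)) {
    stop("preprocess_apply: feature count mismatch")
  }
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- params$medians[j]
  sweep(sweep(x, 2L, params$means), 2L, params$sds, `/`)
}

glorot_init <- function(n_in, n_out) {
  b <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -b, b), n_in, n_out)
}

#' Train a correctness network
#'
#' One hidden layer of `hidden` tanh units and a single linear output,
#' squared-error loss with L2 regularization `alpha`, optimized with Adam
#' (learning rate 1e-3, beta1 0.9, beta2 0.999, minibatch 200) for at most
#' `max_iter` epochs. Bit-reproducible given (`data`, `seed`).
#'
#' @param scaled Numeric matrix of preprocessed features.
#' @param targets Numeric vector of targets (binary correctness labels or
#'   any regression target).
#' @param seed Integer RNG seed controlling initialization and shuffling.
#' @param preprocess Preprocessing list from [preprocess_fit()]; stored in
#'   the returned object so it can be reapplied at prediction time.
#' @param hidden Hidden-layer width (default 10).
#' @param alpha L2 penalty (default 1e-4).
#' @param max_iter Maximum epochs (default 200).
#' @param learning_rate,beta1,beta2,epsilon,batch_size Adam hyperparameters.
#' @return Object of class `network_params`.
#' @export
train_network <- function(scaled, targets, seed = 0L, preprocess = NULL,
                          hidden = 10L, alpha = 1e-4, max_iter = 200L,
                          learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                          epsilon = 1e-8, batch_size = 200L) {
  x <- as.matrix(scaled)
  y <- as.numeric(targets)
  if (nrow(x) != length(y)) stop("train_network: row/target length mismatch")
  if (nrow(x) < 50L) stop("train_network: need at least 50 rows")
  if (length(unique(y)) < 2L)
    stop("train_network: targets contain a single value")
  n <- nrow(x); p <- ncol(x)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  W1 <- glorot_init(p, hidden)
  b1 <- rep(0, hidden)
  w2 <- as.vector(glorot_init(hidden, 1L))
  b2 <- 0
  m_W1 <- v_W1 <- matrix(0, p, hidden)
  m_b1 <- v_b1 <- rep(0, hidden)
  m_w2 <- v_w2 <- rep(0, hidden)
  m_b2 <- v_b2 <- 0
  t_step <- 0L
  bs <- min(batch_size, n)
  for (epoch in seq_len(max_iter)) {
    perm <- sample.int(n)
    for (start in seq(1L, n, by = bs)) {
      idx <- perm[start:min(start + bs - 1L, n)]
      nb <- length(idx)
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      h_in <- sweep(xb %*% W1, 2L, -b1)
      h <- tanh(h_in)
      pred <- as.vector(h %*% w2) + b2
      delta <- (pred - yb) / nb
      g_w2 <- as.vector(t(h) %*% delta) + alpha * w2 / nb
      g_b2 <- sum(delta)
      dh <- outer(delta, w2) * (1 - h^2)
      g_W1 <- t(xb) %*% dh + alpha * W1 / nb
      g_b1 <- colSums(dh)
      t_step <- t_step + 1L
      corr <- sqrt(1 - beta2^t_step) / (1 - beta1^t_step)
      upd <- function(m, v, g) {
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g^2
        list(m = m, v = v, step = corr * learning_rate * m / (sqrt(v) + epsilon))
      }
      u <- upd(m_W1, v_W1, g_W1); m_W1 <- u$m; v_W1 <- u$v; W1 <- W1 - u$step
      u <- upd(m_b1, v_b1, g_b1); m_b1 <- u$m; v_b1 <- u$v; b1 <- b1 - u$step
      u <- upd(m_w2, v_w2, g_w2); m_w2 <- u$m; v_w2 <- u$v; w2 <- w2 - u$step
      u <- upd(m_b2, v_b2, g_b2); m_b2 <- u$m; v_b2 <- u$v; b2 <- b2 - u$step
    }
  }
  feature_names <- colnames(x)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(p))
  if (is.null(preprocess)) {
    preprocess <- list(medians = stats::setNames(rep(NA_real_, p), feature_names),
                       means = stats::setNames(rep(0, p), feature_names),
                       sds = stats::setNames(rep(1, p), feature_names))
  }
  structure(list(feature_names = feature_names,
                 medians = preprocess$medians, means = preprocess$means,
                 sds = preprocess$sds, W1 = W1, b1 = b1, w2 = w2, b2 = b2,
                 hidden = hidden, alpha = alpha, max_iter = max_iter,
                 learning_rate = learning_rate, batch_size = batch_size,
                 seed = as.integer(seed)),
            class = "network_params")
}

#' Predict correctness scores from scaled features
#'
#' Evaluates score = sum_k w2_k tanh(sum_n W1_nk x_n + b1_k) + b2 row-wise.
#' Scores are unbounded reals; no clipping is applied.
#'
#' @param scaled Numeric matrix with columns matching the network's inputs.
#' @param params A `network_params` object.
#' @return Numeric score vector.
#' @export
predict_network <- function(scaled, params) {
  x <- as.matrix(scaled)
  if (ncol(x) != nrow(params$W1))
    stop("predict_network: feature count mismatch (expected ",
         nrow(params$W1), ", got ", ncol(x), ")")
  h <- tanh(sweep(x %*% params$W1, 2L, -params$b1))
  as.vector(h %*% params$w2) + params$b2
}

#' Coefficient of determination
#'
#' 1 - sum((t - p)^2) / sum((t - mean(t))^2); 1 for perfect prediction,
#' 0 when the prediction is no better than the target mean.
#'
#' @param predicted,target Equal-length numeric vectors (length >= 2).
#' @return Scalar at most 1.
#' @export
cod <- function(predicted, target) {
  if (length(predicted) != length(target) || length(target) < 2L)
    stop("cod: need equal lengths >= 2")
  ss_tot <- sum((target - mean(target))^2)
  if (ss_tot == 0) stop("cod: constant target")
  1 - sum((target - predicted)^2) / ss_tot
}

#' Confusion counts at a correctness threshold
#'
#' Scores at or above `threshold` are predicted correct; the positive class
#' is "correct". TP = correct predicted correct, TN = incorrect predicted
#' incorrect, FP = incorrect predicted correct, FN = correct predicted
#' incorrect.
#'
#' @param scores Numeric score vector.
#' @param targets Binary target vector (1 = correct).
#' @param threshold Decision threshold (default 0.5; scores equal to it
#'   count as correct).
#' @return List with integer `TP`, `TN`, `FP`, `FN`.
#' @export
classify <- function(scores, targets, threshold = 0.5) {
  if (length(scores) != length(targets)) stop("classify: length mismatch")
  pred <- scores >= threshold
  list(TP = sum(pred & targets == 1), TN = sum(!pred & targets == 0),
       FP = sum(pred & targets == 0), FN = sum(!pred & targets == 1))
}

#' Classification quality metrics, as percentages
#'
#' Accuracy, error, sensitivity (true-positive rate), specificity
#' (true-negative rate), false-negative rate, false-positive rate,
#' precision and F1 score, all in percent. A metric whose denominator is
#' zero is `NA`.
#'
#' @param counts Confusion counts from [classify()].
#' @return Named list of eight percentages.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  n <- tp + tn + fp + fn
  div <- function(a, b) if (b == 0) NA_real_ else 100 * a / b
  acc <- div(tp + tn, n)
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  list(accuracy = acc, error = if (is.na(acc)) NA_real_ else 100 - acc,
       sensitivity = sens, specificity = spec,
       false_negative_rate = if (is.na(sens)) NA_real_ else 100 - sens,
       false_positive_rate = if (is.na(spec)) NA_real_ else 100 - spec,
       precision = prec, f1_score = f1)
}

#' Save / load a trained network as JSON
#'
#' The JSON records a schema version, the feature names, the imputation
#' medians, scaler means/sds, all weights and intercepts, and the training
#' seed; a round-trip preserves predictions bit-for-bit.
#'
#' @param params A `network_params` object.
#' @param path JSON file path.
#' @return `path` (save) or a `network_params` (load).
#' @export
save_network <- function(params, path) {
  obj <- list(schema = "rescorrect-network/1",
              feature_names = params$feature_names,
              medians = as.numeric(params$medians),
              means = as.numeric(params$means),
              sds = as.numeric(params$sds),
              W1 = params$W1, b1 = params$b1, w2 = params$w2, b2 = params$b2,
              hidden = params$hidden, seed = params$seed)
  # I(17) significant digits: doubles round-trip decimal exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("load_network: file not found: ", path)
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$schema) || obj$schema != "rescorrect-network/1")
    stop("load_network: unrecognized network file format")
  p <- length(obj$feature_names)
  W1 <- matrix(as.numeric(obj$W1), nrow = p)
  if (ncol(W1) != obj$hidden || length(obj$medians) != p)
    stop("load_network: inconsistent dimensions in network file")
  nm <- obj$feature_names
  structure(list(feature_names = nm,
                 medians = stats::setNames(as.numeric(obj$medians), nm),
                 means = stats::setNames(as.numeric(obj$means), nm),
                 sds = stats::setNames(as.numeric(obj$sds), nm),
                 W1 = W1, b1 = as.numeric(obj$b1),
                 w2 = as.numeric(obj$w2), b2 = as.numeric(obj$b2),
                 hidden = as.integer(obj$hidden), seed = as.integer(obj$seed)),
            class = "network_params")
}

#' Split structures into training and test sets at a 4:1 ratio
#'
#' The split is by structure (never by residue), seeded and reproducible.
#'
#' @param structure_ids Vector of structure identifiers (one per row).
#' @param seed RNG seed.
#' @param train_fraction Fraction of structures assigned to training.
#' @return Logical vector, TRUE for training rows.
#' @export
split_structures <- function(structure_ids, seed = 0L, train_fraction = 0.8) {
  ids <- unique(structure_ids)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  n_train <- max(1L, round(length(ids) * train_fraction))
  if (length(ids) > 1L) n_train <- min(n_train, length(ids) - 1L)
  train_ids <- sample(ids, n_train)
  structure_ids %in% train_ids
}
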