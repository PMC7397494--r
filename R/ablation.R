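# Feature-ablation harness: retrain with each feature removed, across
# seeds, and report the change in the test-set coefficient of
# determination relative to the full model.

#' Feature ablation study
#'
#' For seeds 0..n_seeds-1: split rows 4:1 (by `groups` when given,
#' otherwise by row), fit preprocessing and train on the training part,
#' and score the test-set COD for the full feature set and for each
#' leave-one-feature-out set. Reports, per feature, the mean test COD, its
#' standard error (sd / sqrt(n_seeds)) and the mean decrease relative to
#' the full model. The baseline row is labelled `"(none)"`.
#'
#' @param table Data frame of features (NA = missing).
#' @param targets Numeric target vector.
#' @param n_seeds Number of training repeats (seeds 0..n_seeds-1).
#' @param groups Optional structure ids for the split.
#' @param ... Passed to [train_network()].
#' @return Data frame with columns `feature`, `mean_cod`, `se`, `drop`.
#' @export
ablation <- function(table, targets, n_seeds = 20L, groups = NULL, ...) {
  feats <- colnames(table)
  if (length(feats) < 2L) stop("ablation: need at least 2 features")
  variants <- c(list(feats), lapply(feats, function(f) setdiff(feats, f)))
  names(variants) <- c("(none)", feats)
  cods <- matrix(NA_real_, n_seeds, length(variants),
                 dimnames = list(NULL, names(variants)))
  for (s in seq_len(n_seeds)) {
    seed <- s - 1L
    train_sel <- if (is.null(groups)) {
      split_structures(seq_along(targets), seed = seed)
    } else split_structures(groups, seed = seed)
    for (v in seq_along(variants)) {
      sub <- table[, variants[[v]], drop = FALSE]
      pp <- preprocess_fit(sub[train_sel, , drop = FALSE])
      xtr <- preprocess_apply(sub[train_sel, , drop = FALSE], pp)
      xte <- preprocess_apply(sub[!train_sel, , drop = FALSE], pp)
      net <- train_network(xtr, targets[train_sel], seed = seed,
                           preprocess = pp, ...)
      cods[s, v] <- cod(predict_network(xte, net), targets[!train_sel])
    }
  }
  mean_cod <- colMeans(cods)
  se <- apply(cods, 2L, stats::sd) / sqrt(n_seeds)
  data.frame(feature = names(variants), mean_cod = mean_cod, se = se,
             drop = mean_cod[["(none)"]] - mean_cod,
             row.names = NULL, stringsAsFactors = FALSE)
}
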