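#' Area under the ROC curve (Mann-Whitney form)
#'
#' `P(score_case > score_control) + 0.5 P(tie)`, computed from ranks.
#'
#' @param scores numeric prediction scores (higher = predicted case).
#' @param labels binary 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_wgp("AUC needs both classes present")
  if (n1 + n0 != length(labels)) stop_wgp("labels must be 0/1")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC points
#'
#' @param scores,labels as in [auc()].
#' @return data frame of (fpr, tpr) points including (0,0) and (1,1),
#'   one point per distinct threshold.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.numeric(labels)
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  tp <- cumsum(lab); fp <- cumsum(1 - lab)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)   # last point per tied threshold
  data.frame(fpr = c(0, fp[keep] / sum(labels == 0)),
             tpr = c(0, tp[keep] / sum(labels == 1)))
}

#' Convex-hull AUC
#'
#' Area under the upper convex hull of the empirical ROC points (always
#' >= the raw AUC; equal when the ROC is already concave).
#'
#' @inheritParams auc
#' @export
convex_hull_auc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1)
    pts <- rbind(pts, data.frame(fpr = 1, tpr = 1))
  # upper hull, monotone-chain style: scan in increasing fpr, drop points
  # that create a convex (upward) kink
  hx <- numeric(0); hy <- numeric(0)
  for (i in seq_len(nrow(pts))) {
    x <- pts$fpr[i]; y <- pts$tpr[i]
    while (length(hx) >= 2) {
      k <- length(hx)
      cross <- (hx[k] - hx[k - 1]) * (y - hy[k - 1]) -
        (hy[k] - hy[k - 1]) * (x - hx[k - 1])
      if (cross >= 0) { hx <- hx[-k]; hy <- hy[-k] } else break
    }
    hx <- c(hx, x); hy <- c(hy, y)
  }
  sum(diff(hx) * (utils::head(hy, -1) + utils::tail(hy, -1)) / 2)
}

#' Label-permutation empirical p-value for AUC above chance
#'
#' Permutes labels `n_perm` times against the fixed scores; the one-sided
#' p-value is `(1 + #{AUC_perm >= AUC_obs}) / (n_perm + 1)`, which can never
#' be zero.
#'
#' @inheritParams auc
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return list with `p_value`, `auc_obs`, `null_auc` (the permuted AUCs).
#' @export
permutation_pvalue <- function(scores, labels, n_perm = 999, seed = 1L) {
  stopifnot(n_perm >= 1)
  a_obs <- auc(scores, labels)
  set.seed(seed)
  null_auc <- vapply(seq_len(n_perm),
                     function(i) auc(scores, sample(labels)), numeric(1))
  list(p_value = (1 + sum(null_auc >= a_obs)) / (n_perm + 1),
       auc_obs = a_obs, null_auc = null_auc)
}

new_eval_result <- function(per_repeat, protocol, n_permutations) {
  structure(list(per_repeat = per_repeat,
                 auc = mean(per_repeat$auc),
                 ch_auc = mean(per_repeat$ch_auc),
                 p_empirical = mean(per_repeat$p),
                 sd_auc = stats::sd(per_repeat$auc),
                 sd_ch_auc = stats::sd(per_repeat$ch_auc),
                 n_permutations = n_permutations,
                 protocol = protocol),
            class = "eval_result")
}

#' @exportS3Method base::print
print.eval_result <- function(x, ...) {
  cat(sprintf("Evaluation (%s, %d repeat(s), %d permutations):\n",
              x$protocol, nrow(x$per_repeat), x$n_permutations))
  cat(sprintf("  mean AUC %.3f (SD %s), mean convex-hull AUC %.3f, mean p %.4f\n",
              x$auc, ifelse(is.na(x$sd_auc), "NA", sprintf("%.3f", x$sd_auc)),
              x$ch_auc, x$p_empirical))
  invisible(x)
}

#' @export
plot.eval_result <- function(x, ...) {
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey",
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = sprintf("%s: mean AUC %.3f", x$protocol, x$auc), ...)
  invisible(x)
}

stratified_split <- function(labels, train_fraction, max_tries = 20) {
  n <- length(labels)
  for (t in seq_len(max_tries)) {
    tr <- logical(n)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      tr[sample(idx, round(train_fraction * length(idx)))] <- TRUE
    }
    if (length(unique(labels[!tr])) > 1 && length(unique(labels[tr])) > 1)
      return(tr)
  }
  stop_wgp("could not produce a two-class split in ", max_tries, " tries")
}

#' Repeated stratified train/test split evaluation
#'
#' The cohort is split into a training fraction (default 75%) and a held-out
#' test fraction, stratified by class; the predictor is trained on the
#' training portion and scored on the test portion; AUC, convex-hull AUC and
#' the label-permutation p-value are recorded; the procedure is repeated
#' (default 25 times) and means and standard deviations reported.
#'
#' @param predictor function `(train_ids, test_ids, repeat_seed) ->
#'   prediction_scores` for the test subjects.
#' @param labels named (or kinship-ordered) 0/1 vector for all subjects.
#' @param subject_ids subject ids aligned with `labels`.
#' @param train_fraction training proportion in (0, 1); default 0.75.
#' @param n_repeats number of random splits; default 25.
#' @param n_perm permutations per repeat.
#' @param seed run-level seed (substreams per repeat).
#' @param stratified stratify splits by class (default TRUE).
#' @return an `eval_result`.
#' @export
repeated_split_eval <- function(predictor, labels, subject_ids,
                                train_fraction = 0.75, n_repeats = 25,
                                n_perm = 199, seed = 1L, stratified = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_repeats >= 1)
  per <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(derive_seed(seed, paste0("split", r)))
    tr <- if (stratified) stratified_split(labels, train_fraction)
          else {
            x <- logical(length(labels))
            x[sample(length(labels), round(train_fraction * length(labels)))] <- TRUE
            if (length(unique(labels[!x])) < 2 || length(unique(labels[x])) < 2)
              stratified_split(labels, train_fraction) else x
          }
    ps <- predictor(subject_ids[tr], subject_ids[!tr],
                    derive_seed(seed, paste0("predict", r)))
    y_test <- labels[match(ps$subject_id, subject_ids)]
    pt <- permutation_pvalue(ps$score, y_test, n_perm,
                             derive_seed(seed, paste0("perm", r)))
    per[[r]] <- data.frame(repeat_index = r, auc = pt$auc_obs,
                           ch_auc = convex_hull_auc(ps$score, y_test),
                           p = pt$p_value)
  }
  new_eval_result(do.call(rbind, per),
                  sprintf("%d/%d split", round(train_fraction * 100),
                          round((1 - train_fraction) * 100)),
                  n_perm)
}

#' Leave-one-out evaluation of GRM-based prediction
#'
#' Computes [loo_predict()] scores for every subject and evaluates the full
#' score vector with AUC, convex-hull AUC and the label-permutation test.
#'
#' @param K full-cohort [kinship_matrix()].
#' @param labels complete 0/1 labels in kinship order.
#' @param method,ridge passed to [loo_predict()].
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return an `eval_result` (single "repeat"); the scores are attached as
#'   attribute `"scores"`.
#' @export
loo_eval <- function(K, labels, method = "gblup", ridge = NULL,
                     n_perm = 999, seed = 1L) {
  ps <- loo_predict(K, labels, method = method, ridge = ridge)
  pt <- permutation_pvalue(ps$score, labels, n_perm, derive_seed(seed, "looperm"))
  res <- new_eval_result(data.frame(repeat_index = 1, auc = pt$auc_obs,
                                    ch_auc = convex_hull_auc(ps$score, labels),
                                    p = pt$p_value),
                         "leave-one-out", n_perm)
  attr(res, "scores") <- ps
  res
}
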