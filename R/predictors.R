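#' Whole-genome prediction scores
#'
#' All predictors return a `prediction_scores` data frame: one row per test
#' subject with columns `subject_id`, `score` (higher = predicted case or
#' higher trait value) and `method`.

new_prediction_scores <- function(subject_id, score, method, fold = NA) {
  if (any(!is.finite(score))) stop_wgp("non-finite prediction score")
  data.frame(subject_id = subject_id, score = score, method = method,
             fold = fold, stringsAsFactors = FALSE)
}

.kin_values <- function(K) if (inherits(K, "kinship_matrix")) K$values else as.matrix(K)

.check_split <- function(K, train_ids, test_ids) {
  v <- .kin_values(K)
  ids <- rownames(v)
  if (length(train_ids) == 0 || length(test_ids) == 0)
    stop_wgp("empty training or test set")
  if (length(intersect(train_ids, test_ids)) > 0)
    stop_wgp("train and test sets overlap")
  if (!all(c(train_ids, test_ids) %in% ids))
    stop_wgp("train/test ids missing from the kinship matrix")
  v
}

#' G-BLUP / kernel-ridge prediction from a kinship matrix
#'
#' Removes the training intercept (estimated by generalized least squares
#' under `V = K_tt + ridge * I`, so that the solution coincides exactly with
#' Henderson's mixed-model equations), solves
#' `(K_tt + ridge * I) alpha = y_train - mu` on the training block and
#' scores test subjects as `K_xt alpha + mu`.  With
#' `ridge = sigma2_e / sigma2_g` this is the genomic best linear unbiased
#' predictor; it is also the kriging predictor on the genomic similarity
#' kernel.  As `ridge` grows the GLS intercept tends to the plain training
#' mean and all scores shrink toward it.
#'
#' @param K a [kinship_matrix()] over all subjects.
#' @param y_train numeric labels (0/1) or traits for the training subjects,
#'   in `train_ids` order.
#' @param train_ids,test_ids disjoint subject id vectors within `K`.
#' @param ridge positive regularizer; `NULL` fits [greml()] on the training
#'   block and uses `sigma2_e / sigma2_g` (falling back to 1, i.e. an assumed
#'   h2 of 0.5, if the genetic component is at the boundary).
#' @return a `prediction_scores` data frame.
#' @export
gblup_predict <- function(K, y_train, train_ids, test_ids, ridge = NULL) {
  v <- .check_split(K, train_ids, test_ids)
  if (length(y_train) != length(train_ids))
    stop_wgp("y_train must match train_ids")
  Ktt <- v[train_ids, train_ids, drop = FALSE]
  if (is.null(ridge)) ridge <- .reml_ridge(Ktt, y_train)
  if (!is.finite(ridge) || ridge <= 0) stop_wgp("ridge must be positive")
  nt <- length(train_ids)
  M <- Ktt + diag(ridge, nt)
  Mi <- tryCatch(cbind(solve(M, y_train), solve(M, rep(1, nt))),
                 error = function(e) stop_wgp("singular kinship system"))
  mu <- sum(Mi[, 1]) / sum(Mi[, 2])        # GLS intercept
  alpha <- Mi[, 1] - mu * Mi[, 2]
  sc <- drop(v[test_ids, train_ids, drop = FALSE] %*% alpha) + mu
  new_prediction_scores(test_ids, sc, "gblup")
}

.reml_ridge <- function(Ktt, y_train) {
  fit <- tryCatch(greml(y_train, Ktt), error = function(e) NULL)
  if (is.null(fit) || fit$boundary || fit$sigma2_g <= 0) return(1)
  fit$sigma2_e / fit$sigma2_g
}

#' Simple kriging prediction: similarity-weighted sum of labels
#'
#' Scores a test subject as the weighted sum of centered training labels
#' with weights proportional to kinship, normalized by the sum of absolute
#' weights, over the `k_neighbors` most similar training subjects
#' (default all).
#'
#' @inheritParams gblup_predict
#' @param k_neighbors number of nearest training subjects, or `Inf` for all.
#' @export
kriging_simple_predict <- function(K, y_train, train_ids, test_ids,
                                   k_neighbors = Inf) {
  v <- .check_split(K, train_ids, test_ids)
  if (length(y_train) != length(train_ids))
    stop_wgp("y_train must match train_ids")
  ybar <- mean(y_train)
  yc <- y_train - ybar
  k <- min(k_neighbors, length(train_ids))
  sc <- vapply(test_ids, function(x) {
    kx <- v[x, train_ids]
    use <- order(kx, decreasing = TRUE)[seq_len(k)]
    w <- kx[use]
    denom <- sum(abs(w))
    if (denom == 0) return(ybar)
    sum(w * yc[use]) / denom + ybar
  }, numeric(1))
  new_prediction_scores(test_ids, sc, "kriging")
}

#' Leave-one-out whole-genome prediction
#'
#' Builds the GRM once on the full cohort, then holds out each subject in
#' turn and predicts it from the remaining n - 1.  For `method = "gblup"` an
#' exact closed-form identity (one full-cohort inverse plus per-subject
#' corrections, with per-fold training means) reproduces per-subject
#' refitting to machine precision.
#'
#' @param K full-cohort [kinship_matrix()].
#' @param y complete numeric labels/traits for all subjects in `K` order.
#' @param method `"gblup"` or `"kriging"`.
#' @param ridge regularizer for G-BLUP; `NULL` fits [greml()] once on the
#'   full cohort.
#' @param k_neighbors for `"kriging"`.
#' @return a `prediction_scores` data frame with one score per subject.
#' @export
loo_predict <- function(K, y, method = c("gblup", "kriging"), ridge = NULL,
                        k_neighbors = Inf) {
  method <- match.arg(method)
  v <- .kin_values(K)
  n <- length(y)
  if (n < 3) stop_wgp("leave-one-out requires at least 3 subjects")
  if (nrow(v) != n) stop_wgp("kinship matrix does not match phenotype length")
  ids <- rownames(v)
  if (method == "kriging") {
    sc <- vapply(seq_len(n), function(j) {
      kriging_simple_predict(K, y[-j], ids[-j], ids[j], k_neighbors)$score
    }, numeric(1))
    return(new_prediction_scores(ids, sc, "kriging", fold = "loo"))
  }
  if (is.null(ridge)) ridge <- .reml_ridge(v, y)
  if (!is.finite(ridge) || ridge <= 0) stop_wgp("ridge must be positive")
  # Exact leave-one-out via block-inverse identities on B = (K + ridge I)^-1:
  # for any vector v, the held-out-j system satisfies
  #   K_{j,-j} (K+rI)_{-j,-j}^{-1} v_{-j} = v_j - (Bv)_j / B_jj
  #   u_{-j}' (K+rI)_{-j,-j}^{-1} v_{-j} = S(u, v; j)  (Schur correction),
  # which gives the per-fold GLS intercept mu_j without refitting.
  B <- solve(v + diag(ridge, n))
  By <- drop(B %*% y)
  B1 <- drop(rowSums(B))
  dB <- diag(B)
  s11 <- sum(B1); s1y <- sum(By)
  a_j <- s11 - 2 * B1 + dB - (B1 - dB)^2 / dB
  b_j <- s1y - By - B1 * y + y * dB - (B1 - dB) * (By - dB * y) / dB
  mu_j <- b_j / a_j
  pred_y <- y - By / dB
  pred_1 <- 1 - B1 / dB
  sc <- pred_y - mu_j * pred_1 + mu_j
  new_prediction_scores(ids, sc, "gblup", fold = "loo")
}

#' G-BLUP prediction with covariate similarity integrated into the kernel
#'
#' Combines the genetic kinship with a covariate-similarity matrix by a
#' convex combination and runs [gblup_predict()] on the combined kernel.
#'
#' @param K_g genetic [kinship_matrix()].
#' @param covariates complete data frame of covariates for all subjects (in
#'   kinship order; a `subject_id` column is honoured).
#' @param y_train,train_ids,test_ids,ridge as in [gblup_predict()].
#' @param mixing length-2 non-negative weights (genetics, covariates)
#'   summing to 1; default equal weights.
#' @export
predict_with_covariates <- function(K_g, covariates, y_train, train_ids,
                                    test_ids, mixing = c(0.5, 0.5),
                                    ridge = NULL) {
  K_c <- covariate_similarity(covariates)
  if (!identical(K_c$subject_ids, K_g$subject_ids)) {
    if (!all(K_g$subject_ids %in% K_c$subject_ids))
      stop_wgp("covariates missing for some subjects")
    K_c$values <- K_c$values[K_g$subject_ids, K_g$subject_ids]
    K_c$subject_ids <- K_g$subject_ids
  }
  Kc <- combine_similarity(list(K_g, K_c), mixing)
  out <- gblup_predict(Kc, y_train, train_ids, test_ids, ridge = ridge)
  out$method <- "gblup+covariates"
  out
}

#' Naive-Bayes whole-genome classifier
#'
#' Per-SNP class-conditional genotype frequencies over the three genotype
#' categories with add-one (Laplace) smoothing; the score is the posterior
#' log-odds summed over SNPs plus the prior log-odds.  Fractional (imputed)
#' dosages are rounded to the nearest genotype.
#'
#' @param g_train [genotype_matrix()] of training subjects.
#' @param labels binary 0/1 training labels.
#' @return an object of class `"wgp_naive_bayes"` with a `predict` method
#'   taking a test [genotype_matrix()].
#' @export
naive_bayes_wgp <- function(g_train, labels) {
  if (length(unique(labels)) < 2) stop_wgp("training labels are single-class")
  d <- round(g_train$dosages)
  tab <- function(x, cls) {
    cnt <- vapply(0:2, function(v) sum(x[cls] == v), numeric(1))
    (cnt + 1) / (sum(cnt) + 3)
  }
  case <- labels == 1
  p1 <- apply(d, 2, tab, cls = case)
  p0 <- apply(d, 2, tab, cls = !case)
  structure(list(log_ratio = log(p1) - log(p0),   # 3 x m
                 prior_logodds = log(mean(case) / (1 - mean(case))),
                 snp_ids = g_train$snps$snp_id),
            class = "wgp_naive_bayes")
}

#' @rdname naive_bayes_wgp
#' @param object fitted model.
#' @param g_test test genotypes.
#' @param ... unused.
#' @export
predict.wgp_naive_bayes <- function(object, g_test, ...) {
  d <- round(g_test$dosages)
  if (!identical(colnames(d), object$snp_ids))
    d <- d[, object$snp_ids, drop = FALSE]
  m <- ncol(d)
  sc <- vapply(seq_len(nrow(d)), function(i) {
    sum(object$log_ratio[cbind(d[i, ] + 1, seq_len(m))])
  }, numeric(1)) + object$prior_logodds
  new_prediction_scores(g_test$subject_ids, sc, "naive_bayes")
}

#' LASSO-penalized logistic whole-genome classifier
#'
#' L1-penalized logistic regression (glmnet) with the penalty chosen by
#' internal cross-validation on the training data only; selection and
#' weighting both happen inside the training set.
#'
#' @param g_train training [genotype_matrix()].
#' @param labels binary 0/1 labels.
#' @param seed integer seed for the internal fold assignment.
#' @param nfolds internal CV folds.
#' @return class `"wgp_lasso"` with a `predict` method.
#' @export
lasso_wgp <- function(g_train, labels, seed = 1L, nfolds = 5) {
  if (length(unique(labels)) < 2) stop_wgp("training labels are single-class")
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(nfolds), length(labels)))
  cv <- glmnet::cv.glmnet(g_train$dosages, labels, family = "binomial",
                          alpha = 1, foldid = foldid)
  structure(list(cv = cv, snp_ids = g_train$snps$snp_id),
            class = "wgp_lasso")
}

#' @rdname lasso_wgp
#' @param object fitted model.
#' @param g_test test genotypes.
#' @param s penalty at which to predict (default the CV-selected
#'   `"lambda.min"`).
#' @param ... unused.
#' @export
predict.wgp_lasso <- function(object, g_test, s = "lambda.min", ...) {
  sc <- drop(stats::predict(object$cv, newx = g_test$dosages,
                            s = s, type = "link"))
  new_prediction_scores(g_test$subject_ids, sc, "lasso")
}

#' Linear-kernel support vector machine classifier
#'
#' Maximum-margin classifier on standardized dosages with a linear kernel
#' (e1071); the decision-function value is the score.
#'
#' @param g_train training [genotype_matrix()].
#' @param labels binary 0/1 labels.
#' @param cost soft-margin cost parameter.
#' @return class `"wgp_svm"` with a `predict` method.
#' @export
svm_wgp <- function(g_train, labels, cost = 1) {
  if (length(unique(labels)) < 2) stop_wgp("training labels are single-class")
  mu <- colMeans(g_train$dosages)
  sdv <- apply(g_train$dosages, 2, stats::sd)
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(g_train$dosages, 2, mu), 2, sdv, `/`)
  fit <- e1071::svm(z, factor(labels, levels = c(0, 1)), kernel = "linear",
                    cost = cost, scale = FALSE)
  structure(list(fit = fit, mu = mu, sd = sdv, snp_ids = g_train$snps$snp_id),
            class = "wgp_svm")
}

#' @rdname svm_wgp
#' @param object fitted model.
#' @param g_test test genotypes.
#' @param ... unused.
#' @export
predict.wgp_svm <- function(object, g_test, ...) {
  z <- sweep(sweep(g_test$dosages, 2, object$mu), 2, object$sd, `/`)
  pr <- stats::predict(object$fit, z, decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  # orient so that higher score = class "1"
  if (grepl("^0/", colnames(attr(pr, "decision.values"))[1])) dv <- -dv
  new_prediction_scores(g_test$subject_ids, dv, "svm")
}
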