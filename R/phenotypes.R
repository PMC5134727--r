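#' Bronchodilator response
#'
#' `(post - pre) / pre` from pre- and post-bronchodilator FEV1.
#'
#' @param pre,post pre- and post-bronchodilator FEV1 (same units; raw volume
#'   or percent-predicted).
#' @return BDR as a proportion.
#' @export
compute_bdr <- function(pre, post) {
  if (any(pre <= 0, na.rm = TRUE)) stop_wgp("pre-bronchodilator FEV1 must be > 0")
  (post - pre) / pre
}

#' Dichotomize a continuous trait about its mean
#'
#' @param values numeric vector with at least two distinct values (NAs are
#'   ignored for the mean and propagate to labels).
#' @return list with `labels` (1 iff value > mean) and `threshold`.
#' @export
dichotomize_about_mean <- function(values) {
  if (length(unique(values[!is.na(values)])) < 2)
    stop_wgp("cannot dichotomize a constant vector")
  thr <- mean(values, na.rm = TRUE)
  list(labels = as.integer(values > thr), threshold = thr)
}

#' Mean-impute a phenotype/covariate table
#'
#' Numeric columns are imputed with the column mean (biasing toward the
#' null); categorical columns with the mode.
#'
#' @param table data frame; `subject_id` is left untouched.
#' @return imputed data frame.
#' @export
mean_impute_table <- function(table) {
  for (nm in setdiff(names(table), "subject_id")) {
    x <- table[[nm]]
    if (!anyNA(x)) next
    if (all(is.na(x))) stop_wgp("column entirely missing: ", nm)
    if (is.numeric(x)) {
      x[is.na(x)] <- mean(x, na.rm = TRUE)
    } else {
      tb <- table(x)
      x[is.na(x)] <- names(tb)[which.max(tb)]
    }
    table[[nm]] <- x
  }
  table
}

#' Percentile rank of percent-predicted FEV1
#'
#' Percentile position against the package's internal synthetic reference
#' population (percent-predicted FEV1 ~ Normal(100, 13)); used only for the
#' relative above/below-25th-percentile call, not as published reference
#' equations.
#'
#' @param fev1_pct_pred numeric percent-predicted values.
#' @param ref_mean,ref_sd reference mean and SD.
#' @return percentile ranks in (0, 1).
#' @export
fev1_percentile <- function(fev1_pct_pred, ref_mean = 100, ref_sd = 13) {
  stats::pnorm((fev1_pct_pred - ref_mean) / ref_sd)
}

#' Classify a longitudinal lung-function growth pattern
#'
#' Base pattern: normal growth (NG) when strictly more than `ng_fraction` of
#' observations sit above the 25th percentile of FEV1 for the reference,
#' reduced growth (RG) otherwise.  Early decline (ED): subjects at least
#' `min_final_age` years old at the end of follow-up whose smoothed series
#' shows a premature reduction from the peak FEV1 — a relative drop
#' `(peak - final)/peak >= decline_threshold` with the peak attained before
#' the final observation.  Series with fewer than 4 observations are
#' unclassifiable (status, not an error).
#'
#' @param trajectory data frame for one subject with `age`, `fev1_pct_pred`
#'   and optionally `percentile_rank` (computed via [fev1_percentile()] if
#'   absent); ages must be strictly increasing.
#' @param min_final_age ED eligibility age (default 23).
#' @param decline_threshold relative drop from peak defining ED (default
#'   0.05).
#' @param ng_fraction fraction of observations above the 25th percentile
#'   required for NG (default 0.5, i.e. majority rule).
#' @param smooth apply a rolling-median smoother before peak/decline
#'   computation (default TRUE).
#' @return list with `base` ("NG"/"RG"), `early_decline` (logical), `label`
#'   ("NG", "NG-ED", "RG", "RG-ED") or `label = "unclassified"`.
#' @export
classify_lung_pattern <- function(trajectory, min_final_age = 23,
                                  decline_threshold = 0.05,
                                  ng_fraction = 0.5, smooth = TRUE) {
  tr <- trajectory[order(trajectory$age), , drop = FALSE]
  if (any(diff(tr$age) <= 0)) stop_wgp("ages must be strictly increasing")
  if (nrow(tr) < 4)
    return(list(base = NA_character_, early_decline = NA,
                label = "unclassified"))
  pr <- tr$percentile_rank %||% fev1_percentile(tr$fev1_pct_pred)
  base <- if (mean(pr > 0.25) > ng_fraction) "NG" else "RG"
  v <- tr$fev1_pct_pred
  if (smooth && length(v) >= 3) v <- stats::runmed(v, k = 3)
  ed <- FALSE
  if (max(tr$age) >= min_final_age) {
    peak_i <- which.max(v)
    if (peak_i < length(v)) {
      drop_frac <- (v[peak_i] - v[length(v)]) / v[peak_i]
      ed <- drop_frac >= decline_threshold
    }
  }
  list(base = base, early_decline = ed,
       label = if (ed) paste0(base, "-ED") else base)
}

#' Classify every subject in a trajectory table
#'
#' @param trajectories data frame with `subject_id`, `age`, `fev1_pct_pred`
#'   (and optionally `percentile_rank`).
#' @param ... passed to [classify_lung_pattern()].
#' @return data frame: subject_id, base, early_decline, label.
#' @export
classify_lung_patterns <- function(trajectories, ...) {
  ids <- unique(trajectories$subject_id)
  out <- lapply(ids, function(s) {
    cl <- classify_lung_pattern(
      trajectories[trajectories$subject_id == s, , drop = FALSE], ...)
    data.frame(subject_id = s, base = cl$base,
               early_decline = cl$early_decline, label = cl$label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Composite lung-pattern indicators
#'
#' Expands per-subject pattern labels into the six analysis indicators:
#' the four mutually exclusive base patterns NG, NG-ED, RG, RG-ED, plus
#' ED-All (early decline with either growth pattern) and RG-All (reduced
#' growth with or without early decline).  Unclassified subjects get NA.
#'
#' @param labels data frame from [classify_lung_patterns()] (or a character
#'   vector of labels).
#' @return data frame of 0/1 indicator columns `NG`, `NG_ED`, `RG`, `RG_ED`,
#'   `ED_All`, `RG_All` plus `subject_id` when available.
#' @export
composite_patterns <- function(labels) {
  if (is.data.frame(labels)) {
    lab <- labels$label
    sid <- labels$subject_id
  } else {
    lab <- as.character(labels)
    sid <- NULL
  }
  cls <- ifelse(lab == "unclassified", NA_character_, lab)
  out <- data.frame(
    NG = as.integer(cls == "NG"),
    NG_ED = as.integer(cls == "NG-ED"),
    RG = as.integer(cls == "RG"),
    RG_ED = as.integer(cls == "RG-ED"),
    ED_All = as.integer(cls %in% c("NG-ED", "RG-ED")),
    RG_All = as.integer(cls %in% c("RG", "RG-ED")))
  out$ED_All[is.na(cls)] <- NA_integer_
  out$RG_All[is.na(cls)] <- NA_integer_
  if (!is.null(sid)) out <- cbind(data.frame(subject_id = sid), out)
  out
}
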