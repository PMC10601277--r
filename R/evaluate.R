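# Classifier evaluation: ROC/AUC via the rank statistic, confusion metrics,
# 0.632+ bootstrap estimates of misclassification error and AUC, and
# multivariable confounder-adjusted logistic models.

#' ROC curve and AUC
#'
#' The AUC is the tie-corrected Mann-Whitney statistic `U / (n1 * n2)`
#' (ties counted one half); ROC points are computed over all score
#' thresholds.
#'
#' @param scores Numeric classifier scores (higher = more positive-like).
#' @param labels Class labels; `positive` marks the positive class.
#' @param positive Positive class label (default `"CR"`).
#' @return A `meth_roc` list: `auc` and `points` (tibble of `threshold`,
#'   `tpr`, `fpr`).
#' @examples
#' roc_auc(c(0.9, 0.8, 0.4, 0.2), c("CR", "CR", "RD", "RD"))$auc  # 1
#' @export
roc_auc <- function(scores, labels, positive = "CR") {
  labels <- as.character(labels)
  pos <- labels == positive
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores) # average ranks handle ties (counted 1/2)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  points <- purrr::map_dfr(thr, function(t) {
    call_pos <- scores >= t
    tibble::tibble(threshold = t,
                   tpr = sum(call_pos & pos) / n1,
                   fpr = sum(call_pos & !pos) / n2)
  })
  structure(list(auc = auc, points = points, n_pos = n1, n_neg = n2),
            class = "meth_roc")
}

#' @export
print.meth_roc <- function(x, ...) {
  cat(sprintf("<meth_roc> AUC %.3f (%d positive / %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object A `meth_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.meth_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix metrics
#'
#' Counts and derived rates for binary calls; the positive class (default
#' `"CR"`, responder) defines sensitivity and PPV.
#'
#' @param calls Predicted class labels.
#' @param labels True class labels.
#' @param positive Positive class label.
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `misclassification`.
#' @export
confusion_metrics <- function(calls, labels, positive = "CR") {
  calls <- as.character(calls); labels <- as.character(labels)
  if (!length(calls) || length(calls) != length(labels)) {
    stop("`calls` and `labels` must be non-empty and aligned",
         call. = FALSE)
  }
  tp <- sum(calls == positive & labels == positive)
  fp <- sum(calls == positive & labels != positive)
  tn <- sum(calls != positive & labels != positive)
  fn <- sum(calls != positive & labels == positive)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = tp / (tp + fp),
    npv = tn / (tn + fn),
    misclassification = (fp + fn) / length(calls)
  )
}

#' Enumerate integer confusion matrices consistent with printed rates
#'
#' Searches all integer confusion matrices up to `max_total` samples whose
#' sensitivity, specificity, PPV and NPV round to the given printed
#' percentages at one-decimal precision (a half-unit tolerance of 0.05
#' percentage points). Useful for reconstructing the underlying counts
#' behind a published set of rates.
#'
#' @param sensitivity,specificity,ppv,npv Printed percentages.
#' @param max_total Maximum total sample count to search.
#' @param tol Matching tolerance in percentage points (default 0.05, i.e.
#'   agreement at one printed decimal).
#' @return Tibble of all consistent matrices with their exact rates and the
#'   majority-class (null model) misclassification.
#' @export
enumerate_confusion_matrices <- function(sensitivity, specificity, ppv, npv,
                                         max_total = 57, tol = 0.05) {
  res <- list()
  for (p_tot in 1:(max_total - 1)) {
    tp <- 0:p_tot
    sens_ok <- tp[abs(100 * tp / p_tot - sensitivity) <= tol]
    if (!length(sens_ok)) next
    for (n_tot in 1:(max_total - p_tot)) {
      tn <- 0:n_tot
      spec_ok <- tn[abs(100 * tn / n_tot - specificity) <= tol]
      if (!length(spec_ok)) next
      for (tp_i in sens_ok) for (tn_i in spec_ok) {
        fn_i <- p_tot - tp_i; fp_i <- n_tot - tn_i
        if (tp_i + fp_i == 0 || tn_i + fn_i == 0) next
        if (abs(100 * tp_i / (tp_i + fp_i) - ppv) > tol) next
        if (abs(100 * tn_i / (tn_i + fn_i) - npv) > tol) next
        res[[length(res) + 1]] <- tibble::tibble(
          tp = tp_i, fn = fn_i, fp = fp_i, tn = tn_i,
          total = p_tot + n_tot,
          sensitivity = 100 * tp_i / p_tot,
          specificity = 100 * tn_i / n_tot,
          ppv = 100 * tp_i / (tp_i + fp_i),
          npv = 100 * tn_i / (tn_i + fn_i),
          null_misclassification =
            min(p_tot, n_tot) / (p_tot + n_tot)
        )
      }
    }
  }
  dplyr::bind_rows(res)
}

#' 0.632+ bootstrap estimates of misclassification error and AUC
#'
#' Optimism-corrected performance estimation. The apparent error
#' `err_bar` comes from the model trained on all data; the leave-one-out
#' bootstrap error `err1` averages, per sample, that sample's error over
#' the bootstrap models for which it was out of bag, then averages over
#' samples. The no-information rate is
#' `gamma = p(1 - q) + (1 - p)q` with `p` the observed positive fraction
#' and `q` the predicted-positive fraction; the relative overfitting rate
#' `R = (err1' - err_bar) / (gamma - err_bar)` (with
#' `err1' = min(err1, gamma)`, clipped to `[0, 1]`) sets the weight
#' `w = 0.632 / (1 - 0.368 R)` and
#' `err632plus = (1 - w) err_bar + w err1'`. The AUC analog applies the
#' same blend to `1 - AUC` with no-information value 0.5, averaging
#' out-of-bag AUCs per replicate.
#'
#' @param x Samples-by-features data (matrix or tibble).
#' @param y Response labels (`"CR"`/`"RD"`).
#' @param trainer Function `(x, y) -> model`; the full training procedure,
#'   including any internal cross-validation, so selection optimism is
#'   re-estimated inside every resample.
#' @param predictor Function `(model, x) -> numeric scores/probabilities`
#'   (default wraps [predict_probability()]).
#' @param B Bootstrap replicates (default 1000, minimum 50).
#' @param seed Seed for the resampling.
#' @param threshold Probability threshold for class calls.
#' @param positive Positive class.
#'
#' @details Replicates with fewer than two in-bag samples of either class
#'   are redrawn (the redraw count is reported).
#'
#' @return A `boot632` list with `err_bar`, `err1`, `gamma`, `R`, `w`,
#'   `err632plus`, `auc_apparent`, `auc632`, replicate bookkeeping and the
#'   seed.
#' @export
bootstrap_632plus <- function(x, y, trainer, predictor = NULL, B = 1000,
                              seed = 1L, threshold = 0.5,
                              positive = "CR") {
  stopifnot(B >= 50)
  xm <- as_feature_matrix(x)
  y <- as.character(y)
  n <- length(y)
  stopifnot(nrow(xm) == n)
  if (is.null(predictor)) {
    predictor <- function(model, newx) {
      predict_probability(model, newx, threshold = threshold)$probability
    }
  }
  full <- trainer(xm, y)
  score_full <- predictor(full, xm)
  call_full <- ifelse(score_full >= threshold, positive,
                      setdiff(c("CR", "RD"), positive))
  err_bar <- mean(call_full != y)
  auc_app <- roc_auc(score_full, y, positive = positive)$auc

  p_hat <- mean(y == positive)
  q_hat <- mean(call_full == positive)
  gamma <- p_hat * (1 - q_hat) + (1 - p_hat) * q_hat

  err_sum <- numeric(n); err_cnt <- integer(n)
  oob_auc <- numeric(0)
  n_redraw <- 0L; n_auc_skip <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        # a fit needs at least two in-bag samples of each class
        idx <- sample.int(n, n, replace = TRUE)
        if (min(table(factor(y[idx], levels = unique(y)))) >= 2) break
        n_redraw <- n_redraw + 1L
      }
      oob <- setdiff(seq_len(n), unique(idx))
      if (!length(oob)) next
      model_b <- trainer(xm[idx, , drop = FALSE], y[idx])
      sc <- predictor(model_b, xm[oob, , drop = FALSE])
      cl <- ifelse(sc >= threshold, positive,
                   setdiff(c("CR", "RD"), positive))
      e <- as.numeric(cl != y[oob])
      err_sum[oob] <- err_sum[oob] + e
      err_cnt[oob] <- err_cnt[oob] + 1L
      if (length(unique(y[oob])) == 2) {
        oob_auc <- c(oob_auc, roc_auc(sc, y[oob], positive = positive)$auc)
      } else {
        n_auc_skip <- n_auc_skip + 1L
      }
    }
  })
  never_oob <- err_cnt == 0
  if (any(never_oob)) {
    warning(sum(never_oob), " sample(s) never out-of-bag across B = ", B,
            " replicates; increase B", call. = FALSE)
  }
  err1 <- mean(err_sum[!never_oob] / err_cnt[!never_oob])

  blend <- function(e_bar, e1, gam) {
    e1p <- min(e1, gam)
    r <- if (gam > e_bar && e1p > e_bar) {
      (e1p - e_bar) / (gam - e_bar)
    } else 0
    r <- min(max(r, 0), 1)
    w <- 0.632 / (1 - 0.368 * r)
    list(R = r, w = w, est = (1 - w) * e_bar + w * e1p, err1_prime = e1p)
  }
  bl <- blend(err_bar, err1, gamma)
  bl_auc <- blend(1 - auc_app, 1 - mean(oob_auc), 0.5)

  structure(
    list(err_bar = err_bar, err1 = err1, err1_prime = bl$err1_prime,
         gamma = gamma, R = bl$R, w = bl$w, err632plus = bl$est,
         auc_apparent = auc_app, auc1 = mean(oob_auc),
         auc632 = 1 - bl_auc$est, R_auc = bl_auc$R, w_auc = bl_auc$w,
         B = B, n = n, n_redraw = n_redraw, n_auc_skip = n_auc_skip,
         seed = seed),
    class = "boot632"
  )
}

#' @export
print.boot632 <- function(x, ...) {
  cat("<boot632>\n")
  cat(sprintf("  apparent error %.4f | err1 %.4f | gamma %.4f\n",
              x$err_bar, x$err1, x$gamma))
  cat(sprintf("  R %.3f  w %.3f  ->  0.632+ error %.4f\n",
              x$R, x$w, x$err632plus))
  cat(sprintf("  apparent AUC %.3f  ->  0.632+ AUC %.3f  (B = %d)\n",
              x$auc_apparent, x$auc632, x$B))
  invisible(x)
}

#' @export
tidy.boot632 <- function(x, ...) {
  tibble::tibble(
    statistic = c("err_bar", "err1", "err1_prime", "gamma", "R", "w",
                  "err632plus", "auc_apparent", "auc632"),
    value = c(x$err_bar, x$err1, x$err1_prime, x$gamma, x$R, x$w,
              x$err632plus, x$auc_apparent, x$auc632)
  )
}

#' @export
glance.boot632 <- function(x, ...) {
  tibble::tibble(err632plus = x$err632plus, auc632 = x$auc632,
                 err_bar = x$err_bar, gamma = x$gamma, B = x$B, n = x$n)
}

#' Merge small karyotype groups
#'
#' Collapses karyotype classes with fewer than `min_n` samples into
#' `"other"`, the convention for sparse cytogenetic groups in small-cohort
#' multivariable models.
#'
#' @param karyotype Character vector of karyotype classes.
#' @param min_n Minimum group size kept separate (default 5).
#' @return Character vector with small groups merged.
#' @export
merge_karyotype <- function(karyotype, min_n = 5) {
  tab <- table(karyotype)
  small <- names(tab)[tab < min_n]
  ifelse(karyotype %in% small, "other", karyotype)
}

#' Multivariable logistic model of response on signature and confounders
#'
#' Maximum-likelihood logistic regression of the response on the signature
#' score plus clinical covariates, with Wald 95% confidence intervals.
#' Perfect separation is flagged and a ridge-penalized fallback fit is
#' reported (without Wald intervals); aliased (collinear) covariates are
#' flagged rather than silently dropped.
#'
#' @param data Tibble containing the response and all covariates.
#' @param response Name of the response column (`"CR"`/`"RD"`; CR is
#'   modeled as the event).
#' @param signature Name of the signature-score column.
#' @param covariates Character vector of covariate column names.
#' @return Tibble `term`, `estimate`, `std_error`, `conf_low`,
#'   `conf_high`, `p_value`, with attributes `separation` and `aliased`.
#' @export
fit_confounder_model <- function(data, response = "response",
                                 signature = "signature_score",
                                 covariates = character(0)) {
  stopifnot(response %in% names(data), signature %in% names(data),
            all(covariates %in% names(data)))
  df <- as.data.frame(data)
  df$.y <- as.integer(df[[response]] == "CR")
  rhs <- paste(c(signature, covariates), collapse = " + ")
  fml <- stats::as.formula(paste(".y ~", rhs))
  n_coef_est <- length(c(signature, covariates)) + 1
  if (nrow(df) < 10 * n_coef_est) {
    warning("fewer than 10 samples per coefficient; estimates may be ",
            "unstable", call. = FALSE)
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = df, family = stats::binomial()),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg)) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
      if (grepl("algorithm did not converge", msg)) {
        separation <<- TRUE  # non-convergence accompanies separation
        invokeRestart("muffleWarning")
      }
    }
  )
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased)) {
    warning("aliased (collinear) term(s): ",
            paste(aliased, collapse = ", "), call. = FALSE)
  }
  if (separation) {
    warning("perfect separation detected; reporting a ridge-penalized ",
            "fallback without Wald intervals", call. = FALSE)
    mm <- stats::model.matrix(fml, df)[, -1, drop = FALSE]
    if (ncol(mm) < 2) mm <- cbind(mm, `.pad` = 0) # glmnet needs >= 2 cols
    rf <- glmnet::glmnet(mm, df$.y, family = "binomial", alpha = 0,
                         lambda = 1e-3)
    cf <- as.matrix(stats::coef(rf))
    cf <- cf[rownames(cf) != ".pad", , drop = FALSE]
    out <- tibble::tibble(term = rownames(cf), estimate = cf[, 1],
                          std_error = NA_real_, conf_low = NA_real_,
                          conf_high = NA_real_, p_value = NA_real_)
  } else {
    sm <- summary(fit)$coefficients
    out <- tibble::tibble(
      term = rownames(sm),
      estimate = sm[, "Estimate"],
      std_error = sm[, "Std. Error"],
      conf_low = sm[, "Estimate"] - 1.96 * sm[, "Std. Error"],
      conf_high = sm[, "Estimate"] + 1.96 * sm[, "Std. Error"],
      p_value = sm[, "Pr(>|z|)"]
    )
  }
  attr(out, "separation") <- separation
  attr(out, "aliased") <- aliased
  out
}

#' Plot the components of a 0.632+ bootstrap report
#'
#' Shows the apparent error, the leave-one-out bootstrap error, the
#' no-information rate and the 0.632+ blend side by side, with the AUC
#' analogs.
#'
#' @param object A `boot632`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.boot632 <- function(object, ...) {
  df <- tibble::tibble(
    statistic = factor(c("apparent", "bootstrap (err1')",
                         "no-information", "0.632+"),
                       levels = c("apparent", "bootstrap (err1')",
                                  "no-information", "0.632+")),
    error = c(object$err_bar, object$err1_prime, object$gamma,
              object$err632plus)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic, y = .data$error)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Misclassification error",
                  title = sprintf(
                    "0.632+ bootstrap (B = %d): error %.3f, AUC %.3f",
                    object$B, object$err632plus, object$auc632)) +
    ggplot2::theme_minimal()
}
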