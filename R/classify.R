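# Penalized-logistic signature training on M values or CpG-unit values,
# arm-specific Mann-Whitney unit refinement, and lasso recomposition.
# Fitting is delegated to glmnet; prediction uses the stored coefficients.

# small CV folds are routine for the cohort sizes handled here; glmnet's
# small-class advisory would otherwise flood bootstrap loops
quiet_glmnet <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fewer than 8", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    id_col <- intersect(c("sample_id"), names(x))
    m <- as.matrix(x[, setdiff(names(x), id_col), drop = FALSE])
    if (length(id_col)) rownames(m) <- x[[id_col]]
    m
  } else {
    as.matrix(x)
  }
}

#' Fit a penalized logistic methylation signature
#'
#' Elastic-net penalized logistic regression (`alpha` mixing L1 and L2;
#' `alpha = 1` is the lasso) with the penalty weight `lambda` chosen by
#' stratified k-fold cross-validation minimizing mean binomial deviance
#' over a log-spaced lambda path. Features are standardized internally;
#' coefficients are reported on the input scale. The positive (modeled)
#' class is `"CR"`: predictions are probabilities of complete response.
#'
#' @param x Samples-by-features matrix or tibble (optionally with a
#'   `sample_id` column) of M values or unit methylation values; no
#'   missing values allowed.
#' @param y Response labels, `"CR"`/`"RD"`, one per row of `x`.
#' @param alpha Elastic-net mixing parameter in `[0, 1]` (default 0.5).
#' @param nfolds Cross-validation folds (default 5).
#' @param seed Seed fixing the fold assignment (recorded in the model).
#' @param lambda Either `"cv"` (default: pick the deviance-minimizing
#'   lambda by cross-validation) or a fixed numeric value.
#' @return A `meth_signature` object: selected `features` (nonzero
#'   coefficients only), `coefficients`, `intercept`, `alpha`, `lambda`,
#'   `cv` results, `foldid`, `seed`, and training metadata.
#' @export
fit_penalized_logistic <- function(x, y, alpha = 0.5, nfolds = 5,
                                   seed = 1L, lambda = "cv") {
  xm <- as_feature_matrix(x)
  y <- as.character(y)
  stopifnot(length(y) == nrow(xm), all(y %in% c("CR", "RD")))
  if (anyNA(xm)) stop("feature matrix contains missing values",
                      call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("both response classes must be present", call. = FALSE)
  }
  const <- apply(xm, 2, function(col) stats::sd(col) == 0)
  if (any(const)) {
    warning("constant feature(s) forced to zero coefficient: ",
            paste(colnames(xm)[const], collapse = ", "), call. = FALSE)
  }
  yf <- factor(y, levels = c("RD", "CR")) # glmnet models the second level

  cv <- NULL
  foldid <- NULL
  # stratified CV needs at least 2 samples of each class per fold family;
  # shrink the fold count on very small resamples (e.g. inside bootstraps)
  k_folds <- min(nfolds, min(table(y)))
  if (identical(lambda, "cv") && k_folds < 3) lambda <- 0.05
  if (identical(lambda, "cv")) {
    foldid <- withr::with_seed(seed, {
      f <- integer(length(y))
      for (cls in c("RD", "CR")) {
        idx <- which(y == cls)
        f[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
      }
      f
    })
    cv <- quiet_glmnet(glmnet::cv.glmnet(xm, yf, family = "binomial",
                                         alpha = alpha, foldid = foldid,
                                         type.measure = "deviance",
                                         standardize = TRUE))
    lambda_use <- cv$lambda.min
    fit <- cv$glmnet.fit
    cf <- as.matrix(stats::coef(fit, s = lambda_use, exact = FALSE))
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0)
    lambda_use <- lambda
    fit <- quiet_glmnet(glmnet::glmnet(xm, yf, family = "binomial",
                                       alpha = alpha, standardize = TRUE))
    # refit exactly at the requested penalty rather than interpolating
    cf <- as.matrix(quiet_glmnet(
      stats::coef(fit, s = lambda_use, exact = TRUE,
                  x = xm, y = yf, family = "binomial",
                  alpha = alpha, standardize = TRUE)))
  }
  intercept <- cf[1, 1]
  beta <- cf[-1, 1]
  nz <- beta != 0
  structure(
    list(
      features = names(beta)[nz],
      coefficients = beta[nz],
      intercept = intercept,
      alpha = alpha,
      lambda = lambda_use,
      nfolds = nfolds,
      foldid = foldid,
      cv = if (!is.null(cv)) {
        tibble::tibble(lambda = cv$lambda, deviance = cv$cvm,
                       deviance_se = cv$cvsd, nonzero = cv$nzero)
      },
      seed = seed,
      positive_class = "CR",
      n_train = nrow(xm),
      feature_universe = colnames(xm)
    ),
    class = "meth_signature"
  )
}

#' @export
print.meth_signature <- function(x, ...) {
  cat("<meth_signature>\n")
  cat(sprintf("  %d feature(s), alpha %.2f, lambda %.4g, trained on %d samples\n",
              length(x$features), x$alpha, x$lambda, x$n_train))
  cat("  positive class:", x$positive_class, "\n")
  invisible(x)
}

#' Predict response probabilities from a signature
#'
#' `p = plogis(intercept + X beta)` over the stored nonzero coefficients;
#' the probability refers to the positive class (`"CR"`).
#'
#' @param model A `meth_signature`.
#' @param x New samples-by-features data containing every model feature
#'   column (a missing feature column is an error naming it).
#' @param threshold Class-call threshold on the probability (default 0.5).
#' @return Tibble with `sample_id` (when available), `probability` and
#'   `call`.
#' @export
predict_probability <- function(model, x, threshold = 0.5) {
  stopifnot(inherits(model, "meth_signature"))
  xm <- as_feature_matrix(x)
  missing_feat <- setdiff(model$features, colnames(xm))
  if (length(missing_feat)) {
    stop("missing feature column(s): ",
         paste(missing_feat, collapse = ", "), call. = FALSE)
  }
  eta <- model$intercept +
    if (length(model$features)) {
      drop(xm[, model$features, drop = FALSE] %*% model$coefficients)
    } else 0
  p <- stats::plogis(eta)
  tibble::tibble(
    sample_id = rownames(xm) %||% sprintf("sample_%d", seq_len(nrow(xm))),
    probability = unname(p),
    call = ifelse(p >= threshold, "CR", "RD")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Arm-specific Mann-Whitney CpG-unit selection
#'
#' Tests every unit for a CR vs RD methylation difference separately within
#' each treatment arm (two-sided Mann-Whitney; exact for small tie-free
#' groups, normal approximation with tie correction otherwise). Retained
#' units are significant in the EXP arm (`p < alpha_level`) without being
#' significant in the STD arm, removing candidates that reflect
#' arm-unspecific chemotherapy effects.
#'
#' @param values Wide unit tibble (`unit_id` x samples), no missing values
#'   (run [process_unit_matrix()] first).
#' @param labels,arms Per-sample response labels and arm assignments
#'   aligned with the sample columns.
#' @param alpha_level Significance level (default 0.05, unadjusted).
#' @return A `unit_selection` tibble: `unit_id`, `p_exp`, `p_std`,
#'   `sig_exp`, `sig_std`, `retained`.
#' @export
select_refinement_units <- function(values, labels, arms,
                                    alpha_level = 0.05) {
  v <- as.matrix(values[, setdiff(names(values), "unit_id"), drop = FALSE])
  labels <- as.character(labels); arms <- as.character(arms)
  stopifnot(length(labels) == ncol(v), length(arms) == ncol(v))
  if (anyNA(v)) stop("unit matrix contains missing values; run ",
                     "process_unit_matrix() first", call. = FALSE)
  for (a in c("EXP", "STD")) {
    cells <- table(labels[arms == a])
    if (length(cells) < 2 || min(cells) < 2) {
      stop("arm ", a, " needs at least 2 samples per response class",
           call. = FALSE)
    }
  }
  arm_p <- function(a) {
    idx <- arms == a
    apply(v[, idx, drop = FALSE], 1, function(row) {
      mw_test(row[labels[idx] == "CR"], row[labels[idx] == "RD"])
    })
  }
  p_exp <- arm_p("EXP")
  p_std <- arm_p("STD")
  out <- tibble::tibble(
    unit_id = values$unit_id,
    p_exp = p_exp, p_std = p_std,
    sig_exp = p_exp < alpha_level,
    sig_std = p_std < alpha_level,
    retained = p_exp < alpha_level & p_std >= alpha_level
  )
  class(out) <- c("unit_selection", class(out))
  out
}

#' Recompose the signature on retained CpG units
#'
#' Lasso (`alpha = 1`) logistic fit on the retained units' methylation
#' values with cross-validated lambda selection; reports the selected units
#' and, when a unit manifest with `n_cpgs` is given, the total number of
#' member CpGs in the recomposed signature.
#'
#' @param values Wide unit tibble restricted to retained units.
#' @param y Response labels for the sample columns.
#' @param unit_manifest Optional tibble with `unit_id`, `n_cpgs`.
#' @param seed,nfolds,lambda Passed to [fit_penalized_logistic()].
#' @return A `meth_signature`; `$n_cpgs` holds the member-CpG total and
#'   `$degenerate` flags an empty signature.
#' @export
recompose_signature <- function(values, y, unit_manifest = NULL,
                                seed = 1L, nfolds = 5, lambda = "cv") {
  if (nrow(values) < 1) {
    stop("no retained units to recompose from; the refinement selection ",
         "is empty", call. = FALSE)
  }
  x <- t(as.matrix(values[, setdiff(names(values), "unit_id"),
                          drop = FALSE]))
  colnames(x) <- values$unit_id
  model <- fit_penalized_logistic(x, y, alpha = 1, nfolds = nfolds,
                                  seed = seed, lambda = lambda)
  model$degenerate <- length(model$features) == 0
  if (model$degenerate) {
    warning("recomposed signature is empty (full shrinkage)",
            call. = FALSE)
  }
  if (!is.null(unit_manifest)) {
    model$n_cpgs <- sum(unit_manifest$n_cpgs[
      match(model$features, unit_manifest$unit_id)])
  }
  model
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted methylation signature
#'
#' @param x A `meth_signature`.
#' @param ... Unused.
#' @return Tibble with one row per term (intercept first): `term`,
#'   `estimate`.
#' @export
tidy.meth_signature <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$features),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' One-row summary of a fitted methylation signature
#'
#' @param x A `meth_signature`.
#' @param ... Unused.
#' @return One-row tibble: feature count, member-CpG count (if known),
#'   alpha, lambda, minimum CV deviance, training size and seed.
#' @export
glance.meth_signature <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$features),
    n_cpgs = x$n_cpgs %||% NA_integer_,
    alpha = x$alpha,
    lambda = x$lambda,
    cv_deviance = if (!is.null(x$cv)) min(x$cv$deviance) else NA_real_,
    n_train = x$n_train,
    seed = x$seed
  )
}
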