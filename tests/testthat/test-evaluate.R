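# ROC/AUC against a pair-counting oracle, confusion metrics and the
# printed-rate reconstruction, 0.632+ bootstrap algebra and behavior, and
# the multivariable confounder model against an IRLS oracle.

auc_pair_oracle <- function(scores, labels, positive = "CR") {
  # O(n^2) concordant-pair count with ties worth 1/2
  pos <- which(labels == positive); neg <- which(labels != positive)
  s <- 0
  for (i in pos) for (j in neg) {
    s <- s + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  s / (length(pos) * length(neg))
}

test_that("AUC worked examples and tie convention", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.2),
                       c("CR", "CR", "RD", "RD"))$auc, 1)
  expect_equal(roc_auc(rep(0.3, 6), rep(c("CR", "RD"), 3))$auc, 0.5)
  expect_error(roc_auc(1:3, rep("CR", 3)), "both classes")
})

test_that("AUC equals the brute-force pair-counting oracle", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    scores <- sample(round(rnorm(n), 1))  # rounded: ties occur
    labels <- sample(c("CR", "RD"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("CR", "RD")
    expect_equal(roc_auc(scores, labels)$auc,
                 auc_pair_oracle(scores, labels))
  }
})

test_that("AUC times n1*n2 equals the tie-corrected U statistic", {
  set.seed(22)
  for (i in 1:10) {
    scores <- sample(round(rnorm(15), 1))
    labels <- sample(rep(c("CR", "RD"), c(7, 8)))
    u <- stats::wilcox.test(scores[labels == "CR"],
                            scores[labels == "RD"],
                            exact = FALSE)$statistic
    expect_equal(roc_auc(scores, labels)$auc * 7 * 8, unname(u))
  }
})

test_that("ROC points step from (0,0) to (1,1) and autoplot works", {
  r <- roc_auc(c(0.9, 0.7, 0.7, 0.2, 0.1), c("CR", "CR", "RD", "RD", "RD"))
  expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(utils::tail(r$points$tpr, 1), 1)
  expect_equal(utils::tail(r$points$fpr, 1), 1)
  expect_s3_class(autoplot(r), "ggplot")
})

test_that("confusion metrics reproduce the derived integer matrix", {
  # the unique integer matrix consistent with printed rates 93.3 / 42.9 /
  # 70.0 / 81.8 (verified by enumeration below)
  labels <- c(rep("CR", 30), rep("RD", 21))
  calls <- c(rep("CR", 28), rep("RD", 2), rep("CR", 12), rep("RD", 9))
  cm <- confusion_metrics(calls, labels)
  expect_equal(cm$tp, 28); expect_equal(cm$fn, 2)
  expect_equal(cm$fp, 12); expect_equal(cm$tn, 9)
  expect_equal(round(100 * cm$sensitivity, 1), 93.3)
  expect_equal(round(100 * cm$specificity, 1), 42.9)
  expect_equal(round(100 * cm$ppv, 1), 70.0)
  expect_equal(round(100 * cm$npv, 1), 81.8)
  expect_equal(cm$misclassification, 14 / 51)

  perfect <- confusion_metrics(labels, labels)
  expect_equal(perfect$misclassification, 0)
  expect_equal(perfect$sensitivity, 1)
  all_pos <- confusion_metrics(rep("CR", 51), labels)
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
  expect_error(confusion_metrics(character(0), character(0)), "non-empty")
})

test_that("printed-rate enumeration has a unique solution", {
  hits <- enumerate_confusion_matrices(93.3, 42.85, 70, 81.8,
                                       max_total = 57)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$tp, 28)
  expect_equal(hits$fn, 2)
  expect_equal(hits$fp, 12)
  expect_equal(hits$tn, 9)
  expect_equal(hits$total, 51)
  # positives are a multiple of 15, negatives a multiple of 7
  expect_equal((hits$tp + hits$fn) %% 15, 0)
  expect_equal((hits$fp + hits$tn) %% 7, 0)
  # majority-class misclassification rounds to 41%
  expect_equal(round(100 * hits$null_misclassification), 41)
})

# deterministic stub learners for the bootstrap algebra
fixed_score_trainer <- function(x, y) structure(list(), class = "stub")
fixed_score_predictor <- function(model, x) as.numeric(x[, 1])

# feature sign encodes the true class, so "unseen means wrong" is exact:
# perfect recall on memorized samples, guaranteed-wrong on the rest
memorizer_trainer <- function(x, y) list(key = x[, 1], y = y)
memorizer_predictor <- function(model, x) {
  vapply(x[, 1], function(k) {
    hit <- match(k, model$key)
    if (!is.na(hit)) as.numeric(model$y[hit] == "CR")
    else as.numeric(k < 0)
  }, numeric(1))
}

test_that("0.632+ algebra: err1 equal to err_bar gives w = 0.632", {
  set.seed(23)
  n <- 30
  x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "f"))
  y <- ifelse(x[, 1] > 0, "CR", "RD")
  y[1:4] <- rev(y[1:4])  # a few fixed errors
  b <- bootstrap_632plus(x, y, fixed_score_trainer, fixed_score_predictor,
                         B = 60, seed = 1)
  # the prediction rule is constant, so every OOB error equals the
  # apparent error sample-wise
  expect_equal(b$err1, b$err_bar)
  expect_equal(b$R, 0)
  expect_equal(b$w, 0.632)
  expect_equal(b$err632plus, b$err_bar)
})

test_that("0.632+ algebra: total overfit drives w to 1 and the estimate to gamma", {
  set.seed(24)
  n <- 24
  y <- sample(rep(c("CR", "RD"), n / 2))
  x <- matrix(seq_len(n) * ifelse(y == "CR", 1, -1), ncol = 1,
              dimnames = list(NULL, "f"))
  b <- bootstrap_632plus(x, y, memorizer_trainer, memorizer_predictor,
                         B = 80, seed = 2, threshold = 0.5)
  expect_equal(b$err_bar, 0)
  expect_gte(b$err1, b$gamma)  # unseen samples are predicted wrongly
  expect_equal(b$R, 1)
  expect_equal(b$w, 1)
  expect_equal(b$err632plus, b$err1_prime)
  expect_equal(b$err632plus, min(b$err1, b$gamma))
})

test_that("0.632+ bounds hold for a real trainer on noisy data", {
  set.seed(25)
  n <- 40
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- ifelse(x[, 1] + rnorm(n) > 0, "CR", "RD")
  trainer <- function(x, y) fit_penalized_logistic(x, y, alpha = 1,
                                                   lambda = 0.05)
  b <- bootstrap_632plus(x, y, trainer, B = 60, seed = 3)
  expect_gte(b$w, 0.632); expect_lte(b$w, 1)
  expect_gte(b$R, 0); expect_lte(b$R, 1)
  expect_gte(b$err632plus, min(b$err_bar, b$err1_prime) - 1e-12)
  expect_lte(b$err632plus, max(b$err_bar, b$err1_prime) + 1e-12)
  expect_equal(tidy(b)$value[tidy(b)$statistic == "err632plus"],
               b$err632plus)
  expect_equal(glance(b)$B, 60)
})

irls_logistic <- function(x, y, tol = 1e-12, maxit = 100) {
  # independent hand-rolled Newton/IRLS oracle
  x1 <- cbind(1, x)
  beta <- numeric(ncol(x1))
  for (it in seq_len(maxit)) {
    eta <- drop(x1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    upd <- solve(t(x1) %*% (x1 * w), t(x1) %*% (y - mu))
    beta <- beta + upd
    if (max(abs(upd)) < tol) break
  }
  drop(beta)
}

test_that("confounder model matches the IRLS oracle and reports Wald CIs", {
  set.seed(26)
  n <- 120
  df <- tibble::tibble(
    signature_score = rnorm(n),
    age = rnorm(n, 60, 8),
    mut_DNMT3A = rbinom(n, 1, 0.2)
  )
  eta <- 1.2 * df$signature_score - 0.02 * (df$age - 60)
  df$response <- ifelse(runif(n) < plogis(eta), "CR", "RD")
  fit <- fit_confounder_model(df, covariates = c("age", "mut_DNMT3A"))
  oracle <- irls_logistic(as.matrix(df[, c("signature_score", "age",
                                           "mut_DNMT3A")]),
                          as.integer(df$response == "CR"))
  expect_equal(unname(fit$estimate), unname(oracle), tolerance = 1e-6)
  sig <- fit[fit$term == "signature_score", ]
  expect_gt(sig$conf_low, 0)  # planted effect: CI excludes zero
  expect_true(all(fit$conf_low < fit$estimate &
                    fit$estimate < fit$conf_high))
})

test_that("collinear covariates and separation are flagged", {
  set.seed(27)
  n <- 60
  df <- tibble::tibble(signature_score = rnorm(n))
  df$dup <- df$signature_score
  df$response <- ifelse(runif(n) < plogis(df$signature_score), "CR", "RD")
  expect_warning(fit <- fit_confounder_model(df, covariates = "dup"),
                 "collinear")
  expect_true("dup" %in% attr(fit, "aliased"))

  df2 <- tibble::tibble(signature_score = c(rnorm(20, -3), rnorm(20, 3)),
                        response = rep(c("RD", "CR"), each = 20))
  expect_warning(fit2 <- fit_confounder_model(df2), "separation")
  expect_true(attr(fit2, "separation"))
})

test_that("small karyotype groups merge into other", {
  k <- c(rep("CN", 10), rep("complex", 6), "del5q", "del5q", "inv3",
         "t11q23", "t11q23", rep("other", 4))
  merged <- merge_karyotype(k, min_n = 5)
  expect_setequal(unique(merged), c("CN", "complex", "other"))
  expect_equal(sum(merged == "other"), 9)
})
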