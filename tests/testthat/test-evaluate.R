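# AUC machinery, covariate adjustment, concordance, PCA and Procrustes.

test_that("AUC matches closed forms and the all-pairs count", {
  # perfectly separated scores
  expect_equal(roc_auc(c(1, 2, 9, 10), c(0, 0, 1, 1), n_boot = 0)$auc, 1)
  # cases {3, 1}, controls {2, 0}: 3 of 4 pairs concordant
  expect_equal(roc_auc(c(3, 1, 2, 0), c(1, 1, 0, 0), n_boot = 0)$auc, 0.75)
  # ties count half
  expect_equal(roc_auc(c(1, 1), c(1, 0), n_boot = 0)$auc, 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "Both classes")
})

test_that("AUC agrees with brute force and pROC on random data", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      n <- sample(20:120, 1)
      case <- rbinom(n, 1, 0.4) == 1
      if (!any(case) || all(case)) next
      scores <- round(rnorm(n) + case, 1) # rounding forces exact ties
      est <- roc_auc(scores, case, n_boot = 0)$auc
      expect_equal(est, brute_auc(scores, case))
      ref <- as.numeric(pROC::auc(pROC::roc(case, scores, quiet = TRUE,
                                            direction = "<")))
      expect_equal(est, ref)
    }
  })
})

test_that("bootstrap CI brackets the estimate and is seed-reproducible", {
  withr::with_seed(7, {
    scores <- c(rnorm(40), rnorm(40) + 1)
    labels <- rep(c(0, 1), each = 40)
  })
  r1 <- roc_auc(scores, labels, n_boot = 500, seed = 11)
  r2 <- roc_auc(scores, labels, n_boot = 500, seed = 11)
  expect_identical(glance(r1), glance(r2))
  expect_true(r1$ci_low <= r1$auc && r1$auc <= r1$ci_high)
  expect_equal(r1$n_boot, 500)
})

test_that("adjusted AUC approximately equals unadjusted under null covariates", {
  withr::with_seed(5, {
    n <- 300
    case <- rbinom(n, 1, 0.4) == 1
    scores <- rnorm(n) + 0.8 * case
    cov <- data.frame(age = rnorm(n, 60, 8), bmi = rnorm(n, 27, 4))
  })
  plain <- roc_auc(scores, case, n_boot = 0)$auc
  adj <- adjusted_auc(scores, case, cov, n_boot = 0)$auc
  expect_lt(abs(adj - plain), 0.05)
})

test_that("placement values give 0.5 when scores are constant within strata", {
  # score identical for everyone: residuals all tie -> placement 0.5
  scores <- rep(1, 40)
  case <- rep(c(TRUE, FALSE), 20)
  cov <- data.frame(z = rnorm(40))
  adj <- suppressWarnings(adjusted_auc(scores, case, cov, n_boot = 0))
  expect_equal(adj$auc, 0.5)
})

test_that("constant covariates are dropped with a warning", {
  withr::with_seed(2, {
    scores <- rnorm(60)
    case <- rep(c(TRUE, FALSE), 30)
  })
  cov <- data.frame(flat = rep(1, 60), z = rnorm(60))
  expect_warning(adjusted_auc(scores, case, cov, n_boot = 0), "constant")
  expect_warning(
    expect_warning(adjusted_auc(scores, case, data.frame(flat = rep(1, 60)),
                                n_boot = 0), "constant"),
    "unadjusted"
  )
})

test_that("confusion metrics reproduce a hand-counted 2x2 table", {
  # 4 controls at 0.1 + 1 control at 0.5; 3 cases at 0.6 + 2 cases at 0.2
  p <- c(rep(0.1, 4), 0.5, rep(0.6, 3), rep(0.2, 2))
  labels <- c(rep("control", 5), rep("case", 5))
  cm <- confusion_at_threshold(p, labels, 0.33)
  expect_equal(cm$specificity, 4 / 5)
  expect_equal(cm$sensitivity, 3 / 5)
  expect_equal(cm$precision, 3 / 4)
  # perfect classifier
  perfect <- confusion_at_threshold(c(0.1, 0.9), c("control", "case"), 0.33)
  expect_equal(unlist(perfect[c("specificity", "sensitivity", "precision")]),
               c(specificity = 1, sensitivity = 1, precision = 1))
  # threshold above every probability: nothing positive
  none <- suppressMessages(confusion_at_threshold(p, labels, 1.01))
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)
  expect_true(is.na(none$precision))
})

test_that("Spearman concordance matches the rank formula", {
  a <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman_concordance(a, exp(a)), 1) # monotone transform
  expect_equal(spearman_concordance(a, -a), -1)
  b <- c(2, 7, 1, 8, 3)
  # independent oracle: Pearson correlation of the ranks
  expect_equal(spearman_concordance(a, b), cor(rank(a), rank(b)))
  expect_warning(out <- spearman_concordance(rep(1, 5), b), "Constant")
  expect_true(is.na(out))
  expect_error(spearman_concordance(1:2, 1:2), "3")
})

test_that("clr-PCA explains variance correctly and reconstructs at full rank", {
  # collinear data: PC1 explains everything
  line <- tibble::tibble(sample_id = paste0("s", 1:6),
                         a = 1:6, b = 2 * (1:6), c = -(1:6))
  pca <- clr_pca(line)
  expect_equal(pca$explained[1], 1)
  expect_true(all(diff(pca$explained) <= 1e-12))
  # full-rank round trip: scores %*% t(loadings) + centre = data
  withr::with_seed(13, {
    X <- matrix(rnorm(40), 8, 5,
                dimnames = list(paste0("s", 1:8), paste0("t", 1:5)))
  })
  p2 <- clr_pca(tibble::as_tibble(X, rownames = "sample_id"))
  expect_equal(sum(p2$explained), 1)
  S <- as.matrix(p2$scores[, -1])
  rec <- S %*% t(p2$loadings) + rep(p2$center, each = 8)
  expect_equal(unname(rec), unname(X), tolerance = 1e-9)
})

test_that("projection reproduces training scores and handles shifts", {
  x <- rand_counts(12, 6, seed = 19, lambda = 10)
  clr <- clr_transform(replace_zeros_bm(x))
  pca <- clr_pca(clr)
  self <- project_samples(pca, clr)
  expect_equal(as.matrix(self[, -1]), as.matrix(pca$scores[, -1]),
               tolerance = 1e-9)
  # the column-mean row projects to the origin
  ctr <- tibble::as_tibble(as.data.frame(t(pca$center)))
  ctr <- dplyr::bind_cols(tibble::tibble(sample_id = "mean"), ctr)
  expect_equal(unname(as.matrix(project_samples(pca, ctr)[, -1])[1, ]),
               rep(0, ncol(pca$loadings)), tolerance = 1e-9)
  # a constant shift of the data translates all scores equally
  m <- tbl_mat(clr)
  shift <- rnorm(ncol(m))
  shifted <- tibble::as_tibble(sweep(m, 2, -shift), rownames = "sample_id")
  ps <- project_samples(pca, shifted)
  offset <- as.matrix(ps[, -1]) - as.matrix(self[, -1])
  expect_equal(unname(offset),
               matrix(rep(unname(offset[1, ]), each = nrow(offset)),
                      nrow(offset)), tolerance = 1e-9)
  expect_error(project_samples(pca, clr[, 1:3]), "lacks")
})

test_that("Procrustes detects identity and similarity-transformed copies", {
  withr::with_seed(23, {
    X <- matrix(rnorm(60), 30, 2, dimnames = list(paste0("s", 1:30), NULL))
  })
  same <- procrustes_compare(X, X, n_perm = 99, seed = 1)
  expect_equal(same$correlation, 1, tolerance = 1e-9)
  expect_equal(same$m12_squared, 0, tolerance = 1e-9)
  # rotation + scaling + translation leave the correlation at 1
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  Y <- 3 * X %*% R + 5
  rownames(Y) <- rownames(X)
  sim <- procrustes_compare(X, Y, n_perm = 99, seed = 1)
  expect_equal(sim$correlation, 1, tolerance = 1e-9)
  # symmetry in the two arguments
  withr::with_seed(29, {
    Z <- matrix(rnorm(60), 30, 2, dimnames = list(paste0("s", 1:30), NULL))
  })
  expect_equal(procrustes_compare(X, Z, n_perm = 99, seed = 1)$correlation,
               procrustes_compare(Z, X, n_perm = 99, seed = 1)$correlation,
               tolerance = 1e-9)
  expect_error(procrustes_compare(X[1:2, ], Z[1:2, ], n_perm = 99),
               "more samples")
})

test_that("roc_result tidiers expose the curve and the summary", {
  r <- roc_auc(c(0.2, 0.8, 0.6, 0.3), c(0, 1, 1, 0), n_boot = 50, seed = 3)
  g <- glance(r)
  expect_identical(names(g)[1:3], c("auc", "ci_low", "ci_high"))
  curve <- tidy(r)
  expect_equal(curve$fpr[1], 0)
  expect_equal(curve$tpr[nrow(curve)], 1)
  expect_true(all(diff(curve$fpr) >= 0) && all(diff(curve$tpr) >= 0))
})
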