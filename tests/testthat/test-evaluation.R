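test_that("temporal split takes the earliest two thirds as training", {
  cfg <- small_config(volumes = FALSE)
  co <- simulate_cohort(150, kps_outcome_model(), config = cfg, seed = 6)
  sp <- temporal_split(co)
  expect_length(sp$train, 100)
  expect_length(sp$test, 50)
  expect_length(intersect(sp$train, sp$test), 0)
  rec <- co$records
  expect_lte(max(rec$operation_date[rec$patient_id %in% sp$train]),
             min(rec$operation_date[rec$patient_id %in% sp$test]))

  tiny <- data.frame(patient_id = c("c", "a", "b"),
                     operation_date = as.Date(c("2020-03-01", "2020-01-01",
                                                "2020-02-01")))
  sp3 <- temporal_split(tiny)
  expect_identical(sp3$train, c("a", "b"))
  expect_identical(sp3$test, "c")

  tied <- data.frame(patient_id = c("b", "c", "a"),
                     operation_date = as.Date(rep("2020-01-01", 3)))
  spt <- temporal_split(tied)       # ties break by patient id
  expect_identical(spt$train, c("a", "b"))
})

test_that("metrics match hand-computed confusion and ranking values", {
  m <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.3, 0.8, 0.2))
  expect_equal(m$auc, 0.75)          # 3 of 4 concordant pairs

  perfect <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$accuracy, 1)

  labels <- c(rep(1, 4), rep(0, 6))
  scores <- c(0.9, 0.8, 0.4, 0.3, 0.6, 0.2, 0.2, 0.1, 0.05, 0)
  cm <- compute_metrics(labels, scores)   # TP=2 FN=2 FP=1 TN=5
  expect_equal(cm$sensitivity, 0.5)
  expect_equal(cm$specificity, 5 / 6)
  expect_equal(cm$f1, 2 * 2 / (2 * 2 + 1 + 2))
  expect_equal(cm$accuracy, 0.7)

  # tied constant scores carry no ranking information
  expect_equal(compute_metrics(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)

  expect_warning(one <- compute_metrics(c(1, 1), c(0.2, 0.8)), "one class")
  expect_true(is.na(one$auc))
  expect_equal(one$accuracy, 0.5)
})

test_that("AUC equals the rescaled Mann-Whitney U statistic", {
  set.seed(5)
  for (i in 1:100) {
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    scores <- sample(seq(0, 1, 0.1), n1 + n0, replace = TRUE)  # with ties
    labels <- c(rep(1, n1), rep(0, n0))
    auc <- compute_metrics(labels, scores)$auc
    U <- mann_whitney_u(scores[labels == 1], scores[labels == 0])$U
    expect_equal(auc, U / (n1 * n0))
    W <- suppressWarnings(wilcox.test(scores[labels == 1],
                                      scores[labels == 0]))$statistic
    expect_equal(auc, unname(W) / (n1 * n0))
  }
})

test_that("repeated CV emits one stratified record per repeat and fold", {
  toy <- toy_separable(n = 36, seed = 8)
  X <- toy$X + matrix(rnorm(length(toy$X), sd = 2), nrow(toy$X))
  builder <- nn_builder(nn_config(hidden_widths = c(4L), dropout = 0,
                                  epochs = 20L, batch_size = 12L))
  rep_cv <- repeated_cv(builder, X, toy$y, folds = 3, repeats = 2, seed = 2)
  expect_equal(nrow(rep_cv$records), 6)
  expect_true(all(rep_cv$records$auc >= 0 & rep_cv$records$auc <= 1))
  # per repeat the validation folds partition the cohort
  for (r in 1:2) {
    sizes <- vapply(Filter(function(f) f$repeat_ == r,
                           rep_cv$fold_predictions),
                    function(f) length(f$labels), 1L)
    expect_equal(sum(sizes), nrow(X))
  }
  # stratification keeps both classes in every validation fold
  expect_true(all(vapply(rep_cv$fold_predictions,
                         function(f) length(unique(f$labels)) == 2L, NA)))
  expect_error(repeated_cv(builder, X, rep(c(0, 1), c(34, 2)), folds = 3,
                           repeats = 1, seed = 1), "stratify")
})

test_that("mean ROC curves average vertically over a fixed FPR grid", {
  set.seed(10)
  fold <- function() {
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) == 1) y[1] <- 1 - y[1]
    list(labels = y, scores = runif(40))
  }
  f1 <- fold()
  single <- mean_roc_curve(list(f1))
  expect_equal(nrow(single), 101)
  expect_equal(single$fpr, seq(0, 1, length.out = 101))
  expect_equal(single$tpr_mean[1], 0)
  expect_equal(single$tpr_mean[101], 1)
  twin <- mean_roc_curve(list(f1, f1))
  expect_equal(twin$tpr_mean, single$tpr_mean)

  many <- mean_roc_curve(replicate(10, fold(), simplify = FALSE))
  expect_true(all(diff(many$tpr_mean) >= -1e-12))
  expect_error(mean_roc_curve(list()), "at least one fold")
})

test_that("the paired t-test matches its closed form and flags ties", {
  a <- c(0.7, 0.85, 0.9); b <- c(0.6, 0.7, 0.8)
  res <- paired_t_test(a, b)
  expect_equal(res$t, 7, tolerance = 1e-10)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(res$p, ref$p.value)
  expect_false(res$tie)

  expect_warning(tie <- paired_t_test(a, a), "tie")
  expect_true(tie$tie)
  expect_true(is.na(tie$t))
  expect_warning(shift <- paired_t_test(a, a + 0.1), "tie")
  expect_equal(shift$mean_diff, -0.1)
})
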