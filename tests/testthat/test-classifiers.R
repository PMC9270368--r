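test_that("stepwise Wilks' lambda is exact on the hand-computed 1-D fixture", {
  d <- tibble::tibble(x = c(0, 1, 10, 11), cls = c("a", "a", "b", "b"))
  sw <- stepwise_wilks(d, "x", cls)
  expect_equal(sw$selected, "x")
  expect_equal(sw$lambda, 1 / 101, tolerance = 1e-12) # SSW = 1, SST = 101
  expect_equal(sw$chi_square, -(4 - 1 - (1 + 2) / 2) * log(1 / 101),
               tolerance = 1e-12)
  expect_equal(sw$df, 1)
})

test_that("stepwise selection prefers the separating variable and lambda never increases", {
  set.seed(1)
  n <- 40
  d <- tibble::tibble(
    sep = c(rnorm(n / 2), rnorm(n / 2) + 4),
    noise = rnorm(n),
    cls = rep(c("a", "b"), each = n / 2)
  )
  sw <- stepwise_wilks(d, c("noise", "sep"), cls)
  expect_equal(sw$steps$variable[1], "sep")
  # exhaustive one-variable lambda comparison oracle
  lam_each <- vapply(c("noise", "sep"), function(v)
    oracle_wilks(d[v], factor(d$cls)), numeric(1))
  expect_equal(names(which.min(lam_each)), "sep")
  entered <- sw$steps[sw$steps$action == "enter", ]
  expect_true(all(diff(entered$lambda) <= 1e-12))
  expect_true(sw$lambda > 0 && sw$lambda <= 1)
  expect_true(all(sw$selected %in% c("noise", "sep")))
})

test_that("identical class means give the flagged empty model with lambda 1", {
  d <- tibble::tibble(x = rep(c(1, 2, 3), 2), y = rep(c(5, 6, 7), 2),
                      cls = rep(c("a", "b"), each = 3))
  sw <- stepwise_wilks(d, c("x", "y"), cls)
  expect_true(sw$empty)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$selected, character(0))
})

test_that("QDA leave-one-out matches the brute-force density oracle and handles degeneracy", {
  # tiny 1-D fixture with interleaved classes
  d <- tibble::tibble(x = c(0.1, 0.9, 1.7, 2.2, 2.8, 3.1, 4.0, 4.6),
                      cls = c("a", "a", "a", "b", "a", "b", "b", "b"))
  rep_ <- qda_crossval(d, "x", cls)
  expect_equal(rep_$per_individual$predicted, oracle_qda_loo(d["x"], d$cls))
  # far-separated clusters classify perfectly
  set.seed(2)
  d2 <- tibble::tibble(x = c(rnorm(10), rnorm(10) + 50), y = rnorm(20),
                       cls = rep(c("a", "b"), each = 10))
  r2 <- qda_crossval(d2, c("x", "y"), cls)
  expect_equal(r2$rate_global, 100)
  expect_equal(r2$n_misclassified, 0)
  # class smaller than the predictor count is a precondition error
  d3 <- tibble::tibble(x = rnorm(5), y = rnorm(5), z = rnorm(5),
                       cls = c("a", "a", "b", "b", "b"))
  expect_error(qda_crossval(d3, c("x", "y", "z"), cls),
               class = "morphoverlap_validation_error")
})

test_that("QDA-LOO predictions are permutation-equivariant", {
  set.seed(3)
  d <- tibble::tibble(individual_id = sprintf("i%02d", 1:24),
                      x = c(rnorm(12), rnorm(12) + 2), y = rnorm(24),
                      cls = rep(c("a", "b"), each = 12))
  r1 <- qda_crossval(d, c("x", "y"), cls)
  perm <- sample(24)
  r2 <- qda_crossval(d[perm, ], c("x", "y"), cls)
  m1 <- r1$per_individual[order(r1$per_individual$individual_id), ]
  m2 <- r2$per_individual[order(r2$per_individual$individual_id), ]
  expect_equal(m1$predicted, m2$predicted)
})

test_that("the single-claim combination rule is enforced exactly", {
  claims <- matrix(c(TRUE, FALSE, TRUE, FALSE,
                     FALSE, FALSE, TRUE, TRUE), ncol = 2,
                   dimnames = list(NULL, c("a", "b")))
  truth <- c("a", "a", "b", "b")
  out <- morphoverlap:::combine_claims(claims, truth, is_hybrid = rep(FALSE, 4))
  # row 1: single correct claim; row 2: no claim; row 3: double claim;
  # row 4: single claim matching truth
  expect_equal(out$correct, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$n_claims, c(1L, 0L, 2L, 1L))
  expect_equal(out$predicted, c("a", NA, NA, "b"))
})

test_that("SVM ensemble is seed-reproducible and perfect on separable scores", {
  set.seed(4)
  d <- tibble::tibble(s1 = c(rnorm(15, -3), rnorm(15, 3)), s2 = rnorm(30),
                      cls = rep(c("a", "b"), each = 15))
  cfg <- svm_config(n_restarts = 5, seed = 42)
  r1 <- svm_ensemble(d, c("s1", "s2"), cls, config = cfg)
  expect_equal(r1$rate_global, 100)
  r2 <- svm_ensemble(d, c("s1", "s2"), cls, config = cfg)
  expect_identical(r1$per_individual, r2$per_individual)
})

test_that("with one deterministic restart and one gamma the ensemble degenerates to a single one-vs-rest SVM pair", {
  # XOR pattern: radial kernel separates what a linear rule cannot
  d <- tibble::tibble(
    s1 = c(-1, -1, 1, 1, -1.2, -0.8, 1.2, 0.8),
    s2 = c(-1, 1, -1, 1, -1.1, 0.9, -1.2, 1.1),
    cls = c("a", "b", "b", "a", "a", "b", "b", "a")
  )
  cfg <- svm_config(gamma = 10, n_restarts = 1, restart_scheme = "none",
                    seed = 1)
  rep_ <- svm_ensemble(d, c("s1", "s2"), cls, config = cfg)
  # reference single-SVM predictions at the same fixed hyperparameters
  x <- as.matrix(d[c("s1", "s2")])
  ref <- lapply(c("a", "b"), function(cl) {
    yc <- factor(ifelse(d$cls == cl, cl, ".rest"), levels = c(cl, ".rest"))
    as.character(predict(e1071::svm(x, yc, type = "C-classification",
                                    kernel = "radial", gamma = 10, cost = 1,
                                    scale = FALSE), x)) == cl
  })
  claims_ref <- cbind(a = ref[[1]], b = ref[[2]])
  expect_equal(rep_$per_individual$n_claims, as.integer(rowSums(claims_ref)))
  agree <- rowSums(claims_ref) == 1
  expect_equal(rep_$per_individual$predicted[agree],
               colnames(claims_ref)[apply(claims_ref[agree, ], 1, which)])
  expect_equal(rep_$rate_global, 100) # XOR solved by the radial kernel
})

test_that("report rates are internally consistent with the confusion counts", {
  set.seed(5)
  d <- tibble::tibble(x = c(rnorm(12), rnorm(12) + 1.2), y = rnorm(24),
                      cls = rep(c("a", "b"), each = 12))
  for (rep_ in list(qda_crossval(d, c("x", "y"), cls),
                    svm_ensemble(d, c("x", "y"), cls,
                                 config = svm_config(n_restarts = 3, seed = 2)))) {
    pc <- rep_$per_class
    expect_equal(rep_$rate_global,
                 100 * sum(pc$n_correct) / sum(pc$n), tolerance = 1e-12)
    expect_gte(rep_$rate_global, min(pc$rate))
    expect_lte(rep_$rate_global, max(pc$rate))
    expect_equal(rep_$n_misclassified, sum(pc$n) - sum(pc$n_correct))
    expect_lte(rep_$n_misclassified_hybrids, rep_$n_misclassified)
  }
})
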