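test_that("Kruskal-Wallis matches the rank formula without ties and handles degeneracy", {
  d <- tibble::tibble(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
  res <- kruskal_wallis(d, v, g)
  expect_equal(res$statistic, 3.857, tolerance = 1e-3) # 12/(N(N+1)) sum ni (Ri - (N+1)/2)^2
  expect_equal(res$df1, 1)
  # tie correction: dividing the corrected H by the correction factor
  # reproduces the uncorrected midrank statistic
  dt <- tibble::tibble(v = c(1, 2, 2, 3, 5, 5, 6, 7),
                       g = rep(c("a", "b"), each = 4))
  r <- rank(dt$v)
  N <- length(r)
  h_uncorr <- 12 / (N * (N + 1)) *
    sum(tapply(r, dt$g, function(x) length(x) * (mean(x) - (N + 1) / 2)^2))
  ties <- table(dt$v)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  expect_equal(kruskal_wallis(dt, v, g)$statistic, h_uncorr / corr,
               tolerance = 1e-12)
  # identical values in every group: tie correction degenerates
  dd <- tibble::tibble(v = c(5, 5, 5, 5), g = c("a", "a", "b", "b"))
  expect_error(kruskal_wallis(dd, v, g),
               class = "morphoverlap_degenerate_data")
  expect_error(kruskal_wallis(dplyr::mutate(d, g = "a"), v, g),
               class = "morphoverlap_validation_error")
})

test_that("one-way ANOVA is exact on hand-sized data and location/scale invariant", {
  d <- tibble::tibble(v = c(1, 2, 1, 2), g = c("a", "a", "b", "b"))
  expect_equal(one_way_anova(d, v, g)$statistic, 0)
  d2 <- tibble::tibble(v = c(25.2, 26.8, 13.6, 7.6),
                       g = c("c", "c", "m", "m"))
  res <- one_way_anova(d2, v, g)
  expect_equal(res$statistic, 24.602, tolerance = 1e-3)
  expect_equal(c(res$df1, res$df2), c(1, 2))
  # invariance properties
  set.seed(1)
  d3 <- tibble::tibble(v = rnorm(12), g = rep(letters[1:3], 4))
  f0 <- one_way_anova(d3, v, g)$statistic
  expect_equal(one_way_anova(dplyr::mutate(d3, v = v + 100), v, g)$statistic, f0)
  expect_equal(one_way_anova(dplyr::mutate(d3, v = v * 3.7), v, g)$statistic, f0)
})

test_that("post hocs find the separated group and Tukey never undercuts LSD", {
  d <- tibble::tibble(v = c(1.0, 1.2, 0.9, 1.1, 1.05, 0.95, 9.0, 9.2, 8.9),
                      g = rep(c("a", "b", "c"), each = 3))
  for (m in c("LSD", "TukeyHSD")) {
    ph <- posthoc(d, v, g, method = m)
    far <- ph$p_value[ph$group_a == "c" | ph$group_b == "c"]
    near <- ph$p_value[ph$group_a != "c" & ph$group_b != "c"]
    expect_true(all(far < 0.001))
    expect_true(all(near > 0.1))
  }
  # brute-force pooled-variance t oracle for one LSD pair
  ph <- posthoc(d, v, g, method = "LSD")
  msw <- sum(tapply(d$v, d$g, function(x) sum((x - mean(x))^2))) / (9 - 3)
  tstat <- (mean(d$v[d$g == "a"]) - mean(d$v[d$g == "b"])) /
    sqrt(msw * (2 / 3))
  expect_equal(ph$p_value[ph$group_a == "a" & ph$group_b == "b"],
               2 * pt(-abs(tstat), df = 6), tolerance = 1e-12)
  # identical groups: estimate 0, p = 1 under LSD
  d0 <- tibble::tibble(v = c(1, 2, 1, 2), g = c("a", "a", "b", "b"))
  ph0 <- posthoc(d0, v, g, method = "LSD")
  expect_equal(ph0$estimate, 0)
  expect_equal(ph0$p_value, 1)
  # adjustment monotonicity on arbitrary data
  set.seed(2)
  dr <- tibble::tibble(v = rnorm(15), g = rep(letters[1:3], 5))
  lsd <- posthoc(dr, v, g, method = "LSD")
  tk <- posthoc(dr, v, g, method = "TukeyHSD")
  expect_true(all(tk$p_value >= lsd$p_value - 1e-8))
})

test_that("Box's M matches the determinant oracle and is zero for equal covariances", {
  set.seed(3)
  x <- matrix(rnorm(24), ncol = 2)
  d <- tibble::as_tibble(as.data.frame(x))
  names(d) <- c("v1", "v2")
  d$g <- rep(c("a", "b"), each = 6)
  res <- box_m(d, g, c("v1", "v2"))
  expect_equal(res$statistic, oracle_box_m(x, d$g), tolerance = 1e-10)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  # identical rows duplicated across groups -> equal covariances -> M = 0
  dup <- dplyr::bind_rows(dplyr::mutate(d[1:6, ], g = "a"),
                          dplyr::mutate(d[1:6, ], g = "b"))
  expect_equal(box_m(dup, g, c("v1", "v2"))$statistic, 0, tolerance = 1e-10)
  # group size must exceed dimension
  small <- d[c(1, 2, 7, 8), ]
  expect_error(box_m(small, g, c("v1", "v2")),
               class = "morphoverlap_validation_error")
})

test_that("permutation MANOVA pseudo-F matches the distance identity and vegan, with exact and seeded p-values", {
  set.seed(4)
  d <- tibble::tibble(v1 = rnorm(8), v2 = rnorm(8),
                      g = rep(c("a", "b"), each = 4))
  res <- permutation_manova(d, g, c("v1", "v2"), n_perm = 499, seed = 11)
  expect_equal(res$statistic, oracle_pseudo_f(d[c("v1", "v2")], d$g),
               tolerance = 1e-10)
  skip_if_not_installed("vegan")
  ad <- vegan::adonis2(d[c("v1", "v2")] ~ g, data = d, permutations = 99,
                       method = "euclidean")
  expect_equal(res$statistic, ad$F[1], tolerance = 1e-10)
  # exhaustive two-group enumeration is exact
  ex <- permutation_manova(d, g, c("v1", "v2"), exhaustive = TRUE)
  expect_equal(ex$p_value, oracle_exhaustive_p(d[c("v1", "v2")], d$g),
               tolerance = 1e-12)
  # Monte-Carlo p agrees with the exact p within binomial error
  mc <- permutation_manova(d, g, c("v1", "v2"), n_perm = 1999, seed = 5)
  se <- sqrt(ex$p_value * (1 - ex$p_value) / 1999)
  expect_lt(abs(mc$p_value - ex$p_value), 4 * se + 1e-3)
  # determinism and the attainable minimum under strong separation
  expect_identical(permutation_manova(d, g, c("v1", "v2"), n_perm = 199, seed = 9),
                   permutation_manova(d, g, c("v1", "v2"), n_perm = 199, seed = 9))
  dsep <- tibble::tibble(v1 = c(rnorm(10), rnorm(10) + 100), v2 = rnorm(20),
                         g = rep(c("a", "b"), each = 10))
  expect_equal(permutation_manova(dsep, g, c("v1", "v2"), n_perm = 199,
                                  seed = 1)$p_value, 1 / 200)
})

test_that("classical MANOVA reduces to ANOVA for one response and matches the determinant oracle", {
  set.seed(6)
  d <- tibble::tibble(v1 = rnorm(12), v2 = rnorm(12),
                      g = rep(c("a", "b"), each = 6))
  one <- classical_manova(d, g, "v1")
  aov1 <- one_way_anova(d, v1, g)
  expect_equal(one$statistic, aov1$statistic, tolerance = 1e-12)
  expect_equal(one$p_value, aov1$p_value, tolerance = 1e-12)
  two <- classical_manova(d, g, c("v1", "v2"))
  expect_equal(two$wilks, oracle_wilks(d[c("v1", "v2")], d$g),
               tolerance = 1e-10)
  # identical group means: lambda ~ 1, F ~ 0
  dnull <- tibble::tibble(v1 = rep(c(1, 2, 3), 2), v2 = rep(c(2, 1, 3), 2),
                          g = rep(c("a", "b"), each = 3))
  resn <- classical_manova(dnull, g, c("v1", "v2"))
  expect_equal(resn$wilks, 1, tolerance = 1e-10)
  expect_equal(resn$statistic, 0, tolerance = 1e-10)
})
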