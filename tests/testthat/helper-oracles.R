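# Fixture builders and independent brute-force oracles used across the suite.

# A small, fully valid trait table (n rows, alternating species/zones).
make_test_table <- function(n = 6) {
  base <- tibble::tibble(
    individual_id = sprintf("id%02d", seq_len(n)),
    species = rep(c("isabellinus", "serotinus"), length.out = n),
    is_hybrid = FALSE,
    zone = rep(c("allopatric", "sympatric"), length.out = n),
    FA = 50 + seq_len(n) / 10,
    D3_MC = 46 + seq_len(n) / 10,
    D3_F1 = 18 + seq_len(n) / 20,
    D5_MC = 44 + seq_len(n) / 10,
    D5_F1 = 11 + seq_len(n) / 20,
    C1_C1 = 6.5 + seq_len(n) / 50,
    CM3 = 7.2 + seq_len(n) / 50,
    L_dorsal = 30 + seq_len(n),
    a_dorsal = 5 + seq_len(n) / 10,
    b_dorsal = 15 + seq_len(n) / 10,
    L_ventral = 40 + seq_len(n),
    a_ventral = 4 + seq_len(n) / 10,
    b_ventral = 13 + seq_len(n) / 10
  )
  base
}

# The published reference rates grid in the layout overlap_summary() expects.
reference_grid <- function() morphoverlap::reference_rates()

# Plug-in leave-one-out QDA predictions by direct evaluation of both class
# log-densities (unbiased covariance estimates, equal priors).
oracle_qda_loo <- function(x, g) {
  x <- as.matrix(x)
  g <- factor(g)
  vapply(seq_len(nrow(x)), function(i) {
    scores <- vapply(levels(g), function(cl) {
      xi <- x[g == cl & seq_len(nrow(x)) != i, , drop = FALSE]
      mu <- colMeans(xi)
      S <- stats::cov(xi)
      d <- x[i, ] - mu
      as.numeric(-0.5 * log(det(S)) - 0.5 * t(d) %*% solve(S) %*% d +
                   log(1 / nlevels(g)))
    }, numeric(1))
    levels(g)[which.max(scores)]
  }, character(1))
}

# Box's M by explicit log-determinants.
oracle_box_m <- function(x, g) {
  x <- as.matrix(x)
  g <- factor(g)
  ns <- table(g)
  n <- nrow(x)
  k <- nlevels(g)
  covs <- lapply(levels(g), function(l) stats::cov(x[g == l, , drop = FALSE]))
  pooled <- Reduce(`+`, Map(function(S, ni) (ni - 1) * S, covs, ns)) / (n - k)
  (n - k) * log(det(pooled)) -
    sum(vapply(seq_along(covs), function(i) (ns[i] - 1) * log(det(covs[[i]])),
               numeric(1)))
}

# Cronbach's alpha by direct variance computation.
oracle_alpha <- function(x) {
  x <- as.matrix(x)
  k <- ncol(x)
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / stats::var(rowSums(x)))
}

# Pseudo-F from the pairwise-distance identity (independent of the centroid
# route used by the implementation): SS within a set of m points equals the
# sum of squared pairwise distances divided by m.
oracle_pseudo_f <- function(x, g) {
  x <- as.matrix(x)
  g <- factor(g)
  d2 <- as.matrix(stats::dist(x))^2
  n <- nrow(x)
  k <- nlevels(g)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- sum(vapply(levels(g), function(l) {
    idx <- which(g == l)
    di <- d2[idx, idx, drop = FALSE]
    sum(di[upper.tri(di)]) / length(idx)
  }, numeric(1)))
  ((sst - ssw) / (k - 1)) / (ssw / (n - k))
}

# Exact exhaustive-permutation p-value for a two-group design.
oracle_exhaustive_p <- function(x, g) {
  g <- factor(g)
  n <- nrow(x)
  n1 <- sum(g == levels(g)[1])
  f_obs <- oracle_pseudo_f(x, g)
  sets <- utils::combn(n, n1)
  f_all <- apply(sets, 2, function(idx) {
    lab <- factor(ifelse(seq_len(n) %in% idx, levels(g)[1], levels(g)[2]),
                  levels = levels(g))
    oracle_pseudo_f(x, lab)
  })
  mean(f_all >= f_obs - 1e-12)
}

# Wilks' lambda by explicit SSCP determinants.
oracle_wilks <- function(x, g) {
  x <- as.matrix(x)
  g <- factor(g)
  T_ <- crossprod(sweep(x, 2, colMeans(x)))
  W <- Reduce(`+`, lapply(levels(g), function(l) {
    xi <- x[g == l, , drop = FALSE]
    crossprod(sweep(xi, 2, colMeans(xi)))
  }))
  det(W) / det(T_)
}
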