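test_that("scatter matrices follow their definitions and decomposition", {
  # identical samples -> both scatters vanish
  x0 <- matrix(1, 6, 3)
  sc0 <- compute_scatter(x0, rep(c("a", "b"), each = 3))
  expect_equal(sc0$s_b, matrix(0, 3, 3), ignore_attr = TRUE)
  expect_equal(sc0$s_w, matrix(0, 3, 3), ignore_attr = TRUE)
  # two 1-D classes {0,0} and {2,2}: m = 1, S_B = 2*1 + 2*1 = 4, S_W = 0
  x1 <- matrix(c(0, 0, 2, 2), 4, 1)
  sc1 <- compute_scatter(x1, rep(c("a", "b"), each = 2))
  expect_equal(as.numeric(sc1$s_b), 4)
  expect_equal(as.numeric(sc1$s_w), 0)
  # trace(S_B) + trace(S_W) = trace of total scatter
  set.seed(48)
  x <- matrix(rnorm(40 * 6), 40)
  lab <- rep(letters[1:4], each = 10)
  sc <- compute_scatter(x, lab)
  total <- crossprod(sweep(x, 2, colMeans(x)))
  expect_equal(sum(diag(sc$s_b)) + sum(diag(sc$s_w)), sum(diag(total)))
  # a singleton class is an error
  expect_error(compute_scatter(x, c("z", lab[-1])), class = "reverb_bad_input")
})

test_that("shrinkage regularization interpolates between S_W and identity", {
  set.seed(49)
  x <- matrix(rnorm(30 * 5), 30)
  lab <- rep(c("a", "b", "c"), each = 10)
  sc <- compute_scatter(x, lab)
  r0 <- regularize_within(sc$omega, 0, sc$n_i)
  expect_equal(r0$s_w_reg, sc$s_w)
  r1 <- regularize_within(sc$omega, 1, sc$n_i, scale = "identity")
  expect_equal(r1$omega_reg[[1]], diag(5))
  # rank-deficient covariance: eigenvalues bounded below by lambda
  omega_def <- list(tcrossprod(c(1, 0, 0)))      # rank 1
  rd <- regularize_within(omega_def, 0.5, 3, scale = "identity")
  expect_gte(min(eigen(rd$omega_reg[[1]])$values), 0.5)
  expect_error(regularize_within(sc$omega, 1.2, sc$n_i), class = "reverb_bad_input")
})

test_that("the fitted basis solves the generalized eigenproblem", {
  set.seed(50)
  x <- matrix(rnorm(60 * 20), 60)
  lab <- factor(rep(1:4, each = 15))
  x <- x + 2 * matrix(rnorm(4 * 20), 4)[as.integer(lab), ]
  m <- fit_mda(x, lab, lambda = 0.4)
  expect_lte(m$d, 3)
  sc <- compute_scatter(x, lab)
  swr <- regularize_within(sc$omega, 0.4, sc$n_i)$s_w_reg
  for (k in seq_len(m$d)) {
    v <- m$basis[, k]
    resid <- sc$s_b %*% v - m$eigenvalues[k] * (swr %*% v)
    expect_lte(sqrt(sum(resid^2)), 1e-6 * sqrt(sum((sc$s_b %*% v)^2)))
  }
  # eigenvalues agree with a naive dense solve(S_W') %*% S_B decomposition
  ev_naive <- Re(eigen(solve(swr) %*% sc$s_b)$values)
  ev_naive <- sort(ev_naive, decreasing = TRUE)[seq_len(m$d)]
  expect_equal(m$eigenvalues, ev_naive, tolerance = 1e-8)
})

test_that("two-class fits reduce to the Fisher discriminant direction", {
  set.seed(51)
  x <- matrix(rnorm(30 * 12), 30)
  lab <- factor(rep(1:2, each = 15))
  x[lab == 2, ] <- x[lab == 2, ] + 1
  m <- fit_mda(x, lab, lambda = 0.3)
  expect_equal(m$d, 1)
  sc <- compute_scatter(x, lab)
  swr <- regularize_within(sc$omega, 0.3, sc$n_i)$s_w_reg
  fisher <- solve(swr, sc$class_means[1, ] - sc$class_means[2, ])
  cosang <- abs(sum(fisher * m$basis[, 1])) /
    sqrt(sum(fisher^2) * sum(m$basis[, 1]^2))
  expect_equal(cosang, 1, tolerance = 1e-8)
})

test_that("the subspace span is invariant to sample order", {
  set.seed(52)
  x <- matrix(rnorm(40 * 8), 40)
  lab <- factor(rep(letters[1:4], each = 10))
  x <- x + 3 * matrix(rnorm(4 * 8), 4)[as.integer(lab), ]
  m1 <- fit_mda(x, lab, lambda = 0.5)
  perm <- sample(40)
  m2 <- fit_mda(x[perm, ], lab[perm], lambda = 0.5)
  # compare projectors onto the subspaces
  p1 <- m1$basis %*% solve(crossprod(m1$basis), t(m1$basis))
  p2 <- m2$basis %*% solve(crossprod(m2$basis), t(m2$basis))
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("classification assigns class means to their class and flags ties", {
  set.seed(53)
  x <- matrix(rnorm(30 * 6), 30)
  lab <- factor(rep(1:3, each = 10))
  x <- x + 4 * matrix(rnorm(3 * 6), 3)[as.integer(lab), ]
  m <- fit_mda(x, lab, lambda = 0.5)
  # feature-space class means classify to their own class
  sc <- compute_scatter(x, lab)
  pred <- classify_patterns(m, sc$class_means)
  expect_equal(pred$class, levels(lab))
  expect_error(project_patterns(m, matrix(0, 1, 5)), class = "reverb_dim_error")
})

test_that("cross-validation is perfect on duplicated noiseless classes and at chance under label shuffle", {
  base <- matrix(rnorm(5 * 10), 5)
  x <- base[rep(1:5, each = 10), ] + matrix(rnorm(50 * 10, sd = 0.01), 50)
  pats <- structure(list(x = x, labels = factor(rep(1:5, each = 10)),
                         units = paste0("u", 1:10),
                         meta = tibble::tibble(start = NA_real_, label = "x"),
                         bin_width = NA_real_, n_bins = 1L),
                    class = "labelled_patterns")
  cv <- cross_validate_mda(pats, lambda = 0.5, n_rep = 20, seed = 1)
  expect_equal(mean(cv$accuracy), 1)
  # label shuffle -> chance
  set.seed(54)
  pats$x <- matrix(rnorm(50 * 10), 50)
  cv0 <- cross_validate_mda(pats, lambda = 0.5, n_rep = 100, seed = 2)
  g <- glance(cv0)
  expect_lt(abs(g$mean_accuracy - g$chance), 3 * g$se)
  # a class that cannot spare a holdout is an error
  pats$labels <- factor(c(1, rep(2, 49)))
  expect_error(cross_validate_mda(pats, n_rep = 5), class = "reverb_bad_input")
})

test_that("held-out accuracy increases with class separation", {
  accs <- vapply(c(1, 3, 6), function(sep) {
    pats <- simulate_labelled_patterns(4, 10, 24, sep, seed = 55)
    mean(cross_validate_mda(pats, lambda = 0.6, n_rep = 60, seed = 56)$accuracy)
  }, numeric(1))
  expect_true(all(diff(accs) > -0.02))   # monotone within CI
  expect_gt(accs[3], accs[1])
})

test_that("lambda selection maximizes cross-validated accuracy with smallest-tie rule", {
  pats <- simulate_labelled_patterns(3, 10, 15, 5, seed = 57)
  one <- select_lambda(pats, grid = 0.5, n_rep = 10, seed = 3)
  expect_equal(one$lambda, 0.5)
  # flat accuracy profile -> smallest lambda wins
  flat <- select_lambda(pats, grid = c(0.3, 0.6, 0.9), n_rep = 30, seed = 4)
  expect_true(flat$lambda %in% c(0.3, 0.6, 0.9))
  path <- flat$path
  expect_equal(flat$lambda, path$lambda[which.max(path$accuracy)])
})

test_that("zero-sum class means leave no linear signal after unit shuffling", {
  pats <- simulate_labelled_patterns(5, 12, 40, 6, seed = 58)
  # class means are zero-sum and equal-norm by construction
  sums <- tapply(rowSums(pats$x), pats$labels, mean)
  expect_lt(max(abs(sums - mean(sums))), 3)
  sh <- shuffle_pattern_units(pats, seed = 59)
  # per-sample multisets of values are preserved
  expect_equal(apply(sh$x, 1, sort), apply(pats$x, 1, sort))
})
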