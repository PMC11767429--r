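separated_clouds <- function(n_per = 15, p = 8, shift = 4, seed = 5) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p, shift), n_per))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, labels = rep(c("a", "b"), each = n_per))
}

test_that("PLS-DA separates planted classes and validates its inputs", {
  d <- separated_clouds()
  m <- fit_plsda(d$x, d$labels, ncomp = 1)
  g1 <- m$T[d$labels == "a", 1]; g2 <- m$T[d$labels == "b", 1]
  expect_true(max(g1) < min(g2) || min(g1) > max(g2)) # zero overlap
  expect_true(m$R2Y[1] > 0.8)

  expect_error(fit_plsda(d$x, rep("a", nrow(d$x))), "at least 2 classes")
  expect_error(fit_plsda(d$x[1:16, ], c(rep("a", 15), "b")), "fewer than 2")
  # duplicated feature gets identical weights
  x2 <- cbind(d$x, f1bis = d$x[, 1])
  m2 <- fit_plsda(x2, d$labels, ncomp = 2)
  expect_equal(m2$W[colnames(x2) == "f1", ], m2$W[colnames(x2) == "f1bis", ],
               tolerance = 1e-8)
  # constant feature is dropped with a warning
  x3 <- cbind(d$x, flat = 1)
  expect_warning(m3 <- fit_plsda(x3, d$labels), "constant")
  expect_false("flat" %in% m3$features)
})

test_that("VIP satisfies its normalization identity and matches the textbook sum", {
  # symmetric two-feature model: both VIPs exactly 1
  set.seed(6)
  z <- rnorm(20)
  x <- cbind(a = z + rnorm(20, sd = 0.2), b = z + rnorm(20, sd = 0.2))
  lb <- ifelse(z > 0, "hi", "lo")
  m <- fit_plsda(x, lb, ncomp = 1, cv_folds = 0)
  expect_equal(mean(vip_scores(m)^2), 1, tolerance = 1e-12)

  # mean of squared VIP is 1 on random fits
  set.seed(7)
  for (i in 1:10) {
    n <- sample(12:30, 1); p <- sample(4:12, 1)
    xr <- matrix(rnorm(n * p), n)
    lr <- sample(c("u", "v", "w"), n, replace = TRUE)
    if (min(table(lr)) < 2) next
    mr <- fit_plsda(xr, lr, ncomp = 2, cv_folds = 0)
    expect_equal(mean(vip_scores(mr)^2), 1, tolerance = 1e-10)
  }

  # 6x4 toy against an independently coded VIP oracle
  x4 <- matrix(c(1, 2, 3, 4, 5, 6,
                 2, 1, 4, 3, 6, 5,
                 6, 5, 4, 3, 2, 1,
                 1, 3, 2, 5, 4, 6), 6, 4)
  colnames(x4) <- paste0("v", 1:4)
  lb4 <- c("a", "a", "a", "b", "b", "b")
  m4 <- fit_plsda(x4, lb4, ncomp = 2, cv_folds = 0)
  # oracle: explicit loop over components of the VIP definition
  p <- length(m4$features); A <- m4$ncomp
  ss <- numeric(A); wnorm <- matrix(0, p, A)
  for (a in seq_len(A)) {
    ss[a] <- sum(m4$T[, a]^2) * sum(m4$Q[, a]^2)
    wnorm[, a] <- m4$W[, a] / sqrt(sum(m4$W[, a]^2))
  }
  oracle <- vapply(seq_len(p), function(j)
    sqrt(p * sum(ss * wnorm[j, ]^2) / sum(ss)), numeric(1))
  expect_equal(unname(vip_scores(m4)), oracle, tolerance = 1e-10)
  # threshold selection is inclusive
  thr <- sort(vip_scores(m4), decreasing = TRUE)[2]
  expect_true(names(thr) %in% vip_select(m4, threshold = unname(thr)))
})

test_that("cross-validated Q2 never exceeds R2Y on fitted models", {
  set.seed(8)
  for (i in 1:8) {
    n <- 24; p <- sample(5:10, 1)
    x <- matrix(rnorm(n * p), n)
    lb <- rep(c("a", "b"), each = n / 2)
    x[lb == "b", 1] <- x[lb == "b", 1] + runif(1, 0, 3)
    m <- fit_plsda(x, lb, ncomp = 2)
    expect_lte(m$Q2[m$ncomp], m$R2Y[m$ncomp] + 1e-10)
  }
})

test_that("permutation p-values are reproducible and beat all permutations under strong separation", {
  d <- separated_clouds(shift = 5)
  p1 <- permutation_test(d$x, d$labels, ncomp = 2, nperm = 30, seed = 17)
  p2 <- permutation_test(d$x, d$labels, ncomp = 2, nperm = 30, seed = 17)
  expect_identical(p1$p_r2y, p2$p_r2y)
  expect_identical(p1$permuted, p2$permuted)
  expect_equal(p1$p_q2, 1 / 31) # observed beats every permutation
  expect_error(permutation_test(d$x, d$labels, nperm = 0), "at least 1")
})

test_that("Hotelling flagging catches a planted outlier and runs at the minimal size", {
  d <- separated_clouds()
  sd1 <- apply(d$x, 2, sd)
  x <- rbind(d$x, outlier = colMeans(d$x) + 10 * sd1)
  m <- fit_plsda(x, c(d$labels, "a"), ncomp = 2)
  fl <- hotelling_outliers(m, alpha = 0.05)
  expect_true("outlier" %in% fl)
  # boundary n = ncomp + 2
  set.seed(10)
  xm <- matrix(rnorm(4 * 3), 4)
  mm <- fit_plsda(xm, c("a", "a", "b", "b"), ncomp = 2, cv_folds = 2)
  expect_no_error(hotelling_outliers(mm))
})

test_that("prediction recovers the training classes under clear separation", {
  d <- separated_clouds()
  m <- fit_plsda(d$x, d$labels, ncomp = 2)
  pr <- predict(m, d$x)
  expect_identical(as.character(pr$class), d$labels)
  expect_identical(dim(pr$scores), dim(m$T))
})
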