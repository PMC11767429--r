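#' Partial least-squares discriminant analysis
#'
#' Fits a PLS-DA model by NIPALS on the one-hot class response. Features
#' are mean-centered and unit-variance scaled internally; constant
#' features are dropped with a warning. Model quality is summarized by
#' the cumulative explained response variance R2Y(cum) and the
#' cross-validated predicted variance Q2(cum), the latter from
#' deterministic class-stratified k-fold cross-validation (7 folds by
#' default, the common chemometrics setting).
#'
#' @param x Numeric matrix, samples x features.
#' @param labels Class label per sample (2 or more classes, each with at
#'   least 2 samples).
#' @param ncomp Number of latent components (default 2, the number
#'   typically plotted).
#' @param cv_folds Folds for the Q2 cross-validation; set to 0 to skip.
#' @return Object of class `plsda`: scores `T`, weights `W`, X-loadings
#'   `P`, Y-loadings `Q`, `R2Y`/`Q2` cumulative vectors, per-feature
#'   `vip`, per-sample Hotelling `T2`, scaling constants and the class
#'   design.
#' @seealso [vip_scores()], [permutation_test()], [hotelling_outliers()]
#' @export
fit_plsda <- function(x, labels, ncomp = 2L, cv_folds = 7L) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric")
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  if (length(labels) != nrow(x)) stop("labels must match rows of x")
  small <- table(labels) < 2L
  if (any(small))
    stop("class with fewer than 2 samples: ",
         paste(names(small)[small], collapse = ", "))
  if (is.null(colnames(x))) colnames(x) <- paste0("feat", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant feature(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) == 0L) stop("no non-constant features left")
  ncomp <- min(ncomp, ncol(x), nrow(x) - 1L)

  centers <- colMeans(x)
  scales <- apply(x, 2L, stats::sd)
  xs <- scale(x, center = centers, scale = scales)
  y <- class_dummy(labels)
  ymeans <- colMeans(y)
  ys <- scale(y, center = ymeans, scale = FALSE)

  fit <- nipals_pls(xs, ys, ncomp)
  ncomp <- fit$ncomp
  tss_y <- sum(ys^2)
  r2y <- 1 - fit$rss / tss_y

  q2 <- rep(NA_real_, ncomp)
  if (cv_folds >= 2L) {
    folds <- stratified_folds(labels, cv_folds)
    press <- numeric(ncomp)
    tss_cv <- 0
    for (f in sort(unique(folds))) {
      tr <- folds != f
      ctr <- colMeans(x[tr, , drop = FALSE])
      str <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
      keep <- str > 0
      xtr <- scale(x[tr, keep, drop = FALSE], ctr[keep], str[keep])
      ytr <- class_dummy(labels[tr], levels(labels))
      ymtr <- colMeans(ytr)
      ftr <- nipals_pls(xtr, scale(ytr, ymtr, FALSE), ncomp)
      xte <- scale(x[!tr, keep, drop = FALSE], ctr[keep], str[keep])
      yte <- class_dummy(labels[!tr], levels(labels))
      for (a in seq_len(ncomp)) {
        aa <- min(a, ftr$ncomp)
        pred <- xte %*% pls_coef(ftr, aa)
        press[a] <- press[a] + sum((scale(yte, ymtr, FALSE) - pred)^2)
      }
      tss_cv <- tss_cv + sum(scale(yte, ymtr, FALSE)^2)
    }
    q2 <- 1 - press / tss_cv
  }

  vip <- vip_from_fit(fit)
  t2 <- hotelling_t2(fit$T)

  structure(list(ncomp = ncomp, T = fit$T, W = fit$W, P = fit$P, Q = fit$Q,
                 R2Y = r2y, Q2 = q2, vip = vip, T2 = t2,
                 labels = labels, centers = centers, scales = scales,
                 features = colnames(x), ymeans = ymeans,
                 call = match.call()),
            class = "plsda")
}

# one-hot dummy response for a factor
class_dummy <- function(labels, lev = levels(labels)) {
  labels <- factor(labels, levels = lev)
  y <- matrix(0, length(labels), length(lev),
              dimnames = list(NULL, lev))
  y[cbind(seq_along(labels), as.integer(labels))] <- 1
  y
}

# deterministic class-stratified fold assignment (no RNG)
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    folds[idx] <- (seq_along(idx) - 1L) %% k + 1L
  }
  folds
}

# NIPALS PLS2 on pre-scaled E (X) and F (Y)
nipals_pls <- function(E, F_, ncomp, tol = 1e-10, max_iter = 500L) {
  n <- nrow(E); p <- ncol(E); q <- ncol(F_)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  T_ <- matrix(0, n, ncomp); Q <- matrix(0, q, ncomp)
  a <- 0L
  for (comp in seq_len(ncomp)) {
    u <- F_[, which.max(colSums(F_^2))]
    t_old <- rep(0, n)
    for (i in seq_len(max_iter)) {
      w <- crossprod(E, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) break
      w <- w / nw
      t_ <- E %*% w
      qv <- crossprod(F_, t_) / sum(t_^2)
      u <- F_ %*% qv / sum(qv^2)
      if (sum((t_ - t_old)^2) < tol * sum(t_^2)) break
      t_old <- t_
    }
    if (nw < 1e-12 || sum(t_^2) < 1e-12) break
    p_ <- crossprod(E, t_) / sum(t_^2)
    E <- E - t_ %*% t(p_)
    F_ <- F_ - t_ %*% t(qv)
    a <- comp
    W[, a] <- w; P[, a] <- p_; T_[, a] <- t_; Q[, a] <- qv
  }
  if (a == 0L) stop("NIPALS failed: no extractable component")
  keep <- seq_len(a)
  rss <- numeric(a)
  # residual Y sum of squares after each component, recomputed cumulatively
  list(W = W[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
       T = structure(T_[, keep, drop = FALSE],
                     dimnames = list(rownames(E), paste0("comp", keep))),
       Q = Q[, keep, drop = FALSE], ncomp = a,
       rss = cumulative_rss(T_[, keep, drop = FALSE], Q[, keep, drop = FALSE],
                            F_, a))
}

# RSS of Y after 1..a components; F_resid is Y deflated by all a components
cumulative_rss <- function(T_, Q, F_resid, a) {
  rss <- numeric(a)
  resid <- F_resid
  # rebuild backwards: residual after k comps = resid + sum_{j>k} t_j q_j'
  for (k in rev(seq_len(a))) {
    rss[k] <- sum(resid^2)
    resid <- resid + T_[, k] %*% t(Q[, k])
  }
  rss
}

# regression coefficients on the scaled scale using the first a components
pls_coef <- function(fit, a = fit$ncomp) {
  W <- fit$W[, seq_len(a), drop = FALSE]
  P <- fit$P[, seq_len(a), drop = FALSE]
  Q <- fit$Q[, seq_len(a), drop = FALSE]
  W %*% solve(crossprod(P, W)) %*% t(Q)
}

vip_from_fit <- function(fit) {
  p <- nrow(fit$W)
  ss <- colSums(fit$T^2) * colSums(fit$Q^2)
  w2 <- sweep(fit$W^2, 2L, colSums(fit$W^2), "/")
  vip <- sqrt(p * as.vector(w2 %*% ss) / sum(ss))
  stats::setNames(vip, rownames(fit$W))
}

hotelling_t2 <- function(T_) {
  v <- apply(T_, 2L, stats::var)
  rowSums(sweep(T_^2, 2L, v, "/"))
}

#' Variable importance in the projection
#'
#' VIP of feature j over the A fitted components:
#' \deqn{VIP_j = \sqrt{P \sum_a SS_a (w_{ja}/\|w_a\|)^2 / \sum_a SS_a}}
#' with \eqn{SS_a} the response variance captured by component a. The
#' mean of the squared VIPs equals 1 by construction.
#'
#' @param m A fitted [fit_plsda()] model.
#' @return Named numeric vector of VIP scores per feature.
#' @export
vip_scores <- function(m) {
  stopifnot(inherits(m, "plsda"))
  stats::setNames(m$vip, m$features)
}

#' Select discriminant features by VIP threshold
#'
#' @param m A fitted [fit_plsda()] model.
#' @param threshold Inclusive VIP cutoff; the conventional biomarker
#'   screen uses 1.2.
#' @return Character vector of features with `VIP >= threshold`.
#' @export
vip_select <- function(m, threshold = 1.2) {
  v <- vip_scores(m)
  names(v)[v >= threshold]
}

#' Permutation validation of a PLS-DA model
#'
#' Refits the model under random permutations of the class labels and
#' compares the observed R2Y(cum) and Q2(cum) against the permutation
#' distribution. P-values use the add-one correction
#' `p = (1 + #\{permuted >= observed\}) / (1 + nperm)`.
#'
#' @param x Feature matrix, samples x features.
#' @param labels Class labels.
#' @param ncomp Components, as in [fit_plsda()].
#' @param nperm Number of permutations (500 in the standard protocol).
#' @param seed RNG seed; results are exactly reproducible for a fixed
#'   seed.
#' @param cv_folds Folds for Q2.
#' @return List with `p_r2y`, `p_q2`, the observed statistics and the
#'   permutation null draws.
#' @export
permutation_test <- function(x, labels, ncomp = 2L, nperm = 500L, seed = 1L,
                             cv_folds = 7L) {
  if (nperm < 1L) stop("nperm must be at least 1")
  obs <- fit_plsda(x, labels, ncomp, cv_folds)
  r2_obs <- obs$R2Y[obs$ncomp]
  q2_obs <- obs$Q2[obs$ncomp]
  set.seed(seed)
  perm <- matrix(NA_real_, nperm, 2L, dimnames = list(NULL, c("R2Y", "Q2")))
  for (b in seq_len(nperm)) {
    lb <- sample(labels)
    fit <- tryCatch(suppressWarnings(fit_plsda(x, lb, ncomp, cv_folds)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    perm[b, ] <- c(fit$R2Y[fit$ncomp], fit$Q2[fit$ncomp])
  }
  ok <- stats::complete.cases(perm)
  list(p_r2y = (1 + sum(perm[ok, "R2Y"] >= r2_obs)) / (1 + sum(ok)),
       p_q2 = (1 + sum(perm[ok, "Q2"] >= q2_obs)) / (1 + sum(ok)),
       observed = c(R2Y = r2_obs, Q2 = q2_obs),
       permuted = perm[ok, , drop = FALSE])
}

#' Hotelling T-squared outlier flagging
#'
#' Computes the per-sample T2 statistic from the model scores and flags
#' samples exceeding the F-distribution confidence limit
#' `A(n-1)/(n-A) * F(1-alpha; A, n-A)`. Flagged samples are reported,
#' never silently removed; refitting after exclusion is an explicit
#' second call.
#'
#' @param m A fitted [fit_plsda()] model with at least `ncomp + 2`
#'   samples.
#' @param alpha Significance level; 0.05 gives the usual 95% limit.
#' @return Character vector of flagged sample names, with attributes
#'   `t2` (all statistics) and `limit`.
#' @export
hotelling_outliers <- function(m, alpha = 0.05) {
  stopifnot(inherits(m, "plsda"))
  n <- nrow(m$T); a <- m$ncomp
  if (n < a + 2L) stop("need at least ncomp + 2 samples")
  lim <- a * (n - 1) / (n - a) * stats::qf(1 - alpha, a, n - a)
  flagged <- rownames(m$T)[m$T2 > lim]
  structure(flagged, t2 = m$T2, limit = lim)
}

#' @export
print.plsda <- function(x, ...) {
  cat("PLS-DA model:", x$ncomp, "components,", length(x$features),
      "features,", nlevels(x$labels), "classes\n")
  cat("  R2Y(cum):", paste(sprintf("%.3f", x$R2Y), collapse = " "), "\n")
  if (!all(is.na(x$Q2)))
    cat("  Q2(cum): ", paste(sprintf("%.3f", x$Q2), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.plsda <- function(object, vip_threshold = 1.2, ...) {
  cat("PLS-DA fit of", nrow(object$T), "samples,", length(object$features),
      "features,", nlevels(object$labels), "classes (",
      paste(levels(object$labels), collapse = ", "), ")\n")
  tab <- data.frame(component = seq_len(object$ncomp),
                    R2Y_cum = object$R2Y, Q2_cum = object$Q2)
  print(tab, row.names = FALSE, digits = 3)
  cat("Features with VIP >=", vip_threshold, ":",
      length(vip_select(object, vip_threshold)), "\n")
  invisible(object)
}

#' @export
coef.plsda <- function(object, ...) {
  b <- pls_coef(object)
  dimnames(b) <- list(object$features, levels(object$labels))
  b
}

#' Predict class membership from a PLS-DA model
#'
#' @param object A fitted [fit_plsda()] model.
#' @param newdata Matrix of new samples (same features).
#' @param ... Unused.
#' @return List with `scores` (projected latent scores), `y` (predicted
#'   dummy response) and `class` (argmax class).
#' @export
predict.plsda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, object$features, drop = FALSE]
  xs <- scale(newdata, object$centers[object$features],
              object$scales[object$features])
  rot <- object$W %*% solve(crossprod(object$P, object$W))
  scores <- xs %*% rot
  yhat <- xs %*% pls_coef(object)
  yhat <- sweep(yhat, 2L, object$ymeans, "+")
  colnames(yhat) <- levels(object$labels)
  list(scores = scores, y = yhat,
       class = factor(levels(object$labels)[max.col(yhat)],
                      levels = levels(object$labels)))
}

#' @export
plot.plsda <- function(x, comps = c(1L, 2L), ...) {
  comps <- comps[comps <= x$ncomp]
  if (length(comps) < 2L) stop("need two fitted components to plot")
  graphics::plot(x$T[, comps[1L]], x$T[, comps[2L]],
                 col = as.integer(x$labels), pch = 19,
                 xlab = paste0("Component ", comps[1L]),
                 ylab = paste0("Component ", comps[2L]), ...)
  graphics::legend("topright", legend = levels(x$labels),
                   col = seq_len(nlevels(x$labels)), pch = 19, bty = "n")
  invisible(x)
}
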