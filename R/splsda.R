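# Sparse PLS-DA for two-class problems, written for allele-fraction
# matrices: feature standardization over observed entries, NIPALS-style
# fitting that tolerates NA in the training data (inner products over
# observed entries rescaled by the ratio of total to observed counts),
# per-component sparse weight vectors with exactly K nonzeros obtained by
# soft-thresholding, and prediction with the group-mean-mean imputation
# rule for NA test entries.

#' Per-feature standardization parameters from training data
#'
#' Mean and standard deviation per feature over the observed (non-`NA`)
#' entries. Features with zero variance (or fewer than two observed
#' values) are flagged `constant`; they standardize to zeros and are never
#' selectable by the sparse fit.
#'
#' @param x Numeric matrix, samples x features, `NA` allowed.
#' @return List with `mean`, `sd`, `constant` (logical), `n_obs`.
#' @export
standardize_fit <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  obs <- !is.na(x)
  n_obs <- colSums(obs)
  x0 <- x
  x0[!obs] <- 0
  mu <- colSums(x0) / pmax(n_obs, 1)
  ss <- colSums(x0^2) - n_obs * mu^2
  v <- ss / pmax(n_obs - 1, 1)
  v[v < 0] <- 0
  s <- sqrt(v)
  constant <- n_obs < 2 | s < sqrt(.Machine$double.eps)
  list(mean = mu, sd = s, constant = constant, n_obs = n_obs)
}

#' Apply standardization parameters
#'
#' @param x Numeric matrix, samples x features, `NA` allowed.
#' @param par Parameters from [standardize_fit()].
#' @return Standardized matrix; `NA` entries stay `NA`; constant features
#'   become zero on observed entries.
#' @export
standardize_apply <- function(x, par) {
  stopifnot(ncol(x) == length(par$mean))
  s <- ifelse(par$constant, 1, par$sd)
  z <- sweep(sweep(x, 2, par$mean, "-"), 2, s, "/")
  if (any(par$constant)) {
    zc <- z[, par$constant, drop = FALSE]
    zc[!is.na(zc)] <- 0
    z[, par$constant] <- zc
  }
  z
}

# Exactly-k sparsification by soft-thresholding at the (k+1)-th largest
# |w|; survivors are shrunk by the threshold. The kept set is the first k
# features ordered by (|w| desc, index asc). When ties straddle the k-th
# position the threshold drops to the largest |w| strictly below the kept
# minimum so kept entries are not shrunk to zero.
.sparsify <- function(w, k) {
  p <- length(w)
  k <- min(k, p)
  if (k == p) return(w)
  ord <- order(-abs(w), seq_len(p))
  keep <- ord[seq_len(k)]
  lam <- max(abs(w[ord[(k + 1L):p]]))
  kept_min <- min(abs(w[keep]))
  if (lam >= kept_min && lam > 0) {
    below <- abs(w)[abs(w) < kept_min]
    lam <- if (length(below)) max(below) else 0
  }
  out <- numeric(p)
  out[keep] <- sign(w[keep]) * (abs(w[keep]) - lam)
  out
}

# Core fit on an already-standardized matrix. z: n x p (NA allowed),
# y: two-level factor. Returns component matrices plus the y-side pieces
# needed for prediction.
.splsda_core <- function(z, y, keep_k, n_components, tol = 1e-9,
                         max_iter = 100L) {
  n <- nrow(z)
  p <- ncol(z)
  g <- cbind(as.numeric(y == levels(y)[1L]), as.numeric(y == levels(y)[2L]))
  y_means <- colMeans(g)
  yc <- sweep(g, 2, y_means)
  obs <- !is.na(z)
  z0 <- z
  z0[!obs] <- 0
  robs <- pmax(rowSums(obs), 1)
  cobs <- pmax(colSums(obs), 1)
  all_obs <- all(obs)

  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  D <- matrix(0, 2, n_components)
  for (h in seq_len(n_components)) {
    u <- yc[, 2L]
    w_old <- rep(Inf, p)
    w <- t_h <- NULL
    for (it in seq_len(max_iter)) {
      w <- as.vector(crossprod(z0, u))
      if (!all_obs) w <- w * (n / cobs)
      if (all(w == 0)) break
      w <- .sparsify(w, keep_k)
      w <- w / sqrt(sum(w^2))
      t_h <- as.vector(z0 %*% w)
      if (!all_obs) t_h <- t_h * (p / robs)
      b <- as.vector(crossprod(yc, t_h)) / sum(t_h^2)
      u <- as.vector(yc %*% b) / sum(b^2)
      if (sum((w - w_old)^2) < tol) break
      w_old <- w
    }
    if (is.null(w) || all(w == 0)) break
    # NA-aware x-loadings: per feature, regression of observed z on t
    if (all_obs) {
      denom <- sum(t_h^2)
      cvec <- as.vector(crossprod(z0, t_h)) / denom
    } else {
      denom <- as.vector(crossprod(obs, t_h^2))
      denom[denom == 0] <- 1
      cvec <- as.vector(crossprod(z0, t_h)) / denom
    }
    d <- as.vector(crossprod(yc, t_h)) / sum(t_h^2)
    z0 <- z0 - (tcrossprod(t_h, cvec)) * obs
    yc <- yc - tcrossprod(t_h, d)
    W[, h] <- w
    P[, h] <- cvec
    Tm[, h] <- t_h
    D[, h] <- d
  }
  list(weights = W, x_loadings = P, scores = Tm, y_coef = D,
       y_means = y_means)
}

#' Fit a sparse PLS-DA model
#'
#' Fits a two-class sparse PLS-DA: the class membership is dummy-coded and
#' column-centered, features are centered and scaled using their observed
#' training entries, and each component retains exactly `keep_k` features
#' via soft-thresholding of the dense weight vector at the (K+1)-th
#' largest absolute weight. Training data may contain `NA` (sub-threshold
#' coverage); inner products are taken over observed entries and rescaled
#' by total/observed counts.
#'
#' @param x An [snv_matrix()] with labels, or a numeric matrix
#'   (samples x features) on the original allele-fraction scale.
#' @param y Two-level factor of group labels (ignored when `x` is a
#'   labelled `snv_matrix`).
#' @param keep_k Number of features with nonzero weight per component.
#' @param n_components Number of latent components (default 1; one
#'   component is the natural discriminant for a two-class problem).
#' @return An object of class `splsda` carrying sparse weights, x-loadings,
#'   training scores, y-side regression coefficients, standardization
#'   parameters, and the per-group standardized feature means used for
#'   test-set imputation.
#' @export
fit_splsda <- function(x, y = NULL, keep_k, n_components = 1L) {
  if (inherits(x, "snv_matrix")) {
    if (is.null(y)) y <- x$labels
    x <- t(x$values)
  }
  stopifnot(is.matrix(x))
  if (is.null(y)) stop("group labels are required (labelled snv_matrix or y)")
  y <- droplevels(factor(y))
  if (nlevels(y) != 2L) stop("exactly two groups are required; got ",
                             nlevels(y))
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  p <- ncol(x)
  if (keep_k < 1) stop("keep_k must be >= 1")
  if (keep_k > p) {
    warning("keep_k = ", keep_k, " exceeds the ", p,
            " available features; clamped")
    keep_k <- p
  }
  par <- standardize_fit(x)
  z <- standardize_apply(x, par)
  core <- .splsda_core(z, y, keep_k, n_components)

  # per-group means of standardized training values (observed entries),
  # for the test-set NA fill: (mean_A + mean_B) / 2
  gm <- .group_means_std(z, y)
  model <- structure(
    list(
      weights = core$weights, x_loadings = core$x_loadings,
      scores = core$scores, y_coef = core$y_coef, y_means = core$y_means,
      keep_k = keep_k, n_components = n_components,
      standardization = par,
      group_means_std = gm$means, na_fill = gm$fill,
      groups = levels(y), prevalence = as.vector(table(y)) / length(y),
      feature_names = colnames(x), decision_rule = "max.dist"
    ),
    class = "splsda"
  )
  model
}

.group_means_std <- function(z, y) {
  lv <- levels(y)
  mean_obs <- function(rows) {
    zz <- z[rows, , drop = FALSE]
    o <- !is.na(zz)
    zz[!o] <- 0
    colSums(zz) / pmax(colSums(o), 1)
  }
  m_a <- mean_obs(y == lv[1L])
  m_b <- mean_obs(y == lv[2L])
  n_a <- colSums(!is.na(z[y == lv[1L], , drop = FALSE]))
  n_b <- colSums(!is.na(z[y == lv[2L], , drop = FALSE]))
  # a group with no observed training value falls back to the other group
  none_a <- n_a == 0
  none_b <- n_b == 0
  if (any(none_a | none_b)) {
    message(sum(none_a | none_b),
            " feature(s) unobserved in one group; imputation falls back ",
            "to the other group's mean")
    m_a[none_a] <- m_b[none_a]
    m_b[none_b] <- m_a[none_b]
  }
  means <- cbind(m_a, m_b)
  colnames(means) <- lv
  list(means = means, fill = (m_a + m_b) / 2)
}

#' @export
print.splsda <- function(x, ...) {
  nz <- colSums(x$weights != 0)
  cat("sparse PLS-DA model:", length(x$feature_names) %||% nrow(x$weights),
      "features,", x$n_components, "component(s), keep_k =", x$keep_k, "\n")
  cat("  groups:", paste(x$groups, collapse = " vs "), "\n")
  cat("  nonzero weights per component:", paste(nz, collapse = ", "), "\n")
  invisible(x)
}

#' Impute `NA` entries of a standardized test matrix
#'
#' Every missing value of feature `f` is replaced by the mean of the two
#' training-group means of the centered and standardized values of `f`
#' (computed on the training set only). Observed entries are untouched.
#'
#' @param x_std Standardized test matrix (samples x features), `NA`
#'   allowed.
#' @param model A fitted [fit_splsda()] model.
#' @return The matrix with `NA` filled.
#' @export
impute_test_na <- function(x_std, model) {
  stopifnot(inherits(model, "splsda"), ncol(x_std) == length(model$na_fill))
  na <- which(is.na(x_std), arr.ind = TRUE)
  if (nrow(na)) x_std[na] <- model$na_fill[na[, 2L]]
  x_std
}

#' Predict group membership with a sparse PLS-DA model
#'
#' New data on the original allele-fraction scale is standardized with the
#' training parameters, `NA` entries are imputed via [impute_test_na()],
#' and the continuous score is the predicted dummy value of the second
#' group minus that of the first (max.dist rule); a sample is called for
#' the second group when its score is positive, with ties going to the
#' group with larger training prevalence.
#'
#' @param object A fitted [fit_splsda()] model.
#' @param newdata Numeric matrix (samples x features, original scale) or an
#'   [snv_matrix()]; features must match the training features.
#' @param ... Unused.
#' @return List with `score` (numeric) and `label` (factor over the
#'   training groups).
#' @export
predict.splsda <- function(object, newdata, ...) {
  if (inherits(newdata, "snv_matrix")) newdata <- t(newdata$values)
  stopifnot(is.matrix(newdata))
  if (!is.null(colnames(newdata)) && !is.null(object$feature_names)) {
    miss <- setdiff(object$feature_names, colnames(newdata))
    if (length(miss)) {
      stop("newdata is missing training feature(s): ",
           paste(head(miss, 5L), collapse = ", "),
           if (length(miss) > 5L) ", ...")
    }
    newdata <- newdata[, object$feature_names, drop = FALSE]
  } else if (ncol(newdata) != nrow(object$weights)) {
    stop("newdata has ", ncol(newdata), " features; model expects ",
         nrow(object$weights))
  }
  z <- standardize_apply(newdata, object$standardization)
  z <- impute_test_na(z, object)
  n <- nrow(z)
  yhat <- matrix(object$y_means, n, 2L, byrow = TRUE)
  for (h in seq_len(object$n_components)) {
    t_h <- as.vector(z %*% object$weights[, h])
    z <- z - tcrossprod(t_h, object$x_loadings[, h])
    yhat <- yhat + tcrossprod(t_h, object$y_coef[, h])
  }
  score <- yhat[, 2L] - yhat[, 1L]
  tie_group <- object$groups[which.max(object$prevalence)]
  label <- ifelse(score > 0, object$groups[2L],
                  ifelse(score < 0, object$groups[1L], tie_group))
  list(score = score, label = factor(label, levels = object$groups))
}

#' Features selected by a sparse PLS-DA model
#'
#' @param model A fitted [fit_splsda()] model.
#' @param component Component index (default 1).
#' @return Data.frame of selected features with their weights, ordered by
#'   absolute weight (ties broken by feature index).
#' @export
selected_features <- function(model, component = 1L) {
  stopifnot(inherits(model, "splsda"))
  w <- model$weights[, component]
  idx <- which(w != 0)
  idx <- idx[order(-abs(w[idx]), idx)]
  data.frame(
    feature = if (is.null(model$feature_names)) as.character(idx) else
      model$feature_names[idx],
    index = idx, component = component,
    loading = w[idx], abs_loading = abs(w[idx]),
    stringsAsFactors = FALSE
  )
}
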