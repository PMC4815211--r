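# Model selection and evaluation: stratified repeated K-fold designs,
# nested cross-validation over a grid of sparsity values K with the
# optimum taken at the mode of a kernel density over selected Ks,
# repeated-CV performance summaries, and the label-permutation test.

#' Cross-validation design
#'
#' @param n_folds Number of folds (default 10).
#' @param n_repeats Number of repeated cross-validations (default 15).
#' @param stratified Stratify folds by class (default `TRUE`); per-fold
#'   class proportions then deviate from the global ones by at most one
#'   sample.
#' @param rng_seed Integer seed making the whole
#'   select/evaluate/permute pipeline reproducible, or `NULL` to use the
#'   current RNG state.
#' @return A list of class `cv_design`.
#' @export
cv_design <- function(n_folds = 10L, n_repeats = 15L, stratified = TRUE,
                      rng_seed = NULL) {
  stopifnot(n_folds >= 2L, n_repeats >= 1L)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 stratified = isTRUE(stratified), rng_seed = rng_seed),
            class = "cv_design")
}

#' Sparsity grid for nested cross-validation
#'
#' The triple (minimum K, maximum K, step): candidate values are
#' `seq(k_min, k_max, by = step)`, clamped to the number of available
#' features at use time.
#'
#' @param k_min,k_max,step Integers, `k_min >= 1`, `step >= 1`.
#' @return A list of class `k_grid`.
#' @export
k_grid <- function(k_min, k_max, step = 1L) {
  stopifnot(k_min >= 1, step >= 1, k_max >= k_min)
  structure(list(k_min = as.integer(k_min), k_max = as.integer(k_max),
                 step = as.integer(step)), class = "k_grid")
}

.grid_values <- function(grid, p) {
  ks <- seq(grid$k_min, grid$k_max, by = grid$step)
  ks <- unique(pmin(ks, p))
  ks[ks >= 1]
}

#' Stratified fold assignment
#'
#' @param y Factor of class labels.
#' @param n_folds Number of folds (clamped to `length(y)`).
#' @param stratified Stratify by class.
#' @return Integer vector of fold ids in `1..n_folds`.
#' @export
make_folds <- function(y, n_folds, stratified = TRUE) {
  n <- length(y)
  n_folds <- min(n_folds, n)
  fold <- integer(n)
  if (stratified) {
    for (lv in levels(factor(y))) {
      idx <- which(y == lv)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(sample.int(n_folds), length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(n_folds), n)
  }
  fold
}

# Folds whose training side would lose a class are re-drawn (rare: only
# when a class has a single member).
.safe_folds <- function(y, n_folds, stratified, max_tries = 25L) {
  for (i in seq_len(max_tries)) {
    fold <- make_folds(y, n_folds, stratified)
    ok <- all(vapply(unique(fold), function(f) {
      length(unique(y[fold != f])) == 2L
    }, TRUE))
    if (ok) return(fold)
  }
  stop("could not build folds whose training sets keep both classes")
}

#' Area under the ROC curve from continuous scores
#'
#' Computed as the Mann-Whitney pair statistic: the fraction of
#' (positive, negative) pairs in which the positive sample has the larger
#' score, ties counted 1/2. The positive class is the second factor level.
#'
#' @param scores Numeric scores.
#' @param labels Two-level factor (or coercible).
#' @return AUC in `[0, 1]`.
#' @export
auc_of_scores <- function(scores, labels) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2L) {
    stop("AUC is undefined unless both classes are present")
  }
  pos <- labels == levels(labels)[2L]
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.as_xy <- function(x, y) {
  if (inherits(x, "snv_matrix")) {
    if (is.null(y)) y <- x$labels
    x <- t(x$values)
  }
  if (is.null(y)) stop("group labels are required")
  y <- droplevels(factor(y))
  if (nlevels(y) != 2L) stop("exactly two groups are required")
  list(x = x, y = y)
}

# One K-fold CV at a fixed K: returns pooled test scores/labels/calls in
# sample order.
.cv_scores <- function(x, y, k, n_folds, stratified) {
  fold <- .safe_folds(y, n_folds, stratified)
  score <- numeric(length(y))
  call <- character(length(y))
  for (f in unique(fold)) {
    te <- fold == f
    fit <- fit_splsda(x[!te, , drop = FALSE], y[!te], keep_k = k)
    pr <- predict(fit, x[te, , drop = FALSE])
    score[te] <- pr$score
    call[te] <- as.character(pr$label)
  }
  list(score = score, call = factor(call, levels = levels(y)), truth = y)
}

#' Select the sparsity K by nested cross-validation
#'
#' For each outer fold of each repeat, an inner cross-validation on the
#' outer-training set evaluates every candidate K (pooled inner-test AUC);
#' the best K (ties to the smallest) is recorded. The optimum is the mode
#' of a Gaussian kernel density over all recorded Ks (see
#' [optimal_k_from_density()]).
#'
#' @param x An [snv_matrix()] with labels, or samples x features matrix.
#' @param grid A [k_grid()].
#' @param design A [cv_design()] for the outer loop (default fifteen
#'   10-fold cross-validations).
#' @param y Labels when `x` is a bare matrix.
#' @param inner_folds Folds of the inner cross-validation (default the
#'   outer fold count).
#' @return List of class `k_selection` with `selected_ks` (one per outer
#'   fold per repeat), the kernel `density`, and `optimal_k`.
#' @export
nested_cv_select_k <- function(x, grid, design = cv_design(), y = NULL,
                               inner_folds = design$n_folds) {
  d <- .as_xy(x, y)
  x <- d$x
  y <- d$y
  if (!is.null(design$rng_seed)) set.seed(design$rng_seed)
  ks <- .grid_values(grid, ncol(x))
  if (!length(ks)) stop("empty K grid")
  selected <- numeric(0)
  for (r in seq_len(design$n_repeats)) {
    fold <- .safe_folds(y, design$n_folds, design$stratified)
    for (f in sort(unique(fold))) {
      tr <- fold != f
      x_tr <- x[tr, , drop = FALSE]
      y_tr <- y[tr]
      inner <- .safe_folds(y_tr, min(inner_folds, length(y_tr)),
                           design$stratified)
      aucs <- vapply(ks, function(k) {
        sc <- numeric(length(y_tr))
        for (g in unique(inner)) {
          te <- inner == g
          fit <- fit_splsda(x_tr[!te, , drop = FALSE], y_tr[!te], keep_k = k)
          sc[te] <- predict(fit, x_tr[te, , drop = FALSE])$score
        }
        auc_of_scores(sc, y_tr)
      }, numeric(1))
      best <- ks[which.max(aucs)] # which.max ties -> first = smallest K
      selected <- c(selected, best)
    }
  }
  dens_k <- optimal_k_from_density(selected, k_range = c(grid$k_min, grid$k_max),
                                   return_density = TRUE)
  structure(list(selected_ks = selected, density = dens_k$density,
                 optimal_k = dens_k$optimal_k, grid = grid, design = design),
            class = "k_selection")
}

# Inner fits at a fixed K reuse the fold loop above; the inner loop is the
# hot path of the package, so it stays free of data.frame overhead.

#' Mode of the kernel density over selected K values
#'
#' Gaussian kernel, Silverman rule-of-thumb bandwidth, density evaluated
#' on a 512-point grid spanning the data range plus three bandwidths; the
#' argmax is rounded to the nearest integer and clamped to the tested
#' range.
#'
#' @param selected_ks Numeric vector of selected K values (nonempty).
#' @param k_range Optional `c(min, max)` clamp for the optimum.
#' @param return_density Also return the density object.
#' @return The optimal K (integer), or a list with `optimal_k` and
#'   `density` when `return_density = TRUE`.
#' @export
optimal_k_from_density <- function(selected_ks, k_range = NULL,
                                   return_density = FALSE) {
  stopifnot(length(selected_ks) >= 1)
  if (length(unique(selected_ks)) == 1L) {
    opt <- round(selected_ks[1L])
    dens <- list(x = selected_ks[1L], y = 1)
  } else {
    dens <- stats::density(selected_ks, bw = "nrd0", kernel = "gaussian",
                           n = 512L, cut = 3)
    opt <- round(dens$x[which.max(dens$y)])
  }
  if (!is.null(k_range)) opt <- min(max(opt, k_range[1L]), k_range[2L])
  if (return_density) list(optimal_k = opt, density = dens) else opt
}

#' Evaluate a model at a fixed K by repeated cross-validation
#'
#' Per repeat, all folds are trained at `keep_k = k` and the test scores
#' pooled over folds give one AUC, one predictive accuracy and one
#' sensitivity per group; the summary averages over repeats with a normal
#' 95% confidence interval for the AUC (`mean +/- 1.96 sd/sqrt(repeats)`).
#'
#' @param x An [snv_matrix()] with labels, or samples x features matrix.
#' @param k Sparsity (number of retained features).
#' @param design A [cv_design()].
#' @param y Labels when `x` is a bare matrix.
#' @return List of class `performance_summary`: `auc_mean`, `auc_ci_low`,
#'   `auc_ci_high`, `predictive_accuracy`, `sensitivity` (named per
#'   group), and the per-repeat metric vectors.
#' @export
evaluate_model <- function(x, k, design = cv_design(), y = NULL) {
  d <- .as_xy(x, y)
  x <- d$x
  y <- d$y
  if (!is.null(design$rng_seed)) set.seed(design$rng_seed)
  lv <- levels(y)
  aucs <- acc <- numeric(design$n_repeats)
  sens <- matrix(0, design$n_repeats, 2L, dimnames = list(NULL, lv))
  for (r in seq_len(design$n_repeats)) {
    cv <- .cv_scores(x, y, k, design$n_folds, design$stratified)
    aucs[r] <- auc_of_scores(cv$score, cv$truth)
    correct <- cv$call == cv$truth
    acc[r] <- mean(correct)
    sens[r, 1L] <- mean(correct[cv$truth == lv[1L]])
    sens[r, 2L] <- mean(correct[cv$truth == lv[2L]])
  }
  m <- mean(aucs)
  half <- 1.96 * stats::sd(aucs) / sqrt(design$n_repeats)
  if (is.na(half)) half <- 0
  structure(list(
    auc_mean = m, auc_ci_low = max(0, m - half), auc_ci_high = min(1, m + half),
    predictive_accuracy = mean(acc),
    sensitivity = colMeans(sens),
    per_repeat = list(auc = aucs, accuracy = acc, sensitivity = sens),
    k = k, design = design, groups = lv
  ), class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("repeated-CV performance at K = %d (%d x %d-fold)\n",
              x$k, x$design$n_repeats, x$design$n_folds))
  cat(sprintf("  AUC %.3f [%.3f-%.3f]  accuracy %.3f\n", x$auc_mean,
              x$auc_ci_low, x$auc_ci_high, x$predictive_accuracy))
  cat(sprintf("  sensitivity: %s %.3f, %s %.3f\n", x$groups[1L],
              x$sensitivity[1L], x$groups[2L], x$sensitivity[2L]))
  invisible(x)
}

#' Label-permutation significance test of the cross-validated AUC
#'
#' For each permutation the group labels are shuffled and one K-fold
#' cross-validation (fresh fold split) is trained and tested at the same
#' K as the true model; the p-value is the fraction of permutations whose
#' AUC reaches the true AUC.
#'
#' @param x An [snv_matrix()] with labels, or samples x features matrix.
#' @param k Sparsity used by the true model.
#' @param true_auc The true model's cross-validated AUC.
#' @param n_perm Number of permutations (default 1000).
#' @param design A [cv_design()]; only `n_folds`/`stratified`/`rng_seed`
#'   are used (one CV per permutation).
#' @param y Labels when `x` is a bare matrix.
#' @return List of class `permutation_test`: `p_value`
#'   (`count(perm >= true)/n_perm`), `p_display` (`"<1/n_perm"` when the
#'   count is zero), `true_auc`, `permuted_aucs`.
#' @export
permutation_test <- function(x, k, true_auc, n_perm = 1000L,
                             design = cv_design(), y = NULL) {
  d <- .as_xy(x, y)
  x <- d$x
  y <- d$y
  stopifnot(n_perm >= 1)
  if (!is.null(design$rng_seed)) set.seed(design$rng_seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    yp <- y[sample.int(length(y))]
    cv <- .cv_scores(x, yp, k, design$n_folds, design$stratified)
    auc_of_scores(cv$score, cv$truth)
  }, numeric(1))
  count <- sum(perm >= true_auc)
  p <- count / n_perm
  structure(list(
    n_perm = as.integer(n_perm), true_auc = true_auc, permuted_aucs = perm,
    p_value = p,
    p_display = if (count == 0) sprintf("<%g", 1 / n_perm) else
      format(p, digits = 3)
  ), class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("permutation test: true AUC %.3f vs %d permutations, p %s\n",
              x$true_auc, x$n_perm, x$p_display))
  invisible(x)
}
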