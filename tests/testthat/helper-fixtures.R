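# Shared fixtures: tiny call files, hand-built matrices, separable
# datasets, and a cached null-calibration simulation reused by the
# calibration and uniformity tests.

write_call_fixture <- function(rows, path = tempfile(fileext = ".bed")) {
  writeLines(rows, path)
  path
}

# matrix with a single perfectly separating feature among noise
separable_matrix <- function(n_per_group = 10, n_noise = 50, seed = 11) {
  set.seed(seed)
  n <- 2 * n_per_group
  x <- matrix(runif(n * (n_noise + 1), 0, 0.5), n, n_noise + 1)
  y <- factor(rep(c("A", "B"), each = n_per_group))
  x[, 1] <- ifelse(y == "B", runif(n, 0.8, 1), runif(n, 0, 0.15))
  colnames(x) <- c("sep", paste0("noise", seq_len(n_noise)))
  list(x = x, y = y)
}

small_snv_matrix <- function() {
  vals <- rbind(
    "chr1:100:A>G" = c(0.5, 0.0, NA, 0.2),
    "chr1:200:C>T" = c(0.0, 0.4, 0.1, NA),
    "chr2:300:G>A" = c(NA, NA, 0.9, 0.8),
    "chr2:400:T>C" = c(0.0, 0.0, 0.0, 0.1)
  )
  colnames(vals) <- paste0("S", 1:4)
  m <- snv_matrix(vals, labels = setNames(factor(c("A", "A", "B", "B")),
                                          colnames(vals)))
  m$annotation$region <- c("exonic", "nonsynonymous_exonic", "intronic", "utr3")
  m$annotation$gene <- c("g1", "g1", "g2", "g3")
  m$annotation$is_editing_site <- c(FALSE, TRUE, TRUE, FALSE)
  m
}

# null-generator permutation p-values, computed once per test run and
# reused by the calibration-rate and KS-uniformity checks
calibration_pvalues <- local({
  cache <- NULL
  function(n_runs = 100, n_perm = 200) {
    if (!is.null(cache)) return(cache)
    p <- vapply(seq_len(n_runs), function(i) {
      ds <- generate_dataset(generator_spec(
        n_per_group = 15, n_features = 80, n_informative = 0,
        na_rate = 0.1, rng_seed = 20000 + i))
      perf <- evaluate_model(ds$matrix, k = 10,
                             cv_design(n_folds = 10, n_repeats = 1,
                                       rng_seed = 30000 + i))
      permutation_test(ds$matrix, k = 10, true_auc = perf$auc_mean,
                       n_perm = n_perm,
                       design = cv_design(n_folds = 10,
                                          rng_seed = 40000 + i))$p_value
    }, numeric(1))
    cache <<- p
    p
  }
})

# small two-model pipeline configuration reused by the artifact and
# determinism tests
pipeline_fixture_config <- function(out_dir, seed = 5, make_plots = FALSE) {
  ds <- generate_dataset(generator_spec(n_per_group = 10, n_features = 80,
                                        n_informative = 6, rng_seed = 300))
  run_config(
    matrix = ds$matrix, min_nonzero = 2,
    models = list(all_SNVs = list(regions = NULL, editing_only = FALSE),
                  intronic = list(regions = "intronic",
                                  editing_only = FALSE)),
    grid = k_grid(4, 16, 4),
    design = cv_design(n_folds = 5, n_repeats = 2),
    inner_folds = 3, n_perm = 20, seed = seed, out_dir = out_dir,
    make_plots = make_plots
  )
}

# brute-force O(n^2) pairwise AUC oracle
auc_pairwise_oracle <- function(scores, labels) {
  lv <- levels(factor(labels))
  sp <- scores[labels == lv[2]]
  sn <- scores[labels == lv[1]]
  tot <- 0
  for (i in seq_along(sp)) {
    tot <- tot + sum(sp[i] > sn) + 0.5 * sum(sp[i] == sn)
  }
  tot / (length(sp) * length(sn))
}
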