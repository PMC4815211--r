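# Final all-sample fit and loading-based ranking of selected SNVs, the
# univariate comparators (exact 2x4 group-by-allele Fisher test, Wilcoxon
# rank-sum on allele fractions), a Friedman comparison of rankings, and a
# resampling enrichment null for allele-specific expression.

#' Final fit and loading-based feature ranking
#'
#' Trains a sparse PLS-DA model on all samples at the optimal K and ranks
#' the selected features by the absolute values of their loadings
#' (predictive coefficients), component-major. When `with_univariate` is
#' `TRUE` and `x` is an `snv_matrix`, each selected SNV is annotated with
#' the exact 2x4 Fisher p-value on allele abundance and the Wilcoxon
#' rank-sum p-value on allele fractions; the univariate annotations never
#' alter the multivariate ordering.
#'
#' @param x An [snv_matrix()] with labels, or samples x features matrix.
#' @param optimal_k The tuned sparsity (e.g. from [nested_cv_select_k()]).
#' @param y Labels when `x` is a bare matrix.
#' @param n_components Components of the final fit (default 1).
#' @param with_univariate Attach Fisher/Wilcoxon p-values (default `TRUE`
#'   for `snv_matrix` input).
#' @return Data.frame of class `feature_ranking`: `snv_key`, `component`,
#'   `loading`, `abs_loading`, `rank`, `gene`, `region`, `fisher_p`,
#'   `wilcoxon_p`.
#' @export
final_rank <- function(x, optimal_k, y = NULL, n_components = 1L,
                       with_univariate = inherits(x, "snv_matrix")) {
  m <- if (inherits(x, "snv_matrix")) x else NULL
  model <- fit_splsda(x, y, keep_k = optimal_k, n_components = n_components)
  parts <- lapply(seq_len(n_components), function(h) {
    sf <- selected_features(model, h)
    if (nrow(sf) == 0) return(NULL)
    data.frame(snv_key = sf$feature, component = h, loading = sf$loading,
               abs_loading = sf$abs_loading, index = sf$index,
               stringsAsFactors = FALSE)
  })
  rk <- do.call(rbind, parts)
  rk$rank <- seq_len(nrow(rk))
  rk$gene <- NA_character_
  rk$region <- NA_character_
  rk$fisher_p <- NA_real_
  rk$wilcoxon_p <- NA_real_
  if (!is.null(m)) {
    i <- match(rk$snv_key, m$annotation$snv_key)
    rk$gene <- m$annotation$gene[i]
    rk$region <- m$annotation$region[i]
    if (with_univariate) {
      lv <- levels(m$labels)
      for (j in seq_len(nrow(rk))) {
        af <- m$values[i[j], ]
        tab <- allele_count_table(af, m$labels, m$annotation$ref[i[j]],
                                  m$annotation$alt[i[j]])
        rk$fisher_p[j] <- tryCatch(fisher_exact_2x4(tab), error = function(e) NA_real_)
        a <- af[m$labels == lv[1L]]
        b <- af[m$labels == lv[2L]]
        rk$wilcoxon_p[j] <- tryCatch(wilcoxon_af(a, b), error = function(e) NA_real_)
      }
    }
  }
  rk$index <- NULL
  class(rk) <- c("feature_ranking", "data.frame")
  rk
}

#' Group-by-allele count table for one SNV locus
#'
#' A 2 (groups) x 4 (A, C, G, T) table counting, per group, the samples
#' with detectable reads for each allele at the locus, disregarding
#' samples with sub-threshold coverage (`NA` entries). Given adequate
#' coverage, the reference allele is detectable when the allele fraction
#' is below 1 and the variant allele when it is above 0, so a sample can
#' contribute to both of its alleles' columns.
#'
#' @param af Allele fractions across samples (`NA` = sub-threshold
#'   coverage).
#' @param labels Two-level factor of group labels.
#' @param ref,alt Reference and variant base (`"A"`, `"C"`, `"G"`, `"T"`).
#' @return Integer matrix, 2 x 4, rows named by group, columns A, C, G, T.
#' @export
allele_count_table <- function(af, labels, ref, alt) {
  labels <- droplevels(factor(labels))
  stopifnot(nlevels(labels) == 2L, .valid_base(ref), .valid_base(alt))
  bases <- c("A", "C", "G", "T")
  tab <- matrix(0L, 2L, 4L, dimnames = list(levels(labels), bases))
  obs <- !is.na(af)
  for (g in 1:2) {
    in_g <- obs & labels == levels(labels)[g]
    tab[g, ref] <- sum(in_g & af < 1)
    tab[g, alt] <- tab[g, alt] + sum(in_g & af > 0)
  }
  tab
}

#' Exact Fisher test on a 2 x 4 group-by-allele table
#'
#' Exact two-sided test of independence between group and allele by full
#' enumeration of tables with the observed margins: conditional on the
#' margins, table probabilities are multivariate hypergeometric, and the
#' p-value sums the probabilities of all tables as or less probable than
#' the observed one. Columns with zero margin are dropped first.
#'
#' @param tab Non-negative integer matrix with 2 rows (groups) and up to 4
#'   columns (alleles).
#' @return Two-sided exact p-value.
#' @export
fisher_exact_2x4 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == 2L, all(tab >= 0), all(tab == round(tab)))
  if (sum(tab) == 0) stop("all-zero table: test undefined")
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L || any(rowSums(tab) == 0)) return(1)
  r1 <- sum(tab[1L, ])
  cs <- colSums(tab)
  n <- sum(cs)
  # enumerate first-row allocations a with 0 <= a_j <= c_j, sum = r1
  grids <- lapply(cs[-length(cs)], function(cj) 0:min(cj, r1))
  a <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  last <- r1 - rowSums(a)
  ok <- last >= 0 & last <= cs[length(cs)]
  a <- cbind(a[ok, , drop = FALSE], last[ok])
  logp <- rep(-lchoose(n, r1), nrow(a))
  for (j in seq_along(cs)) logp <- logp + lchoose(cs[j], a[, j])
  logp_obs <- sum(lchoose(cs, tab[1L, ])) - lchoose(n, r1)
  # FEXACT-style relative tolerance for "as or less probable"
  p <- sum(exp(logp)[logp <= logp_obs + 1e-7])
  min(p, 1)
}

#' Wilcoxon rank-sum test on allele fractions
#'
#' Two-sided rank-sum comparison of the continuous allele-fraction
#' distributions of the two groups. `NA` entries (coverage failures) are
#' excluded; zero allele fractions are observed absences and are kept.
#' Small samples without ties use the exact distribution, larger or tied
#' samples the normal approximation with continuity correction.
#'
#' @param af_group_a,af_group_b Allele fractions of the two groups.
#' @return Two-sided p-value.
#' @export
wilcoxon_af <- function(af_group_a, af_group_b) {
  a <- af_group_a[!is.na(af_group_a)]
  b <- af_group_b[!is.na(af_group_b)]
  if (!length(a) || !length(b)) {
    stop("a group has no observed allele fractions: test undefined")
  }
  if (length(unique(c(a, b))) == 1L) return(1)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && (length(a) + length(b)) <= 25
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value
  )
}

#' Friedman comparison of feature rankings across methods
#'
#' Treats features as blocks and ranking methods as treatments and tests
#' for systematic disagreement among the rankings with the tie-corrected
#' Friedman chi-square statistic (p from the chi-square distribution with
#' `methods - 1` degrees of freedom).
#'
#' @param rankings A named list of numeric rank vectors over the same
#'   feature set (e.g. the multivariate ranking plus univariate rankings
#'   by ascending p-value), or a features x methods matrix.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
friedman_compare <- function(rankings) {
  if (is.list(rankings) && !is.data.frame(rankings)) {
    lens <- lengths(rankings)
    if (length(unique(lens)) != 1L) {
      stop("all rankings must cover the same feature set")
    }
    rankings <- do.call(cbind, rankings)
  }
  rankings <- as.matrix(rankings)
  if (ncol(rankings) < 2L) stop("at least two ranking methods are required")
  if (nrow(rankings) < 3L) stop("at least three features are required")
  ft <- stats::friedman.test(rankings)
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (!is.finite(stat)) {
    # every block fully tied (identical rankings): no disagreement at all
    stat <- 0
    p <- 1
  }
  list(statistic = stat, p_value = p, df = unname(ft$parameter))
}

#' Resampling enrichment of allele-specific expression among selected genes
#'
#' Compares the fraction of significant ASE gene/sample pairs within the
#' selected genes to a null distribution built from random gene subsets of
#' the same size drawn from the universe of genes.
#'
#' @param selected_genes Character vector of selected genes (a subset of
#'   the universe).
#' @param universe_genes Character vector of all genes eligible for
#'   selection.
#' @param ase_calls Data.frame with columns `gene`, `sample`, `testable`
#'   (logical: the gene/sample pair could be assayed) and `significant`
#'   (logical: significant ASE call), covering the universe.
#' @param n_subsets Number of random subsets (default 1000).
#' @param seed Optional RNG seed.
#' @return List of class `ase_enrichment`: `observed_fraction`,
#'   `null_fractions`, `p_value` (fraction of subsets at or above the
#'   observed fraction), `fold` (observed over null mean; `NA` when the
#'   null mean is zero).
#' @export
ase_enrichment <- function(selected_genes, universe_genes, ase_calls,
                           n_subsets = 1000L, seed = NULL) {
  selected_genes <- unique(selected_genes)
  universe_genes <- unique(universe_genes)
  if (!all(selected_genes %in% universe_genes)) {
    stop("selected genes must be a subset of the universe")
  }
  stopifnot(all(c("gene", "testable", "significant") %in% names(ase_calls)))
  if (!is.null(seed)) set.seed(seed)
  # per-gene totals; a subset's fraction is significant pairs / testable pairs
  tt <- tapply(ase_calls$testable, ase_calls$gene, sum)
  ss <- tapply(ase_calls$significant & ase_calls$testable, ase_calls$gene, sum)
  test_n <- setNames(as.numeric(tt), names(tt))[universe_genes]
  sig_n <- setNames(as.numeric(ss), names(ss))[universe_genes]
  test_n[is.na(test_n)] <- 0
  sig_n[is.na(sig_n)] <- 0
  names(test_n) <- names(sig_n) <- universe_genes
  frac <- function(genes) {
    tn <- sum(test_n[genes])
    if (tn == 0) return(NA_real_)
    sum(sig_n[genes]) / tn
  }
  observed <- frac(selected_genes)
  if (is.na(observed)) stop("no testable gene/sample pairs among selected genes")
  m <- length(selected_genes)
  null_fracs <- vapply(seq_len(n_subsets), function(i) {
    frac(sample(universe_genes, m))
  }, numeric(1))
  null_ok <- null_fracs[!is.na(null_fracs)]
  p <- mean(null_ok >= observed)
  null_mean <- mean(null_ok)
  fold <- if (null_mean > 0) observed / null_mean else NA_real_
  if (is.na(fold)) warning("null mean is zero: fold change undefined")
  structure(list(observed_fraction = observed, null_fractions = null_fracs,
                 p_value = p, fold = fold, n_subsets = as.integer(n_subsets)),
            class = "ase_enrichment")
}

#' @export
print.ase_enrichment <- function(x, ...) {
  cat(sprintf(
    "ASE enrichment: %.2f%% of gene/sample pairs significant (%.2fX the null mean, p %s)\n",
    100 * x$observed_fraction, x$fold,
    if (x$p_value == 0) sprintf("<%g", 1 / x$n_subsets) else
      format(x$p_value, digits = 3)))
  invisible(x)
}
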