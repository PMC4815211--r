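# End-to-end pipeline: assemble/filter the matrix, build region sub-models,
# tune K, evaluate, permute, rank, and write tables, figures and a
# machine-readable metrics bundle.

#' Pipeline run configuration
#'
#' Either file paths (calls directory + labels, with optional annotation,
#' editing-site and ASE-call files) or a ready [snv_matrix()] can be
#' supplied. Defaults reproduce the standard settings: coverage threshold
#' 10, fifteen 10-fold cross-validations, 1000 permutations.
#'
#' @param matrix An [snv_matrix()] (alternative to the file inputs).
#' @param calls Named character vector of per-sample call files (names are
#'   sample ids).
#' @param coverage Optional depth table file (TSV: chrom, pos, sample_id,
#'   depth).
#' @param annotations,editing_sites,labels,ase_calls Optional input file
#'   paths (see the respective readers).
#' @param coverage_threshold Read-coverage threshold (default 10).
#' @param min_nonzero Minimum samples with non-zero allele fraction per
#'   feature (default 3).
#' @param models Named list describing the sub-models to fit; each element
#'   is `list(regions = ..., editing_only = ...)`. The default fits the
#'   all-SNVs model plus one model per annotated region present and an
#'   RNA-editing model when flagged sites exist.
#' @param grid A [k_grid()] of candidate K values.
#' @param design A [cv_design()].
#' @param inner_folds Inner folds of the nested cross-validation.
#' @param n_perm Permutations for the significance test (default 1000).
#' @param seed Integer seed for the whole run.
#' @param out_dir Output directory.
#' @param make_plots Write figures (default `TRUE`).
#' @param top_features Features shown in boxplot/heatmap figures
#'   (default 15).
#' @return List of class `run_config`.
#' @export
run_config <- function(matrix = NULL, calls = NULL, coverage = NULL,
                       annotations = NULL, editing_sites = NULL,
                       labels = NULL, ase_calls = NULL,
                       coverage_threshold = 10L, min_nonzero = 3L,
                       models = NULL, grid = k_grid(10L, 100L, 10L),
                       design = cv_design(n_folds = 10L, n_repeats = 15L),
                       inner_folds = NULL, n_perm = 1000L, seed = 1L,
                       out_dir = "snvdisc_out", make_plots = TRUE,
                       top_features = 15L) {
  structure(as.list(environment()), class = "run_config")
}

.load_matrix_from_config <- function(config) {
  if (!is.null(config$matrix)) {
    m <- config$matrix
  } else {
    if (is.null(config$calls)) stop("config needs either a matrix or call files")
    recs <- do.call(rbind, lapply(names(config$calls), function(s) {
      read_snv_calls(config$calls[[s]], s)
    }))
    cov <- if (!is.null(config$coverage)) {
      read.table(config$coverage, sep = "\t", header = TRUE,
                 stringsAsFactors = FALSE)
    }
    m <- build_snv_matrix(recs, coverage = cov,
                          coverage_threshold = config$coverage_threshold)
    if (!is.null(config$annotations) || !is.null(config$editing_sites)) {
      anno <- if (!is.null(config$annotations))
        read_snv_annotations(config$annotations)
      es <- if (!is.null(config$editing_sites))
        read_editing_sites(config$editing_sites)
      m <- annotate_snv_matrix(m, anno, es)
    }
    if (!is.null(config$labels)) m <- set_labels(m, read_sample_labels(config$labels))
  }
  if (is.null(m$labels)) stop("the matrix must carry two-group labels")
  m
}

.default_models <- function(m) {
  models <- list(all_SNVs = list(regions = NULL, editing_only = FALSE))
  present <- sort(unique(stats::na.omit(m$annotation$region)))
  for (r in present) {
    models[[r]] <- list(regions = r, editing_only = FALSE)
  }
  if (any(m$annotation$is_editing_site)) {
    models[["RNA_editing"]] <- list(regions = NULL, editing_only = TRUE)
  }
  models
}

#' Run the full modeling pipeline
#'
#' Builds (or takes) the allele-fraction matrix, applies the
#' minimum-nonzero filter, then for every configured sub-model: tunes K by
#' nested cross-validation, evaluates at the optimal K by repeated
#' cross-validation, runs the label-permutation test, and ranks the
#' selected SNVs with univariate companion p-values. Writes a
#' region-count table, a per-model performance table, per-model ranked
#' feature tables and selected-SNV BED files, figures (K density,
#' allele-fraction boxplots, clustered heatmap with `NA` drawn black), a
#' JSON metrics bundle, and a log echoing the configuration.
#'
#' @param config A [run_config()].
#' @return Invisibly, the results bundle (also serialized to
#'   `metrics.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "log.txt")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logf <- function(...) {
    writeLines(sprintf(...), log_con)
  }
  logf("snvdisc pipeline run")
  logf("seed: %d", config$seed)
  cfg_echo <- config[!vapply(config, is.null, TRUE)]
  cfg_echo$matrix <- if (!is.null(config$matrix)) {
    sprintf("<snv_matrix %d x %d>", nrow(config$matrix$values),
            ncol(config$matrix$values))
  }
  logf("config: %s", paste(utils::capture.output(utils::str(cfg_echo)),
                           collapse = " | "))

  set.seed(config$seed)
  m_all <- .load_matrix_from_config(config)
  m <- filter_min_nonzero(m_all, config$min_nonzero)
  logf("matrix: %d features (%d after min_nonzero=%d filter), %d samples",
       nrow(m_all$values), nrow(m$values), config$min_nonzero,
       ncol(m$values))

  region_tab <- summarize_regions(m_all, config$min_nonzero)
  write.table(region_tab, file.path(config$out_dir, "region_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  models <- config$models
  if (is.null(models)) models <- .default_models(m)
  inner_folds <- config$inner_folds
  if (is.null(inner_folds)) inner_folds <- config$design$n_folds

  results <- list()
  perf_rows <- list()
  for (name in names(models)) {
    spec <- models[[name]]
    mm <- subset_by_region(m, spec$regions, isTRUE(spec$editing_only))
    p <- nrow(mm$values)
    if (p < 2L) {
      logf("model %s: skipped (%d surviving feature(s))", name, p)
      next
    }
    logf("model %s: %d features", name, p)
    design <- config$design
    design$rng_seed <- NULL # the run-level seed governs the RNG stream
    sel <- nested_cv_select_k(mm, config$grid, design,
                              inner_folds = inner_folds)
    perf <- evaluate_model(mm, sel$optimal_k, design)
    perm <- permutation_test(mm, sel$optimal_k, perf$auc_mean,
                             n_perm = config$n_perm, design = design)
    rk <- final_rank(mm, sel$optimal_k)

    rank_path <- file.path(config$out_dir,
                           sprintf("ranked_features_%s.tsv", name))
    write.table(as.data.frame(rk), rank_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    .write_selected_bed(mm, rk,
                        file.path(config$out_dir,
                                  sprintf("selected_%s.bed", name)))

    lv <- perf$groups
    perf_rows[[name]] <- data.frame(
      model = name, k_range = sprintf("%d-%d, %d", config$grid$k_min,
                                      config$grid$k_max, config$grid$step),
      optimal_k = sel$optimal_k,
      auc = perf$auc_mean, auc_ci_low = perf$auc_ci_low,
      auc_ci_high = perf$auc_ci_high, perm_p = perm$p_display,
      accuracy = perf$predictive_accuracy,
      sens_1 = unname(perf$sensitivity[1L]),
      sens_2 = unname(perf$sensitivity[2L]),
      stringsAsFactors = FALSE
    )
    results[[name]] <- list(
      n_features = p, selected_ks = sel$selected_ks,
      optimal_k = sel$optimal_k, auc_mean = perf$auc_mean,
      auc_ci = c(perf$auc_ci_low, perf$auc_ci_high),
      predictive_accuracy = perf$predictive_accuracy,
      sensitivity = as.list(perf$sensitivity),
      permutation_p = perm$p_value, permutation_p_display = perm$p_display,
      n_perm = perm$n_perm,
      ranking = as.data.frame(rk)
    )
    if (isTRUE(config$make_plots)) {
      .pipeline_plots(config, name, mm, results[[name]])
    }
  }

  if (length(perf_rows)) {
    perf_tab <- do.call(rbind, perf_rows)
    names(perf_tab)[names(perf_tab) == "sens_1"] <-
      paste0("sens_", levels(m$labels)[1L])
    names(perf_tab)[names(perf_tab) == "sens_2"] <-
      paste0("sens_", levels(m$labels)[2L])
    write.table(perf_tab, file.path(config$out_dir, "performance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  bundle <- list(
    seed = config$seed,
    coverage_threshold = config$coverage_threshold,
    min_nonzero = config$min_nonzero,
    n_features_total = nrow(m_all$values),
    n_features_filtered = nrow(m$values),
    n_samples = ncol(m$values),
    groups = levels(m$labels),
    region_counts = region_tab,
    models = lapply(results, function(r) r[setdiff(names(r), "ranking")])
  )
  jsonlite::write_json(bundle, file.path(config$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("wrote %d model result(s)", length(results))
  invisible(c(bundle, list(rankings = lapply(results, `[[`, "ranking"))))
}

.write_selected_bed <- function(m, ranking, path) {
  i <- match(ranking$snv_key, m$annotation$snv_key)
  bed <- data.frame(
    chrom = m$annotation$chrom[i],
    start = m$annotation$pos[i] - 1,
    end = m$annotation$pos[i],
    name = paste0(m$annotation$ref[i], ">", m$annotation$alt[i]),
    score = ranking$abs_loading
  )
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

.pipeline_plots <- function(config, name, mm, res) {
  out <- config$out_dir
  .save_plot(file.path(out, sprintf("k_density_%s.png", name)),
             plot_k_density(res$selected_ks, res$optimal_k))
  top <- head(res$ranking$snv_key, config$top_features)
  .save_plot(file.path(out, sprintf("af_boxplot_%s.png", name)),
             plot_af_boxplots(mm, top))
  if (length(top) >= 2L) {
    grDevices::png(file.path(out, sprintf("heatmap_%s.png", name)),
                   width = 900, height = 700)
    plot_feature_heatmap(mm, top)
    grDevices::dev.off()
  }
}

.save_plot <- function(path, plot) {
  grDevices::png(path, width = 800, height = 600)
  print(plot)
  grDevices::dev.off()
}

#' Kernel-density plot of selected K values
#'
#' @param selected_ks K values recorded by [nested_cv_select_k()].
#' @param optimal_k The chosen optimum (vertical line).
#' @return A ggplot object.
#' @export
plot_k_density <- function(selected_ks, optimal_k = NULL) {
  df <- data.frame(k = selected_ks)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$k)) +
    ggplot2::labs(x = "selected K", y = "density",
                  title = "Distribution of K selected by nested CV")
  if (length(unique(selected_ks)) > 1L) {
    gg <- gg + ggplot2::geom_density(bw = "nrd0", fill = "grey80")
  } else {
    gg <- gg + ggplot2::geom_histogram(binwidth = 1)
  }
  if (!is.null(optimal_k)) {
    gg <- gg + ggplot2::geom_vline(xintercept = optimal_k,
                                   linetype = "dashed", colour = "red")
  }
  gg
}

#' Allele-fraction boxplots of top-ranked SNVs by group
#'
#' Box statistics include zero allele fractions, but only non-zero values
#' are drawn as points; `NA` entries are excluded.
#'
#' @param m A labelled [snv_matrix()].
#' @param features SNV keys to plot.
#' @return A ggplot object.
#' @export
plot_af_boxplots <- function(m, features) {
  stopifnot(inherits(m, "snv_matrix"))
  i <- match(features, rownames(m$values))
  v <- m$values[i, , drop = FALSE]
  df <- data.frame(
    snv = factor(rep(features, ncol(v)), levels = features),
    group = rep(as.character(m$labels), each = length(features)),
    af = as.vector(v)
  )
  df <- df[!is.na(df$af), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$snv, y = .data$af,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_point(data = df[df$af > 0, , drop = FALSE],
                        position = ggplot2::position_jitterdodge(
                          jitter.width = 0.1),
                        size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "allele fraction") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Clustered heatmap of top-ranked SNVs with NA drawn black
#'
#' Hierarchical clustering (average linkage, Euclidean distance) is
#' computed on the standardized allele fractions with `NA` replaced by the
#' group-mean midpoint for the distance computation only; displayed values
#' keep their `NA`, rendered black.
#'
#' @param m A labelled [snv_matrix()].
#' @param features SNV keys to include (at least 2).
#' @param ... Passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot_feature_heatmap <- function(m, features, ...) {
  stopifnot(inherits(m, "snv_matrix"), length(features) >= 2L)
  i <- match(features, rownames(m$values))
  x <- t(m$values[i, , drop = FALSE]) # samples x features
  par <- standardize_fit(x)
  z <- standardize_apply(x, par)
  gm <- .group_means_std(z, m$labels)
  zfill <- z
  na <- which(is.na(zfill), arr.ind = TRUE)
  if (nrow(na)) zfill[na] <- gm$fill[na[, 2L]]
  hr <- stats::hclust(stats::dist(t(zfill)), method = "average")
  hc <- stats::hclust(stats::dist(zfill), method = "average")
  ann <- data.frame(group = m$labels)
  rownames(ann) <- colnames(m$values)
  pheatmap::pheatmap(t(z), cluster_rows = hr, cluster_cols = hc,
                     annotation_col = ann, na_col = "black", ...)
}
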