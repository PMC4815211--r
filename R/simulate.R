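# Synthetic allele-fraction datasets with known ground truth: two groups,
# a background of zero-inflated Beta allele fractions, informative
# features carrying an abundance shift (group-dependent probability of a
# non-zero allele fraction), a magnitude shift (group-dependent Beta
# mean), or both, and a negative-binomial read-coverage model that drives
# the NA mask.

#' Specification for the synthetic dataset generator
#'
#' Defaults describe a moderate two-group cohort with a small set of
#' clearly informative SNVs against a zero-inflated background, roughly
#' the structure of an RNA-Seq SNV allele-fraction matrix after coverage
#' masking and minimum-nonzero filtering.
#'
#' @param n_per_group Samples per group (length-2 or scalar).
#' @param n_features Number of SNV features.
#' @param n_informative Number of informative features.
#' @param effect Effect model for informative features: `"both"`
#'   (alternate abundance- and magnitude-shifted features so both modes
#'   are present), `"abundance"`, or `"magnitude"`.
#' @param background_prob Probability of a non-zero allele fraction for
#'   background features (both groups).
#' @param background_shape Beta shape parameters (length 2) of background
#'   non-zero allele fractions.
#' @param abundance_shift Added non-zero probability in the second group
#'   for abundance-shifted features.
#' @param magnitude_means Group allele-fraction means (length 2) for
#'   magnitude-shifted features.
#' @param magnitude_prob Non-zero probability (both groups) for
#'   magnitude-shifted features.
#' @param magnitude_conc Beta concentration (a+b) for magnitude-shifted
#'   features.
#' @param na_rate Target fraction of entries masked `NA` by sub-threshold
#'   coverage.
#' @param depth_mean Mean read depth of the negative-binomial coverage
#'   model when `na_rate = 0` is requested.
#' @param depth_size Negative-binomial size (dispersion) of the coverage
#'   model.
#' @param coverage_threshold Masking threshold (entries with depth below
#'   it become `NA`).
#' @param snvs_per_gene Average number of SNV features per gene.
#' @param ase_genes Number of background genes designated ASE-positive in
#'   addition to the genes hosting informative SNVs.
#' @param ase_link_informative Designate the genes of informative SNVs
#'   ASE-positive (default `TRUE`): allelic imbalance is what makes their
#'   allele fractions discriminative.
#' @param ase_sig_rate Probability that a testable gene/sample pair of an
#'   ASE-positive gene is called significant (background genes use a low
#'   constant rate).
#' @param group_names Group labels.
#' @param rng_seed Integer seed.
#' @return List of class `generator_spec`.
#' @export
generator_spec <- function(n_per_group = c(20L, 20L), n_features = 300L,
                           n_informative = 10L,
                           effect = c("both", "abundance", "magnitude"),
                           background_prob = 0.2,
                           background_shape = c(2, 2),
                           abundance_shift = 0.4,
                           magnitude_means = c(0.35, 0.65),
                           magnitude_prob = 0.7,
                           magnitude_conc = 8,
                           na_rate = 0.1,
                           depth_mean = 30,
                           depth_size = 5,
                           coverage_threshold = 10L,
                           snvs_per_gene = 3,
                           ase_genes = 5L,
                           ase_link_informative = TRUE,
                           ase_sig_rate = 0.5,
                           group_names = c("group_A", "group_B"),
                           rng_seed = NULL) {
  effect <- match.arg(effect)
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 2L)
  if (n_informative > n_features) {
    stop("n_informative cannot exceed n_features")
  }
  stopifnot(background_prob >= 0, background_prob <= 1,
            na_rate >= 0, na_rate < 1,
            abundance_shift >= 0, background_prob + abundance_shift <= 1,
            all(magnitude_means > 0), all(magnitude_means < 1))
  structure(as.list(environment()), class = "generator_spec")
}

# depth distribution whose sub-threshold probability matches the target
# NA rate: NB(size) with mean solved by monotone root finding
.depth_mu_for_na_rate <- function(na_rate, size, threshold) {
  f <- function(log_mu) {
    stats::pnbinom(threshold - 1, size = size, mu = exp(log_mu)) - na_rate
  }
  exp(stats::uniroot(f, c(log(1e-3), log(1e5)))$root)
}

#' Generate a synthetic SNV allele-fraction dataset
#'
#' @param spec A [generator_spec()].
#' @return List with `matrix` (a labelled, annotated [snv_matrix()]),
#'   `truth` (data.frame of informative features and their effect type),
#'   and `ase_calls` (per gene/sample testability and significance flags,
#'   with the designated ASE-positive genes in
#'   `attr(ase_calls, "ase_genes")`).
#' @export
generate_dataset <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.null(spec$rng_seed)) set.seed(spec$rng_seed)
  n1 <- spec$n_per_group[1L]
  n2 <- spec$n_per_group[2L]
  n <- n1 + n2
  p <- spec$n_features
  grp <- factor(rep(spec$group_names, c(n1, n2)), levels = spec$group_names)
  samples <- sprintf("S%03d", seq_len(n))

  info_idx <- if (spec$n_informative > 0) seq_len(spec$n_informative) else integer(0)
  eff_type <- character(0)
  if (length(info_idx)) {
    eff_type <- switch(spec$effect,
      abundance = rep("abundance", length(info_idx)),
      magnitude = rep("magnitude", length(info_idx)),
      both = rep(c("abundance", "magnitude"), length.out = length(info_idx))
    )
  }

  # per-feature, per-sample probability of a non-zero AF and Beta params
  prob <- matrix(spec$background_prob, p, n)
  sh_a <- matrix(spec$background_shape[1L], p, n)
  sh_b <- matrix(spec$background_shape[2L], p, n)
  g2 <- grp == spec$group_names[2L]
  for (i in seq_along(info_idx)) {
    f <- info_idx[i]
    if (eff_type[i] == "abundance") {
      prob[f, g2] <- spec$background_prob + spec$abundance_shift
    } else {
      prob[f, ] <- spec$magnitude_prob
      mu <- ifelse(g2, spec$magnitude_means[2L], spec$magnitude_means[1L])
      sh_a[f, ] <- mu * spec$magnitude_conc
      sh_b[f, ] <- (1 - mu) * spec$magnitude_conc
    }
  }
  nonzero <- matrix(stats::rbinom(p * n, 1L, as.vector(prob)), p, n)
  af <- matrix(0, p, n)
  nz <- nonzero == 1L
  af[nz] <- stats::rbeta(sum(nz), sh_a[nz], sh_b[nz])

  # coverage model -> NA mask
  if (spec$na_rate > 0) {
    mu <- .depth_mu_for_na_rate(spec$na_rate, spec$depth_size,
                                spec$coverage_threshold)
    depth <- matrix(stats::rnbinom(p * n, size = spec$depth_size, mu = mu), p, n)
  } else {
    depth <- matrix(spec$coverage_threshold +
                      stats::rnbinom(p * n, size = spec$depth_size,
                                     mu = spec$depth_mean), p, n)
  }
  af[depth < spec$coverage_threshold] <- NA_real_

  # feature keys, regions, genes
  keys <- sprintf("chr%d:%d:%s>%s",
                  1L + (seq_len(p) - 1L) %% 22L,
                  10000L + 50L * seq_len(p),
                  c("A", "C", "G", "T")[1L + (seq_len(p) %% 4L)],
                  c("G", "T", "A", "C")[1L + (seq_len(p) %% 4L)])
  region_pool <- c("utr3", "exonic", "nonsynonymous_exonic", "intronic",
                   "intergenic", "ncRNA", "utr5", "updownstream")
  region_prob <- c(0.26, 0.12, 0.11, 0.25, 0.12, 0.07, 0.04, 0.03)
  regions <- sample(region_pool, p, replace = TRUE, prob = region_prob)
  n_genes <- max(1L, round(p / spec$snvs_per_gene))
  genes <- sprintf("gene_%04d", sample.int(n_genes, p, replace = TRUE))
  editing <- stats::runif(p) < 0.02

  dimnames(af) <- list(keys, samples)
  anno <- .annotation_from_keys(keys)
  anno$region <- regions
  anno$gene <- genes
  anno$is_editing_site <- editing
  m <- snv_matrix(af, annotation = anno,
                  labels = setNames(grp, samples),
                  coverage_threshold = spec$coverage_threshold)

  truth <- data.frame(
    snv_key = keys[info_idx],
    effect = eff_type,
    gene = genes[info_idx],
    stringsAsFactors = FALSE
  )

  gene_set <- sort(unique(genes))
  # ASE-positive genes: those hosting informative SNVs (allelic imbalance
  # is what makes their allele fractions discriminative) plus random
  # background ASE genes
  info_genes <- if (isTRUE(spec$ase_link_informative)) {
    unique(genes[info_idx])
  } else {
    character(0)
  }
  extra <- setdiff(gene_set, info_genes)
  ase_pos <- c(info_genes,
               sample(extra, min(spec$ase_genes, length(extra))))
  ac <- expand.grid(gene = gene_set, sample = samples,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ac$testable <- stats::runif(nrow(ac)) < 0.6
  base_rate <- ifelse(ac$gene %in% ase_pos, spec$ase_sig_rate, 0.05)
  ac$significant <- ac$testable & (stats::runif(nrow(ac)) < base_rate)
  attr(ac, "ase_genes") <- ase_pos

  list(matrix = m, truth = truth, ase_calls = ac)
}
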