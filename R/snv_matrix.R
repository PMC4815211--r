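# The SNV allele-fraction matrix (features x samples, NA marking
# sub-threshold coverage) and its construction, filtering, subsetting and
# on-disk archive format.

#' Construct an `snv_matrix` object
#'
#' Low-level constructor; most users build one with [build_snv_matrix()]
#' or [generate_dataset()].
#'
#' @param values Numeric matrix, features x samples. Row names are SNV keys
#'   (`chrom:pos:ref>alt`), column names sample ids. Non-`NA` entries must
#'   lie in `[0, 1]`.
#' @param annotation Data.frame with one row per feature (columns
#'   `snv_key`, `chrom`, `pos`, `ref`, `alt`, and optionally `region`,
#'   `gene`, `is_editing_site`, `dbsnp_id`).
#' @param labels Optional named factor of per-sample group labels.
#' @param coverage_threshold Read-coverage threshold used for masking.
#' @return An object of class `snv_matrix`.
#' @export
snv_matrix <- function(values, annotation = NULL, labels = NULL,
                       coverage_threshold = 10) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyDuplicated(rownames(values))) stop("duplicate feature keys")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < 0 || max(v) > 1)) {
    stop("allele fractions must lie in [0,1]")
  }
  if (is.null(annotation)) {
    annotation <- .annotation_from_keys(rownames(values))
  } else {
    stopifnot(nrow(annotation) == nrow(values))
    if (is.null(annotation$snv_key)) {
      annotation$snv_key <- .snv_key(annotation$chrom, annotation$pos,
                                     annotation$ref, annotation$alt)
    }
    if (!identical(annotation$snv_key, rownames(values))) {
      annotation <- annotation[match(rownames(values), annotation$snv_key), ,
                               drop = FALSE]
      if (anyNA(annotation$snv_key)) stop("annotation does not cover all features")
    }
  }
  for (col in c("region", "gene", "dbsnp_id")) {
    if (is.null(annotation[[col]])) annotation[[col]] <- NA_character_
  }
  if (is.null(annotation$is_editing_site)) annotation$is_editing_site <- FALSE
  rownames(annotation) <- NULL
  if (!is.null(labels)) {
    labels <- .check_labels(labels, colnames(values))
  }
  structure(
    list(values = values, annotation = annotation, labels = labels,
         coverage_threshold = coverage_threshold),
    class = "snv_matrix"
  )
}

.annotation_from_keys <- function(keys) {
  m <- regmatches(keys, regexec("^(.+):([0-9]+):([ACGT])>([ACGT])$", keys))
  if (any(lengths(m) != 5L)) stop("feature keys must look like chrom:pos:REF>ALT")
  data.frame(
    snv_key = keys,
    chrom = vapply(m, `[`, "", 2L),
    pos = as.numeric(vapply(m, `[`, "", 3L)),
    ref = vapply(m, `[`, "", 4L),
    alt = vapply(m, `[`, "", 5L),
    region = NA_character_, gene = NA_character_,
    is_editing_site = FALSE, dbsnp_id = NA_character_,
    stringsAsFactors = FALSE
  )
}

.check_labels <- function(labels, samples) {
  if (is.null(names(labels))) {
    if (length(labels) != length(samples)) {
      stop("unnamed labels must match the number of samples")
    }
    names(labels) <- samples
  }
  miss <- setdiff(samples, names(labels))
  if (length(miss)) stop("labels missing for sample(s): ",
                         paste(miss, collapse = ", "))
  labels <- factor(labels[samples])
  labels <- droplevels(labels)
  if (nlevels(labels) != 2L) {
    stop("exactly two groups are required; got ", nlevels(labels))
  }
  labels
}

#' @export
print.snv_matrix <- function(x, ...) {
  cat("snv_matrix:", nrow(x$values), "SNV features x",
      ncol(x$values), "samples\n")
  na_frac <- mean(is.na(x$values))
  cat(sprintf("  NA (sub-threshold coverage, <%d reads): %.1f%%\n",
              x$coverage_threshold, 100 * na_frac))
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat("  groups:", paste(sprintf("%s (n=%d)", names(tb), tb), collapse = ", "),
        "\n")
  }
  if (!all(is.na(x$annotation$region))) {
    cat("  annotated regions:",
        paste(sort(unique(stats::na.omit(x$annotation$region))), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.snv_matrix <- function(x) dim(x$values)

#' Build the allele-fraction matrix from SNV records
#'
#' Assembles the union of SNV keys x union of samples into a matrix whose
#' entry is the allele fraction when read coverage at that locus/sample
#' reaches `coverage_threshold`, `NA` when coverage is below threshold,
#' and 0 when the position is adequately covered but no variant was
#' called there.
#'
#' Coverage comes either from the `depth` column of the records, or from a
#' separate per-locus, per-sample depth table. Without a coverage table,
#' cells that have no record have unknown coverage and are `NA`.
#'
#' @param records Data.frame of SNV records over all samples (as returned
#'   by [read_snv_calls()], row-bound across samples).
#' @param coverage Optional data.frame with columns `chrom`, `pos`
#'   (1-based), `sample_id`, `depth` giving read coverage for every locus
#'   and sample.
#' @param coverage_threshold Minimum read coverage for an entry to be kept
#'   (default 10); entries below it are masked `NA`.
#' @param samples Optional character vector fixing the sample set and order
#'   (defaults to the samples present in `records`/`coverage`).
#' @param labels Optional named factor of group labels.
#' @return An [snv_matrix()] object.
#' @export
build_snv_matrix <- function(records, coverage = NULL, coverage_threshold = 10,
                             samples = NULL, labels = NULL) {
  stopifnot(nrow(records) > 0)
  key <- .snv_key(records$chrom, records$pos, records$ref, records$alt)
  cell <- paste(key, records$sample_id, sep = "\r")
  if (anyDuplicated(cell)) {
    d <- split(records$allele_fraction, cell)
    conflict <- names(d)[vapply(d, function(v) length(unique(v)) > 1L, TRUE)]
    if (length(conflict)) {
      stop("conflicting duplicate records for: ",
           paste(gsub("\r", " in sample ", conflict), collapse = "; "))
    }
    first <- !duplicated(cell)
    records <- records[first, , drop = FALSE]
    key <- key[first]
  }

  feat <- unique(data.frame(snv_key = key, chrom = records$chrom,
                            pos = records$pos, ref = records$ref,
                            alt = records$alt, stringsAsFactors = FALSE))
  feat <- feat[order(feat$chrom, feat$pos, feat$ref, feat$alt), , drop = FALSE]
  if (is.null(samples)) {
    samples <- sort(unique(c(records$sample_id,
                             if (!is.null(coverage)) coverage$sample_id)))
  }
  vals <- matrix(NA_real_, nrow(feat), length(samples),
                 dimnames = list(feat$snv_key, samples))

  if (!is.null(coverage)) {
    stopifnot(all(c("chrom", "pos", "sample_id", "depth") %in% names(coverage)))
    locus <- paste(feat$chrom, feat$pos, sep = "\r")
    cov_locus <- paste(coverage$chrom, coverage$pos, sep = "\r")
    u_locus <- unique(locus)
    rows_by_locus <- split(seq_along(locus), factor(locus, levels = u_locus))
    li <- match(cov_locus, u_locus)
    si <- match(coverage$sample_id, samples)
    # loci can carry several alt alleles: spread coverage over all features
    # at the locus
    idx <- which(!is.na(li) & !is.na(si) & coverage$depth >= coverage_threshold)
    if (length(idx)) {
      reps <- rows_by_locus[li[idx]]
      vals[cbind(unlist(reps), rep(si[idx], lengths(reps)))] <- 0
    }
  }

  fi <- match(key, feat$snv_key)
  si <- match(records$sample_id, samples)
  dep <- records$depth
  has_dep <- !is.na(dep)
  set_af <- ifelse(has_dep & dep < coverage_threshold, NA_real_,
                   records$allele_fraction)
  vals[cbind(fi, si)] <- set_af

  anno <- .annotation_from_keys(feat$snv_key)
  snv_matrix(vals, annotation = anno, labels = labels,
             coverage_threshold = coverage_threshold)
}

#' Attach region/gene annotations and editing-site flags
#'
#' @param m An [snv_matrix()].
#' @param annotation Data.frame from [read_snv_annotations()] (or with the
#'   same columns). Features without a matching row keep `NA` region.
#' @param editing_sites Optional data.frame with columns `chrom`, `pos`;
#'   features at those positions are flagged `is_editing_site`.
#' @return The annotated `snv_matrix`.
#' @export
annotate_snv_matrix <- function(m, annotation = NULL, editing_sites = NULL) {
  stopifnot(inherits(m, "snv_matrix"))
  a <- m$annotation
  if (!is.null(annotation)) {
    if (is.null(annotation$snv_key)) {
      annotation$snv_key <- .snv_key(annotation$chrom, annotation$pos,
                                     annotation$ref, annotation$alt)
    }
    i <- match(a$snv_key, annotation$snv_key)
    hit <- !is.na(i)
    a$region[hit] <- annotation$region[i[hit]]
    if (!is.null(annotation$gene)) a$gene[hit] <- annotation$gene[i[hit]]
    if (!is.null(annotation$dbsnp_id)) a$dbsnp_id[hit] <- annotation$dbsnp_id[i[hit]]
  }
  if (!is.null(editing_sites)) {
    locus <- paste(a$chrom, a$pos, sep = "\r")
    es <- paste(editing_sites$chrom, editing_sites$pos, sep = "\r")
    a$is_editing_site <- locus %in% es
  }
  m$annotation <- a
  m
}

#' Assign group labels to an `snv_matrix`
#'
#' @param m An [snv_matrix()].
#' @param labels Named factor (or character) of group labels covering the
#'   matrix samples.
#' @return The labelled `snv_matrix`.
#' @export
set_labels <- function(m, labels) {
  stopifnot(inherits(m, "snv_matrix"))
  m$labels <- .check_labels(labels, colnames(m$values))
  m
}

#' Drop features with too few non-zero allele fractions
#'
#' Retains exactly the features with at least `min_nonzero` samples whose
#' entry is observed (non-`NA`) and strictly positive. Sample set and
#' feature order are unchanged; surviving values are untouched.
#'
#' @param m An [snv_matrix()].
#' @param min_nonzero Minimum number of samples with non-zero allele
#'   fraction (e.g. 3 for a small cohort, 6 for a larger one).
#' @return The filtered `snv_matrix`.
#' @export
filter_min_nonzero <- function(m, min_nonzero) {
  stopifnot(inherits(m, "snv_matrix"), min_nonzero >= 0)
  nz <- rowSums(!is.na(m$values) & m$values > 0)
  .subset_features(m, nz >= min_nonzero)
}

.subset_features <- function(m, keep) {
  m$values <- m$values[keep, , drop = FALSE]
  m$annotation <- m$annotation[keep, , drop = FALSE]
  rownames(m$annotation) <- NULL
  m
}

#' Restrict features by genomic region and/or editing-site status
#'
#' A request for `exonic` also matches `nonsynonymous_exonic` features
#' (nonsynonymous SNVs are exonic). `regions = NULL` with
#' `editing_only = FALSE` is the identity ("all SNVs").
#'
#' @param m An annotated [snv_matrix()].
#' @param regions Character vector of region classes (see
#'   [region_classes()]), or `NULL` for no region restriction.
#' @param editing_only If `TRUE`, keep only features flagged as RNA-editing
#'   sites.
#' @return The restricted `snv_matrix`.
#' @export
subset_by_region <- function(m, regions = NULL, editing_only = FALSE) {
  stopifnot(inherits(m, "snv_matrix"))
  keep <- rep(TRUE, nrow(m$values))
  if (!is.null(regions)) {
    bad <- setdiff(regions, REGION_CLASSES)
    if (length(bad)) {
      stop("unknown region name(s): ", paste(bad, collapse = ", "),
           "; valid names: ", paste(REGION_CLASSES, collapse = ", "))
    }
    want <- regions
    if ("exonic" %in% want) want <- union(want, "nonsynonymous_exonic")
    keep <- keep & !is.na(m$annotation$region) & m$annotation$region %in% want
  }
  if (editing_only) keep <- keep & m$annotation$is_editing_site
  .subset_features(m, keep)
}

#' Tabulate SNV counts by region, before and after filtering
#'
#' One row per region class present plus an RNA-editing row and an
#' all-SNVs row; the `exonic` row includes nonsynonymous exonic features,
#' which are also counted in their own row.
#'
#' @param m An annotated [snv_matrix()].
#' @param min_nonzero Non-zero sample count used for the filtered column.
#' @return Data.frame with columns `region`, `total`, `filtered`.
#' @export
summarize_regions <- function(m, min_nonzero) {
  stopifnot(inherits(m, "snv_matrix"))
  fm <- filter_min_nonzero(m, min_nonzero)
  count <- function(mm, reg) {
    if (reg == "exonic") {
      sum(mm$annotation$region %in% c("exonic", "nonsynonymous_exonic"))
    } else {
      sum(mm$annotation$region %in% reg)
    }
  }
  rows <- lapply(REGION_CLASSES, function(r) {
    data.frame(region = r, total = count(m, r), filtered = count(fm, r))
  })
  rows <- do.call(rbind, rows)
  rows <- rbind(rows, data.frame(
    region = "RNA-editing",
    total = sum(m$annotation$is_editing_site),
    filtered = sum(fm$annotation$is_editing_site)
  ))
  rows <- rbind(rows, data.frame(
    region = "all_SNVs", total = nrow(m$values), filtered = nrow(fm$values)
  ))
  rows
}

#' Write an `snv_matrix` archive
#'
#' Writes a directory with `matrix.tsv` (features as rows, `NA` literal for
#' masked cells), `annotation.tsv`, and `meta.json` (coverage threshold and
#' label map). The archive round-trips losslessly through
#' [read_snv_matrix()].
#'
#' @param m An [snv_matrix()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_snv_matrix <- function(m, dir) {
  stopifnot(inherits(m, "snv_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vt <- data.frame(snv_key = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(vt, file.path(dir, "matrix.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  write.table(m$annotation, file.path(dir, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
  meta <- list(
    coverage_threshold = m$coverage_threshold,
    samples = colnames(m$values),
    labels = if (is.null(m$labels)) NULL else
      as.list(setNames(as.character(m$labels), names(m$labels)))
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read an `snv_matrix` archive written by [write_snv_matrix()]
#'
#' @param dir Archive directory.
#' @return The reconstructed [snv_matrix()].
#' @export
read_snv_matrix <- function(dir) {
  vt <- read.table(file.path(dir, "matrix.tsv"), sep = "\t", header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  keys <- vt$snv_key
  vals <- as.matrix(vt[, -1, drop = FALSE])
  rownames(vals) <- keys
  anno <- read.table(file.path(dir, "annotation.tsv"), sep = "\t",
                     header = TRUE, stringsAsFactors = FALSE,
                     colClasses = c(pos = "numeric",
                                    is_editing_site = "logical"),
                     na.strings = "NA")
  for (col in c("snv_key", "chrom", "ref", "alt", "region", "gene",
                "dbsnp_id")) {
    anno[[col]] <- as.character(anno[[col]])
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  labels <- NULL
  if (!is.null(meta$labels) && length(meta$labels)) {
    labels <- setNames(factor(unlist(meta$labels)), names(meta$labels))
  }
  storage.mode(vals) <- "double"
  snv_matrix(vals, annotation = anno, labels = labels,
             coverage_threshold = meta$coverage_threshold)
}
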