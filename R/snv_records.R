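# Readers and writers for the small TSV formats surrounding the
# allele-fraction matrix: per-sample SNV call files (BED-style), SNV
# annotation tables, RNA-editing site lists and sample labels.

.snv_key <- function(chrom, pos, ref, alt) {
  paste0(chrom, ":", pos, ":", ref, ">", alt)
}

.valid_base <- function(x) x %in% c("A", "C", "G", "T")

#' Read per-sample SNV calls from a BED-style file
#'
#' Expected columns (TSV, header optional, `#` comments ignored):
#' `chrom`, `start` (0-based), `end`, `name` (`"REF>ALT"`),
#' `allele_fraction`, and optionally `depth`. Positions are converted to
#' 1-based (`pos = start + 1`). Malformed rows raise an error naming the
#' offending line numbers.
#'
#' @param path Path to the call file.
#' @param sample_id Sample identifier attached to every record.
#' @return A data.frame of SNV records with columns `chrom`, `pos`, `ref`,
#'   `alt`, `sample_id`, `allele_fraction`, `depth` (`NA` when the file has
#'   no depth column).
#' @export
read_snv_calls <- function(path, sample_id) {
  stopifnot(length(sample_id) == 1L)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(.empty_records())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  # header detection: a first row whose start column is non-numeric
  first <- fields[[1L]]
  if (length(first) >= 2L && is.na(suppressWarnings(as.numeric(first[2L])))) {
    fields <- fields[-1L]
    lineno <- lineno[-1L]
    if (length(fields) == 0L) return(.empty_records())
    nf <- lengths(fields)
  }
  if (any(nf < 5L)) {
    stop("call file ", path, " is missing required columns ",
         "(chrom, start, end, name, allele_fraction) on line(s) ",
         paste(lineno[nf < 5L], collapse = ", "))
  }
  g <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  chrom <- g(1L)
  start <- suppressWarnings(as.numeric(g(2L)))
  name <- g(4L)
  af <- suppressWarnings(as.numeric(g(5L)))
  depth <- suppressWarnings(as.numeric(g(6L)))

  alleles <- regmatches(name, regexec("^([ACGT])>([ACGT])$", name))
  ok_name <- lengths(alleles) == 3L
  ref <- ifelse(ok_name, vapply(alleles, function(a) a[2L] %||% NA_character_, ""), NA_character_)
  alt <- ifelse(ok_name, vapply(alleles, function(a) if (length(a) == 3L) a[3L] else NA_character_, ""), NA_character_)

  bad_parse <- is.na(start) | !ok_name | is.na(af)
  if (any(bad_parse)) {
    stop("malformed row(s) in ", path, " at line(s) ",
         paste(lineno[bad_parse], collapse = ", "),
         " (expect chrom, 0-based start, end, REF>ALT, allele fraction)")
  }
  bad_af <- af < 0 | af > 1
  if (any(bad_af)) {
    stop("allele fraction outside [0,1] in ", path, " at line(s) ",
         paste(lineno[bad_af], collapse = ", "))
  }
  bad_same <- ref == alt
  if (any(bad_same)) {
    stop("ref and alt allele identical in ", path, " at line(s) ",
         paste(lineno[bad_same], collapse = ", "))
  }
  if (any(!is.na(depth) & depth < 0)) {
    stop("negative depth in ", path, " at line(s) ",
         paste(lineno[!is.na(depth) & depth < 0], collapse = ", "))
  }
  bad_cov <- !is.na(depth) & af > 0 & depth == 0
  if (any(bad_cov)) {
    stop("positive allele fraction with zero depth in ", path,
         " at line(s) ", paste(lineno[bad_cov], collapse = ", "))
  }
  data.frame(
    chrom = chrom, pos = start + 1, ref = ref, alt = alt,
    sample_id = sample_id, allele_fraction = af, depth = depth,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1L])) b else a

.empty_records <- function() {
  data.frame(
    chrom = character(), pos = numeric(), ref = character(),
    alt = character(), sample_id = character(),
    allele_fraction = numeric(), depth = numeric(),
    stringsAsFactors = FALSE
  )
}

#' Write SNV records back to the BED-style call format
#'
#' Inverse of [read_snv_calls()]: 1-based positions become 0-based starts.
#'
#' @param records Data.frame of SNV records.
#' @param path Output path.
#' @export
write_snv_calls <- function(records, path) {
  out <- data.frame(
    chrom = records$chrom,
    start = records$pos - 1,
    end = records$pos,
    name = paste0(records$ref, ">", records$alt),
    allele_fraction = records$allele_fraction,
    depth = records$depth
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an SNV annotation table
#'
#' TSV with header, columns `chrom`, `pos` (1-based), `ref`, `alt`,
#' `region`, `gene`, `dbsnp_id` (`gene`/`dbsnp_id` may be empty).
#'
#' @param path Path to the annotation file.
#' @return Data.frame keyed by the SNV key `chrom:pos:ref>alt`.
#' @export
read_snv_annotations <- function(path) {
  a <- read.table(path, sep = "\t", header = TRUE, quote = "",
                  comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = "character")
  need <- c("chrom", "pos", "ref", "alt", "region")
  miss <- setdiff(need, names(a))
  if (length(miss)) stop("annotation file missing column(s): ",
                         paste(miss, collapse = ", "))
  a$pos <- as.numeric(a$pos)
  bad <- !a$region %in% REGION_CLASSES
  if (any(bad)) {
    stop("unknown region class(es): ",
         paste(unique(a$region[bad]), collapse = ", "),
         "; valid: ", paste(REGION_CLASSES, collapse = ", "))
  }
  if (is.null(a$gene)) a$gene <- ""
  if (is.null(a$dbsnp_id)) a$dbsnp_id <- ""
  a$snv_key <- .snv_key(a$chrom, a$pos, a$ref, a$alt)
  a
}

#' Read an RNA-editing site list
#'
#' TSV with header, columns `chrom`, `pos` (1-based).
#'
#' @param path Path to the editing-site file.
#' @return Data.frame with columns `chrom`, `pos`.
#' @export
read_editing_sites <- function(path) {
  e <- read.table(path, sep = "\t", header = TRUE, quote = "",
                  comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(e))) {
    stop("editing-site file must have columns chrom, pos")
  }
  e$pos <- as.numeric(e$pos)
  e[, c("chrom", "pos")]
}

#' Read sample group labels
#'
#' TSV with header, columns `sample_id`, `group`. Exactly two groups are
#' required for modeling.
#'
#' @param path Path to the labels file.
#' @return Named factor of group labels, names are sample ids.
#' @export
read_sample_labels <- function(path) {
  l <- read.table(path, sep = "\t", header = TRUE, quote = "",
                  comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(l))) {
    stop("labels file must have columns sample_id, group")
  }
  if (anyDuplicated(l$sample_id)) stop("duplicate sample ids in labels file")
  setNames(factor(l$group), l$sample_id)
}
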