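# Reading SNV calls, building the allele-fraction matrix, coverage
# masking, filtering and region subsetting.

test_that("BED-style rows parse with 0-based start converted to 1-based pos", {
  p <- write_call_fixture(c(
    "# a comment",
    "chr9\t68418920\t68418921\tC>T\t0.42\t18",
    "chr1\t99\t100\tA>G\t0\t12"
  ))
  r <- read_snv_calls(p, "s1")
  expect_equal(nrow(r), 2)
  expect_equal(r$pos, c(68418921, 100))
  expect_equal(r$ref, c("C", "A"))
  expect_equal(r$alt, c("T", "G"))
  expect_equal(r$allele_fraction, c(0.42, 0))
  expect_equal(r$sample_id, c("s1", "s1"))
})

test_that("malformed rows are rejected with line numbers and named checks", {
  bad_af <- write_call_fixture("chr1\t10\t11\tA>G\t1.20\t30")
  expect_error(read_snv_calls(bad_af, "s"), "allele fraction outside")
  short <- write_call_fixture("chr1\t10\t11")
  expect_error(read_snv_calls(short, "s"), "missing required column")
  bad_name <- write_call_fixture(c("chr1\t10\t11\tA>G\t0.5\t30",
                                   "chr1\t20\t21\tAG\t0.5\t30"))
  expect_error(read_snv_calls(bad_name, "s"), "line\\(s\\) 2")
  same <- write_call_fixture("chr1\t10\t11\tA>A\t0.5\t30")
  expect_error(read_snv_calls(same, "s"), "identical")
})

test_that("call records round-trip through write/read", {
  p <- write_call_fixture(c(
    "chr2\t499\t500\tG>C\t0.10\t25",
    "chr2\t999\t1000\tT>A\t0.75\t11",
    "chrX\t41\t42\tA>G\t1\t40"
  ))
  r <- read_snv_calls(p, "sampleZ")
  p2 <- tempfile(fileext = ".bed")
  write_snv_calls(r, p2)
  r2 <- read_snv_calls(p2, "sampleZ")
  expect_equal(r2, r)
})

test_that("matrix cells follow the coverage rule: AF if covered, 0 if covered without a call, NA below threshold", {
  recs <- data.frame(
    chrom = c("chr1", "chr1", "chr2"), pos = c(100, 100, 50),
    ref = c("A", "A", "C"), alt = c("G", "G", "T"),
    sample_id = c("s1", "s2", "s1"),
    allele_fraction = c(0.5, 0.3, 0.8), depth = c(9, 20, 15)
  )
  cov <- expand.grid(chrom = c("chr1", "chr2"), pos = c(100, 50),
                     sample_id = c("s1", "s2", "s3"),
                     stringsAsFactors = FALSE)
  cov <- cov[(cov$chrom == "chr1") == (cov$pos == 100), ]
  cov$depth <- c(9, 15, 20, 30, 12, 4)[seq_len(nrow(cov))]
  m <- build_snv_matrix(recs, coverage = cov, coverage_threshold = 10)
  # depth 9 at chr1:100 s1 -> NA even though a call exists
  expect_true(is.na(m$values["chr1:100:A>G", "s1"]))
  expect_equal(m$values["chr1:100:A>G", "s2"], 0.3)
  expect_equal(m$values["chr2:50:C>T", "s1"], 0.8)
  # brute-force NA count: cells whose depth (record or coverage) < 10
  expect_equal(sum(is.na(m$values)),
               sum(vapply(rownames(m$values), function(k) {
                 ch <- sub(":.*", "", k)
                 po <- as.numeric(strsplit(k, ":")[[1]][2])
                 sum(vapply(colnames(m$values), function(s) {
                   d <- cov$depth[cov$chrom == ch & cov$pos == po &
                                    cov$sample_id == s]
                   rd <- recs$depth[recs$chrom == ch & recs$pos == po &
                                      recs$sample_id == s]
                   if (length(rd)) d <- rd
                   length(d) == 0 || d < 10
                 }, TRUE))
               }, numeric(1))))
})

test_that("conflicting duplicate records are an error, identical ones collapse", {
  base <- data.frame(chrom = "chr1", pos = 10, ref = "A", alt = "G",
                     sample_id = "s1", allele_fraction = 0.5, depth = 20)
  expect_error(build_snv_matrix(rbind(base, transform(base, allele_fraction = 0.6))),
               "conflicting duplicate")
  m <- build_snv_matrix(rbind(base, base))
  expect_equal(unname(m$values[1, 1]), 0.5)
})

test_that("minimum-nonzero filter matches a brute-force recount and is antitone", {
  set.seed(5)
  vals <- matrix(sample(c(NA, 0, 0.3, 0.7), 500, replace = TRUE,
                        prob = c(0.2, 0.4, 0.2, 0.2)), 50, 10)
  rownames(vals) <- sprintf("chr1:%d:A>G", seq_len(50) * 10)
  colnames(vals) <- paste0("S", 1:10)
  m <- snv_matrix(vals)
  counts <- apply(vals, 1, function(r) sum(!is.na(r) & r > 0))
  for (mn in c(0, 1, 3, 5)) {
    fm <- filter_min_nonzero(m, mn)
    expect_equal(rownames(fm$values), rownames(vals)[counts >= mn])
    # surviving values are untouched
    expect_identical(fm$values, vals[counts >= mn, , drop = FALSE])
  }
  sizes <- vapply(0:6, function(mn) nrow(filter_min_nonzero(m, mn)$values),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(nrow(filter_min_nonzero(m, 0)$values), nrow(vals))
})

test_that("region subsetting honours the nonsynonymous-within-exonic relation", {
  m <- small_snv_matrix()
  expect_equal(rownames(subset_by_region(m, "exonic")$values),
               c("chr1:100:A>G", "chr1:200:C>T"))
  expect_equal(rownames(subset_by_region(m, "nonsynonymous_exonic")$values),
               "chr1:200:C>T")
  expect_equal(rownames(subset_by_region(m, editing_only = TRUE)$values),
               c("chr1:200:C>T", "chr2:300:G>A"))
  expect_error(subset_by_region(m, "exome"), "unknown region")
  expect_equal(nrow(subset_by_region(m)$values), 4)
})

test_that("disjoint region classes partition the all-SNVs count", {
  ds <- generate_dataset(generator_spec(n_per_group = 5, n_features = 120,
                                        rng_seed = 77))
  m <- ds$matrix
  disjoint <- c("exonic", "intronic", "utr5", "utr3", "intergenic",
                "updownstream", "ncRNA")
  total <- sum(vapply(disjoint, function(r) {
    nrow(subset_by_region(m, r)$values)
  }, numeric(1)))
  expect_equal(total, nrow(m$values))
})

test_that("region summary counts nonsynonymous inside exonic and matches construction", {
  m <- small_snv_matrix()
  tab <- summarize_regions(m, min_nonzero = 0)
  expect_equal(tab$filtered, tab$total)
  expect_equal(tab$total[tab$region == "exonic"], 2)
  expect_equal(tab$total[tab$region == "nonsynonymous_exonic"], 1)
  expect_equal(tab$total[tab$region == "all_SNVs"], 4)
  expect_equal(tab$total[tab$region == "RNA-editing"], 2)
  tab3 <- summarize_regions(m, min_nonzero = 3)
  expect_true(all(tab3$filtered <= tab3$total))
  expect_true(tab3$total[tab3$region == "nonsynonymous_exonic"] <=
                tab3$total[tab3$region == "exonic"])
})

test_that("the snv_matrix archive round-trips losslessly", {
  m <- small_snv_matrix()
  dir <- tempfile("archive")
  write_snv_matrix(m, dir)
  m2 <- read_snv_matrix(dir)
  expect_identical(m2$values, m$values)
  expect_equal(m2$annotation, m$annotation)
  expect_equal(as.character(m2$labels[colnames(m$values)]),
               as.character(m$labels))
  expect_equal(m2$coverage_threshold, m$coverage_threshold)
})

test_that("annotation and label files attach to the matrix", {
  recs <- data.frame(chrom = "chr1", pos = c(100, 200), ref = c("A", "C"),
                     alt = c("G", "T"), sample_id = rep(c("s1", "s2"), each = 2),
                     allele_fraction = c(0.5, 0.2, 0.1, 0.6), depth = 20)
  anno_path <- tempfile()
  writeLines(c("chrom\tpos\tref\talt\tregion\tgene\tdbsnp_id",
               "chr1\t100\tA\tG\texonic\tGENE1\trs1",
               "chr1\t200\tC\tT\tintronic\tGENE2\t"), anno_path)
  es_path <- tempfile()
  writeLines(c("chrom\tpos", "chr1\t200"), es_path)
  lab_path <- tempfile()
  writeLines(c("sample_id\tgroup", "s1\tcase", "s2\tcontrol"), lab_path)
  m <- build_snv_matrix(recs)
  m <- annotate_snv_matrix(m, read_snv_annotations(anno_path),
                           read_editing_sites(es_path))
  m <- set_labels(m, read_sample_labels(lab_path))
  expect_equal(m$annotation$region, c("exonic", "intronic"))
  expect_equal(m$annotation$gene, c("GENE1", "GENE2"))
  expect_equal(m$annotation$is_editing_site, c(FALSE, TRUE))
  expect_equal(as.character(m$labels), c("case", "control"))
})
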