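test_that("TSV reading returns the expected shape and is deterministic", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t0.5\t-0.2", "g2\t1.5\t0.0", "g3\t-1.0\t2.0"),
             path)
  meta <- data.frame(sample_id = c("s1", "s2"), pert_id = c("a", "b"),
                     cell_id = "MCF7", pert_type = "compound",
                     pert_time = "24 h", pert_dose = "10 uM")
  ps <- read_matrix(path, "tsv", meta)
  expect_s3_class(ps, "ProfileSet")
  expect_equal(dim(ps$values), c(3L, 2L))
  expect_equal(ps$genes, c("g1", "g2", "g3"))
  expect_identical(ps$values, read_matrix(path, "tsv", meta)$values)
  expect_error(read_matrix(path, "tsv", meta[1, ]), "missing annotations")
  expect_error(read_matrix(path, "gctx", meta), "unsupported")
})

test_that("GCT 1.3 round-trips and matches an independent text-parsing oracle", {
  set.seed(42)
  n <- 20
  values <- matrix(round(rnorm(n * 4), 6), n,
                   dimnames = list(sprintf("G%02d", 1:n), paste0("s", 1:4)))
  meta <- data.frame(sample_id = paste0("s", 1:4), pert_id = paste0("d", 1:4),
                     cell_id = "PC3", pert_type = "compound",
                     pert_time = "24 h", pert_dose = "10 uM")
  ps0 <- profile_set(values, rownames(values), meta)
  path <- withr::local_tempfile(fileext = ".gct")
  write_gct(ps0, path)
  ps <- read_matrix(path, "gct", meta)
  # independent oracle: raw line splitting, no shared code with the parser
  lines <- readLines(path)
  oracle <- t(vapply(lines[-(1:3)], function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    as.numeric(f[-1])
  }, numeric(4), USE.NAMES = FALSE))
  expect_equal(unname(ps$values), unname(oracle))
  expect_equal(unname(ps$values), unname(values))
  expect_equal(ps$genes, rownames(values))
})

test_that("malformed GCT files are rejected with a located error", {
  meta <- data.frame(sample_id = "s1", pert_id = "d", cell_id = "c",
                     pert_type = "compound", pert_time = "24 h", pert_dose = "x")
  bad1 <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("not-a-gct", "1\t1\t0\t0", "id\ts1", "g1\t1"), bad1)
  expect_error(read_matrix(bad1, "gct", meta), "line 1")
  bad2 <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.3", "2\t1\t0\t0", "id\ts1", "g1\t1", "g2\tnope"), bad2)
  expect_error(read_matrix(bad2, "gct", meta), "line 5")
})

test_that("averaging collapses timepoints and doses by the arithmetic mean", {
  ps <- tiny_profile_set()
  avg <- average_condition_replicates(ps)
  # two (drugA, MCF7) replicates [1,3,5] and [3,5,7] -> [2,4,6]
  expect_equal(unname(avg$values[, avg$meta$pert_id == "drugA"]), c(2, 4, 6))
  expect_true(all(avg$meta$pert_time == "averaged"))
  expect_true(all(avg$meta$pert_dose == "averaged"))
  # keys already unique -> values unchanged
  expect_equal(unname(avg$values[, 2:3]), unname(ps$values[, 3:4]))

  # brute-force mean oracle: 4 timepoint x dose profiles of a 5-gene drug
  set.seed(7)
  vals <- matrix(rnorm(20), 5)
  meta4 <- data.frame(sample_id = paste0("r", 1:4), pert_id = "d1",
                      cell_id = "c1", pert_type = "compound",
                      pert_time = rep(c("6 h", "24 h"), 2),
                      pert_dose = rep(c("1 uM", "10 uM"), each = 2))
  avg4 <- average_condition_replicates(profile_set(vals, paste0("g", 1:5), meta4))
  oracle <- sapply(1:5, function(i) sum(vals[i, ]) / 4)
  expect_equal(unname(avg4$values[, 1]), oracle)
})

test_that("global normalization divides by the matrix-wide max and inverts", {
  ps <- tiny_profile_set()  # global max |value| is 8
  nm <- normalize_global(ps)
  expect_equal(nm$normalization_scale, 8)
  expect_equal(max(abs(nm$values)), 1)
  expect_equal(nm$values[1, 1], 1 / 8)
  # already normalized -> unchanged, scale 1
  again <- normalize_global(profile_set(nm$values, nm$genes, nm$meta))
  expect_equal(unname(again$values), unname(nm$values))
  expect_equal(again$normalization_scale, 1)
  # round trip on a random matrix
  set.seed(1)
  vals <- matrix(rnorm(100), 10)
  meta <- data.frame(sample_id = paste0("s", 1:10), pert_id = paste0("d", 1:10),
                     cell_id = "c", pert_type = "compound",
                     pert_time = "24 h", pert_dose = "1")
  ps2 <- profile_set(vals, paste0("g", 1:10), meta)
  n2 <- normalize_global(ps2)
  expect_true(all(abs(n2$values) <= 1))
  back <- denormalize_global(n2)
  expect_lt(max(abs(back$values - vals)) / max(abs(vals)), 1e-12)
  # all-zero matrix has no scale
  ps0 <- profile_set(matrix(0, 2, 1), c("a", "b"),
                     meta[1, , drop = FALSE])
  expect_error(normalize_global(ps0), "all-zero")
})

test_that("paired-set construction intersects drug lists across cell types", {
  mk <- function(drugs, cells) {
    combos <- expand.grid(drug = drugs, cell = cells, stringsAsFactors = FALSE)
    vals <- matrix(seq_len(3 * nrow(combos)), 3)
    meta <- data.frame(sample_id = paste(combos$drug, combos$cell, sep = "_"),
                       pert_id = combos$drug, cell_id = combos$cell,
                       pert_type = "compound", pert_time = "averaged",
                       pert_dose = "averaged")
    profile_set(vals, paste0("g", 1:3), meta)
  }
  combos <- rbind(expand.grid(drug = c("a", "b", "c"), cell = "A",
                              stringsAsFactors = FALSE),
                  expand.grid(drug = c("b", "c", "d"), cell = "B",
                              stringsAsFactors = FALSE))
  vals <- matrix(rnorm(3 * nrow(combos)), 3)
  ps <- profile_set(vals, paste0("g", 1:3),
                    data.frame(sample_id = paste(combos$drug, combos$cell, sep = "_"),
                               pert_id = combos$drug, cell_id = combos$cell,
                               pert_type = "compound", pert_time = "averaged",
                               pert_dose = "averaged"))
  paired <- build_paired_set(ps, c("A", "B"))
  expect_equal(paired$drugs, c("b", "c"))
  expect_equal(names(paired$mats), c("A", "B"))
  # identical lists -> all retained
  full <- mk(c("x", "y"), c("A", "B"))
  expect_equal(build_paired_set(full, c("A", "B"))$drugs, c("x", "y"))
  # 3 cells, staggered lists, vs a brute-force triple intersection
  sets <- list(A = c("a", "b", "c", "e"), B = c("b", "c", "d", "e"),
               C = c("c", "e", "f", "a"))
  combos3 <- do.call(rbind, lapply(names(sets), function(ct)
    data.frame(drug = sets[[ct]], cell = ct)))
  ps3 <- profile_set(matrix(rnorm(3 * nrow(combos3)), 3), paste0("g", 1:3),
                     data.frame(sample_id = paste(combos3$drug, combos3$cell, sep = "_"),
                                pert_id = combos3$drug, cell_id = combos3$cell,
                                pert_type = "compound", pert_time = "averaged",
                                pert_dose = "averaged"))
  p3 <- build_paired_set(ps3, c("A", "B", "C"))
  brute <- sort(Reduce(intersect, sets))
  expect_equal(p3$drugs, brute)
  expect_equal(length(p3$drugs) * length(p3$cell_types),
               sum(lengths(lapply(p3$mats, colnames))))
  # errors
  expect_error(build_paired_set(mk("q", "A"), c("A", "Z")), "absent")
  disjoint <- mk(c("a"), "A")
  disjoint2 <- mk(c("b"), "B")
  both <- profile_set(cbind(disjoint$values, disjoint2$values), paste0("g", 1:3),
                      rbind(disjoint$meta, disjoint2$meta))
  expect_error(build_paired_set(both, c("A", "B")), "no perturbagen")
})

test_that("CAGE counts convert via pseudo-count, CPM, and log2 fold change", {
  genes <- c("G1", "G2")
  counts <- cbind(ctrl1 = c(4, 4), trt1 = c(4, 4))
  ps <- cage_counts_to_profiles(counts = `rownames<-`(counts, genes),
                                conditions = c("control", "trt"),
                                gene_space = genes)
  expect_equal(unname(ps$values[, 1]), c(0, 0))  # treatment == control

  # stated-formula hand arithmetic: counts [0, 8], c = 2 -> [2, 10],
  # CPM [166666.67, 833333.33]
  pc <- c(0, 8) + 2
  cpm <- pc * 1e6 / sum(pc)
  expect_equal(cpm, c(166666.67, 833333.33), tolerance = 1e-8)
  counts2 <- cbind(ctrl = c(4, 4), trt = c(0, 8))
  ps2 <- cage_counts_to_profiles(`rownames<-`(counts2, genes),
                                 c("control", "trt"), genes)
  ctrl_cpm <- (c(4, 4) + 2) * 1e6 / sum(c(4, 4) + 2)
  expect_equal(unname(ps2$values[, 1]), log2(cpm / ctrl_cpm))

  # landmark gene absent from the count table -> 0
  ps3 <- cage_counts_to_profiles(`rownames<-`(counts2, genes),
                                 c("control", "trt"),
                                 gene_space = c("G1", "G2", "G3"))
  expect_equal(unname(ps3$values[3, 1]), 0)

  expect_error(cage_counts_to_profiles(`rownames<-`(counts2, genes),
                                       c("a", "trt"), genes), "control")
  expect_error(cage_counts_to_profiles(`rownames<-`(cbind(a = c(-1, 2), b = c(1, 2)),
                                                    genes),
                                       c("control", "trt"), genes), "nonnegative")
})

test_that("log fold change profiles match the element-wise log-ratio", {
  expect_equal(logfc_profile(4, 8, genes = "g1")$values, c(g1 = 1))
  expect_equal(unname(logfc_profile(c(2, 3), c(2, 3), genes = c("a", "b"))$values),
               c(0, 0))
  set.seed(3)
  ctrl <- runif(50, 1, 10)
  trt <- runif(50, 1, 10)
  p <- logfc_profile(ctrl, trt, genes = paste0("g", 1:50))
  expect_equal(unname(p$values), log2(trt) - log2(ctrl))
  expect_error(logfc_profile(c(0, 1), c(1, 1), genes = c("a", "b")), "offset")
  # projection onto a landmark space, case-insensitive, missing -> 0
  proj <- logfc_profile(c(4, 2), c(8, 2), genes = c("abc", "def"),
                        gene_space = c("ABC", "XYZ"))
  expect_equal(unname(proj$values), c(1, 0))
})

test_that("external ingestion helpers filter timepoints and rescale with clipping", {
  ps <- tiny_profile_set()
  f <- filter_timepoint(ps, "24 h")
  expect_equal(ncol(f$values), 3L)
  expect_error(filter_timepoint(ps, "48 h"), "48 h")
  model <- list(normalization_scale = 2)
  scaled <- rescale_to_model(ps, model)
  expect_true(all(abs(scaled$values) <= 1))
  expect_equal(scaled$values[1, 1], 0.5)  # 1 / 2
  expect_equal(scaled$values[3, 4], 1)    # 8 / 2 clipped to 1
})

test_that("average -> normalize -> pair is idempotent on re-application", {
  res <- generate_cohort(n_drugs = 12, n_genes = 20, k = 4, seed = 5)
  paired <- res$paired
  values <- do.call(cbind, paired$mats)
  meta <- do.call(rbind, lapply(paired$cell_types, function(ct)
    data.frame(sample_id = paste(paired$drugs, ct, sep = "_"),
               pert_id = paired$drugs, cell_id = ct, pert_type = "compound",
               pert_time = "averaged", pert_dose = "averaged")))
  ps <- profile_set(values, paired$genes, meta)
  once <- build_paired_set(normalize_global(average_condition_replicates(ps)),
                           paired$cell_types)
  expect_equal(unname(once$mats$cellA), unname(paired$mats$cellA))
  # re-apply: averaging singleton keys and re-normalizing a max-1 matrix
  back <- profile_set(do.call(cbind, once$mats), once$genes, meta)
  twice <- build_paired_set(normalize_global(average_condition_replicates(back)),
                            paired$cell_types)
  expect_equal(twice$mats, once$mats)
})
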