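.mk_annotation <- function(beta, chrom = "chr1", stratum = "typeII",
                           gene = NA_character_, blacklist = FALSE) {
  tibble::tibble(cpg = rownames(beta),
                 chrom = rep_len(chrom, nrow(beta)),
                 stratum = rep_len(stratum, nrow(beta)),
                 gene = rep_len(gene, nrow(beta)),
                 blacklist = rep_len(blacklist, nrow(beta)))
}

test_that("probe filtering removes sex-chromosome and blacklisted probes", {
  beta <- rand_beta(10, 4)
  ann <- .mk_annotation(beta)
  ann$chrom[1:2] <- "chrX"
  ann$blacklist[5] <- TRUE
  out <- filter_probes(beta, ann)
  expect_identical(nrow(out), 7L)
  expect_false(any(c("cg0001", "cg0002", "cg0005") %in% rownames(out)))
  counts <- attr(out, "removed")
  expect_identical(counts$sex_chrom, 2L)
  expect_identical(counts$blacklist, 1L)
  expect_identical(counts$removed, 3L)
})

test_that("a probe removable for two reasons is removed once, tallied twice", {
  beta <- rand_beta(6, 3)
  ann <- .mk_annotation(beta)
  ann$chrom[1] <- "chrY"
  ann$blacklist[1] <- TRUE
  out <- filter_probes(beta, ann)
  expect_identical(nrow(out), 5L)
  counts <- attr(out, "removed")
  expect_identical(counts$sex_chrom, 1L)
  expect_identical(counts$blacklist, 1L)
  expect_identical(counts$removed, 1L)
})

test_that("probe filtering is the identity without sex/blacklist probes and matches set algebra", {
  beta <- rand_beta(12, 3)
  ann <- .mk_annotation(beta)
  expect_identical(filter_probes(beta, ann)[, ], beta)
  expect_error(filter_probes(beta, ann[-1, ]), "cg0001")

  set.seed(5)
  for (rep in 1:5) {
    ann2 <- .mk_annotation(beta,
                           chrom = sample(c("chr1", "chrX", "chrY"), 12, TRUE),
                           blacklist = sample(c(TRUE, FALSE), 12, TRUE))
    out <- filter_probes(beta, ann2)
    expected <- setdiff(rownames(beta),
                        ann2$cpg[ann2$chrom %in% c("chrX", "chrY") |
                                   ann2$blacklist])
    expect_identical(rownames(out), expected)
  }
})

test_that("planted sexes are recovered from chrX methylation", {
  cfg <- sim_config(n_samples = 40, n_cpgs = 400, n_genes = 60,
                    n_signature_genes = 20, chrx_fraction = 0.15,
                    pairs = planted_pairs(0), seed = 21)
  coh <- generate_cohort(cfg)
  calls <- infer_sex(coh$beta, coh$annotation)
  expect_identical(calls$predicted_sex,
                   unname(coh$truth$sex_true[calls$sample]))
  expect_true(all(calls$median_chrx >= 0 & calls$median_chrx <= 1))
  no_x <- coh$annotation[coh$annotation$chrom != "chrX", ]
  expect_error(infer_sex(coh$beta[no_x$cpg, ], no_x), "chrX")
})

test_that("sex mismatches planted in a 433-sample cohort leave 429", {
  cfg <- sim_config(n_samples = 433, n_cpgs = 300, n_genes = 60,
                    n_signature_genes = 20, chrx_fraction = 0.15,
                    pairs = planted_pairs(0), sex_mismatch = 4, seed = 22)
  coh <- generate_cohort(cfg)
  calls <- infer_sex(coh$beta, coh$annotation)
  retained <- drop_sex_mismatches(calls, setNames(coh$panel$sex,
                                                  coh$panel$sample))
  expect_length(retained, 429)
  expect_setequal(attr(retained, "dropped"), coh$truth$mismatched)
  # retained samples' data are untouched
  expect_identical(coh$beta[, retained], coh$beta[, retained])
})

test_that("sex-mismatch edge cases behave", {
  pred <- c(a = "male", b = "female")
  expect_identical(as.character(drop_sex_mismatches(pred, pred)), c("a", "b"))
  expect_warning(r <- drop_sex_mismatches(pred, c(a = "female", b = "male")),
                 "all")
  expect_length(r, 0)
  expect_error(drop_sex_mismatches(pred, c(a = "male")), "only one")
})

test_that("quantile normalization maps samples onto the reference distribution", {
  set.seed(31)
  beta <- rand_beta(50, 4)
  ann <- .mk_annotation(beta)
  out <- quantile_normalize_stratified(beta, ann,
                                       reference_samples = "S001")
  ref_sorted <- sort(beta[, "S001"])
  for (s in colnames(beta)) {
    expect_equal(sort(out[, s]), ref_sorted, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # a sample already equal to the reference is a fixed point
  expect_lt(max(abs(out[, "S001"] - beta[, "S001"])), 1e-12)
  # rank order within the sample is preserved
  expect_identical(order(out[, "S002"]), order(beta[, "S002"]))
})

test_that("strata are normalized independently", {
  set.seed(32)
  beta <- rand_beta(60, 5)
  ann <- .mk_annotation(beta, stratum = rep(c("typeII", "typeI_red"), each = 30))
  out1 <- quantile_normalize_stratified(beta, ann)
  # all samples share sorted values within each stratum
  for (s in unique(ann$stratum)) {
    idx <- which(ann$stratum == s)
    sorted <- apply(out1[idx, ], 2L, sort)
    expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  }
  # perturbing stratum A leaves stratum B's output unchanged
  beta2 <- beta
  beta2[1:30, ] <- rand_beta(30, 5, seed = 99)
  out2 <- quantile_normalize_stratified(beta2, ann)
  expect_identical(out1[31:60, ], out2[31:60, ])

  tiny <- .mk_annotation(beta, stratum = c("solo", rep("typeII", 59)))
  expect_warning(out3 <- quantile_normalize_stratified(beta, tiny), "solo")
  expect_identical(out3[1, ], beta[1, ])
})

test_that("gene mapping drops unmapped rows and collapses duplicates", {
  expr <- matrix(1:12, nrow = 4,
                 dimnames = list(paste0("ENSG", 1:4), paste0("s", 1:3)))
  storage.mode(expr) <- "double"
  map <- tibble::tibble(source_id = paste0("ENSG", 1:4),
                        symbol = c("A", "B", NA, "A"))
  out <- map_and_filter_genes(expr, map)
  expect_identical(sort(rownames(out)), c("A", "B"))
  expect_equal(out["A", ], expr["ENSG1", ] + expr["ENSG4", ],
               ignore_attr = TRUE)
  out_first <- map_and_filter_genes(expr, map, collapse = "first")
  expect_equal(out_first["A", ], expr["ENSG1", ], ignore_attr = TRUE)

  expr_na <- expr
  expr_na["ENSG2", ] <- NA
  out2 <- map_and_filter_genes(expr_na, map)
  expect_false("B" %in% rownames(out2))

  expect_error(map_and_filter_genes(expr, map[-1, ]), "ENSG1")
})
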