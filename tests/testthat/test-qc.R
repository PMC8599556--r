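test_that("inter-array correlation matches a brute-force pairwise oracle", {
  set.seed(31)
  mat <- matrix(runif(5 * 40), 5, 40,
                dimnames = list(paste0("s", 1:5), paste0("cg", 1:40)))
  cc <- interarray_correlation(mat)
  expect_true(isSymmetric(cc))
  expect_equal(unname(diag(cc)), rep(1, 5))
  expect_lt(max(abs(cc - oracle_pairwise_cor(mat))), 1e-12)

  # duplicated sample -> r = 1; complemented betas -> r = -1
  mat2 <- rbind(mat, dup = mat[1, ], anti = 1 - mat[1, ])
  cc2 <- interarray_correlation(mat2)
  expect_equal(cc2["s1", "dup"], 1)
  expect_equal(cc2["s1", "anti"], -1)

  flat <- rbind(mat, flat = rep(0.5, 40))
  expect_error(interarray_correlation(flat), "zero-variance")
})

test_that("average linkage reproduces forced merges and the degenerate case", {
  cc <- matrix(c(1, 0.99, 0.90,
                 0.99, 1, 0.90,
                 0.90, 0.90, 1), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- average_linkage_tree(cc)
  expect_equal(tree$height[1], 0.01)
  first <- sort(abs(tree$merge[1, ]))
  expect_identical(tree$labels[first], c("A", "B"))

  same <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(average_linkage_tree(same)$height, rep(0, 3))

  cc_bad <- cc; cc_bad[1, 2] <- 0.5
  expect_error(average_linkage_tree(cc_bad), "symmetric")
})

test_that("dendrogram heights equal the quadratic-time UPGMA oracle up to n = 12", {
  set.seed(17)
  for (n in 2:12) {
    mat <- matrix(runif(n * 30), n, 30,
                  dimnames = list(paste0("s", 1:n), paste0("cg", 1:30)))
    cc <- interarray_correlation(mat)
    tree <- average_linkage_tree(cc)
    expect_equal(sort(tree$height), oracle_upgma_heights(1 - cc),
                 tolerance = 1e-12)
    expect_true(all(diff(tree$height) >= -1e-12))  # monotone merges
  }
})

test_that("a deliberately sex-swapped sample is the unique mismatch flag", {
  panel <- generate_panel(cat_only_config(n = 40, seed = 13))
  sheet <- panel$sheet
  swap <- 7L
  sheet$sex[swap] <- setdiff(c("female", "male"), sheet$sex[swap])
  flags <- flag_sex_mismatches(panel$matrix, sheet, k = 5)
  expect_identical(as.character(flags), sheet$sample_id[swap])

  # consistent labels -> nothing flagged
  expect_length(flag_sex_mismatches(panel$matrix, panel$sheet, k = 5), 0)
})

test_that("sex-mismatch flagging is invariant to sample order", {
  panel <- generate_panel(cat_only_config(n = 30, seed = 19))
  sheet <- panel$sheet
  sheet$sex[4] <- setdiff(c("female", "male"), sheet$sex[4])
  f1 <- flag_sex_mismatches(panel$matrix, sheet, k = 5)
  set.seed(1)
  perm <- sample(nrow(sheet))
  f2 <- flag_sex_mismatches(panel$matrix[perm, ], sheet[perm, ], k = 5)
  expect_setequal(as.character(f1), as.character(f2))
  expect_error(flag_sex_mismatches(panel$matrix, sheet, k = 30), "smaller")
})

test_that("random-forest OOB separates sex perfectly and is at chance under permutation", {
  panel <- generate_panel(cat_only_config(n = 60, seed = 23))
  err <- oob_trait_accuracy(panel$matrix, panel$sheet$sex, seed = 5)
  expect_equal(as.numeric(err), 0)
  expect_identical(attr(err, "n"), 60L)

  set.seed(99)
  permuted <- sample(rep(c("female", "male"), each = 30))
  err_null <- oob_trait_accuracy(panel$matrix, permuted, seed = 5)
  expect_gte(as.numeric(err_null), 0.4)
  expect_lte(as.numeric(err_null), 0.6)
})

test_that("OOB subsetting filters samples before fitting", {
  panel <- generate_panel(cat_only_config(n = 50, seed = 29))
  young <- panel$sheet$age < 10
  err <- oob_trait_accuracy(panel$matrix, panel$sheet$sex,
                            subset = young, seed = 2)
  expect_identical(attr(err, "n"), sum(young))
  all_f <- rep("female", 50)
  expect_error(oob_trait_accuracy(panel$matrix, all_f), "2 classes")
})

test_that("the QC report bundles correlations, flags and OOB results", {
  panel <- generate_panel(cat_only_config(n = 30, seed = 37))
  sheet <- panel$sheet
  sheet$sex[3] <- setdiff(c("female", "male"), sheet$sex[3])
  rep <- qc_report(panel$matrix, sheet, n_trees = 100, seed = 1)
  expect_true(rep$min_correlation >= -1 && rep$min_correlation <= 1)
  expect_identical(rep$flagged$sample_id, sheet$sample_id[3])
  expect_identical(rep$flagged$reason, "sex_mismatch")
  expect_true(is.numeric(rep$oob$sex))
  f <- withr::local_tempfile(fileext = ".json")
  nw <- withr::local_tempfile(fileext = ".nwk")
  write_qc_report(rep, f, newick_path = nw)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$min_correlation, rep$min_correlation)
  expect_match(readLines(nw), "^\\(")
})
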