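test_that("correlation-test chain handles exact zero and perfect correlation", {
  x <- c(-1, 0, 1, 2)
  y <- c(1, -1, -1, 1)  # orthogonal to centered x
  rec <- cor_test_z(x, y)
  expect_equal(rec$r, 0)
  expect_equal(rec$t, 0)
  expect_equal(rec$p, 1)
  expect_equal(rec$z, 0)

  perfect <- cor_test_z(1:6, 2 * (1:6) + 3)
  expect_equal(perfect$z, 40)
  expect_true(perfect$saturated)

  flat <- cor_test_z(1:5, rep(0.5, 5))
  expect_false(flat$valid)
  expect_error(cor_test_z(1:2, 1:2), "at least 3")
})

test_that("the worked six-point example matches the independent chain", {
  x <- 1:6
  y <- c(2, 1, 4, 3, 6, 5)
  rec <- cor_test_z(x, y)
  expect_equal(rec$r, 29 / 35)
  ora <- oracle_cor_chain(x, y)
  expect_equal(rec$t, ora$t, tolerance = 1e-12)
  expect_equal(rec$p, ora$p, tolerance = 1e-12)
  expect_equal(rec$z, ora$z, tolerance = 1e-10)
})

test_that("cor_test_z agrees with the oracle chain over many random vectors", {
  set.seed(71)
  for (i in 1:300) {
    n <- sample(3:50, 1)
    x <- rnorm(n)
    y <- rnorm(n) + runif(1, -1, 1) * x
    rec <- cor_test_z(x, y)
    ora <- oracle_cor_chain(x, y)
    expect_equal(rec$r, ora$r, tolerance = 1e-10)
    expect_equal(rec$z, ora$z, tolerance = 1e-8)
  }
})

test_that("the vectorized screen equals the per-probe loop", {
  panel <- generate_panel(cat_only_config(n = 25, n_probes = 80, seed = 73))
  recs <- ewas_screen(panel$matrix, panel$sheet$age)
  expect_identical(nrow(recs), 80L)
  for (j in c(1, 10, 40, 80)) {
    one <- cor_test_z(panel$sheet$age, panel$matrix[, j])
    expect_equal(recs$r[j], one$r, tolerance = 1e-12)
    expect_equal(recs$z[j], one$z, tolerance = 1e-12)
  }
  single <- ewas_screen(panel$matrix[, 3, drop = FALSE], panel$sheet$age)
  expect_equal(single$z, cor_test_z(panel$sheet$age,
                                    panel$matrix[, 3])$z)
  expect_identical(single$probe_id, colnames(panel$matrix)[3])
})

test_that("permuted ages give nominal false-positive rates", {
  panel <- generate_panel(cat_only_config(n = 40, n_probes = 2000,
                                          noise_sd = 0.05, seed = 79))
  set.seed(80)
  shuffled <- sample(panel$sheet$age)
  recs <- ewas_screen(panel$matrix, shuffled)
  rate <- mean(recs$p < 0.01, na.rm = TRUE)
  ci <- qbinom(c(0.005, 0.995), nrow(recs), 0.01) / nrow(recs)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("Stouffer combination obeys its closed forms", {
  expect_equal(stouffer_combine(c(1, 1)), sqrt(2))
  expect_equal(stouffer_combine(3.2), 3.2)
  expect_equal(stouffer_combine(c(2, -2)), 0)
  for (k in c(2, 5, 9)) {
    expect_equal(stouffer_combine(rep(1.7, k)), 1.7 * sqrt(k))
  }
  # weights and missing tissues
  expect_equal(stouffer_combine(c(2, NA, 4)), 6 / sqrt(2))
  expect_equal(stouffer_combine(c(1, 1), weights = c(2, 1)), 3 / sqrt(5))
  expect_error(stouffer_combine(c(NA_real_, NA_real_)), "finite")
  zm <- rbind(a = c(1, 1), b = c(2, -2))
  expect_equal(unname(stouffer_combine(zm)), c(sqrt(2), 0))
})

make_records <- function(z, probe_id = sprintf("cg%06d", seq_along(z))) {
  p <- 2 * pnorm(-abs(z))
  data.frame(probe_id = probe_id, p = p, z = z, stringsAsFactors = FALSE)
}

test_that("top-CpG selection enforces the threshold, cap and tie-break", {
  set.seed(83)
  z <- c(runif(600, 6.5, 20), runif(100, -20, -6.5), runif(300, -3, 3))
  recs <- make_records(z)
  top <- select_top_cpgs(recs, p_threshold = 1e-8, cap = 500)
  passing <- recs[recs$p < 1e-8 & recs$z > 0, ]
  expect_identical(length(top$hyper), 500L)
  kept <- sort(passing$z[match(top$hyper, passing$probe_id)])
  expect_equal(min(kept), sort(passing$z, decreasing = TRUE)[500])
  expect_true(all(recs$p[match(top$hypo, recs$probe_id)] < 1e-8))
  expect_length(intersect(top$hyper, top$hypo), 0)

  none <- select_top_cpgs(make_records(runif(50, -3, 3)))
  expect_length(none$hyper, 0)
  expect_length(none$hypo, 0)
})

test_that("top-CpG selection is order-invariant with deterministic ties", {
  z <- c(rep(9, 4), 12, 11)
  recs <- make_records(z, probe_id = c("cg9d", "cg9a", "cg9c", "cg9b",
                                       "cg_big", "cg_mid"))
  top <- select_top_cpgs(recs, cap = 3)
  expect_identical(top$hyper, c("cg_big", "cg_mid", "cg9a"))
  perm <- recs[sample(nrow(recs)), ]
  expect_identical(select_top_cpgs(perm, cap = 3)$hyper, top$hyper)
})

test_that("region summaries count directions per genomic context", {
  ann <- data.frame(probe_id = paste0("cg", 1:6),
                    region = c("promoter", "promoter", "intron", "intron",
                               "promoter", "exon"),
                    island = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  top <- structure(list(hyper = c("cg1", "cg2"), hypo = character(0),
                        p_threshold = 1e-8, cap = 500L),
                   class = "top_cpg_set")
  rs <- region_summary(top, ann)
  expect_equal(rs$prop_hyper[rs$region == "promoter"], 1.0)

  top2 <- structure(list(hyper = "cg3", hypo = "cg4",
                         p_threshold = 1e-8, cap = 500L),
                    class = "top_cpg_set")
  rs2 <- region_summary(top2, ann)
  expect_equal(rs2$prop_hyper[rs2$region == "intron"], 0.5)

  top3 <- structure(list(hyper = "cg_unknown", hypo = character(0),
                         p_threshold = 1e-8, cap = 500L),
                    class = "top_cpg_set")
  expect_error(region_summary(top3, ann), "unannotated")
})

test_that("promoter-biased aging signal yields promoter-skewed hypermethylation", {
  panel <- generate_panel(cat_only_config(n = 60, n_probes = 1500,
                                          seed = 89))
  recs <- ewas_screen(panel$matrix, panel$sheet$age)
  top <- select_top_cpgs(recs, p_threshold = 1e-4, cap = 500)
  rs <- region_summary(top, panel$annotation)
  expect_gt(rs$prop_hyper[rs$region == "promoter"],
            rs$prop_hyper[rs$region == "intron"])
})

test_that("island contrast recovers a constructed shift and is null under identity", {
  set.seed(97)
  z <- rnorm(400)
  ann <- data.frame(probe_id = sprintf("cg%06d", 1:800),
                    region = "intron",
                    island = rep(c(TRUE, FALSE), each = 400))
  recs <- make_records(c(z, z), probe_id = ann$probe_id)
  null_res <- island_association_summary(recs, ann)
  expect_equal(null_res$mean_difference, 0)
  expect_gt(null_res$rank_sum_p, 0.9)

  recs2 <- make_records(c(z + 2, z), probe_id = ann$probe_id)
  shift <- island_association_summary(recs2, ann)
  expect_equal(shift$mean_difference, 2, tolerance = 1e-9)
  expect_lt(shift$rank_sum_p, 1e-10)

  tiny <- make_records(c(1, 2, 3), probe_id = ann$probe_id[c(1, 401, 402)])
  expect_error(island_association_summary(tiny, ann[c(1, 401, 402), ]),
               "at least 2")
})
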