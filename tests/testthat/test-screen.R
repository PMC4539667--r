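make_metrics <- function(gc, stretch, group = NA_character_,
                         gene = NA_character_,
                         ids = sprintf("m%04d", seq_along(gc))) {
  tibble::tibble(id = ids, gene = gene, species = NA_character_,
                 group = group, length_nt = 1000L, gc_fraction = gc,
                 n_stretches = 10L, mean_stretch_len = stretch,
                 max_stretch_len = 10L, total_stretch_nt = 100L)
}

test_that("background model records counts and a consistent histogram", {
  set.seed(31)
  m <- make_metrics(runif(2000, 0.3, 0.7), runif(2000, 3, 8))
  model <- build_background(m)
  expect_s3_class(model, "gc_background")
  expect_equal(model$n, 2000)
  expect_equal(sum(model$histogram$count), 2000)
  expect_equal(model$histogram$bin_start[1], 3)
  expect_error(build_background(m[1:50, ]), "insufficient background")
  # records with missing stretch are excluded and counted
  m2 <- m
  m2$mean_stretch_len[1:7] <- NA
  model2 <- build_background(m2)
  expect_equal(model2$n, 1993)
  expect_equal(model2$n_missing_stretch, 7)
})

test_that("percentile rank matches the counting oracle", {
  m <- make_metrics(seq_len(100) / 100, as.numeric(seq_len(100)))
  model <- build_background(m)
  expect_equal(percentile_rank(model, "mean_stretch_len", 100), 100)
  expect_equal(percentile_rank(model, "mean_stretch_len", 1), 1)
  expect_equal(percentile_rank(model, "mean_stretch_len", 0.5), 0)
  expect_equal(percentile_rank(model, "gc_fraction", 2), 100)
  expect_error(percentile_rank(model, "n_stretches", 1), "unknown metric")
  set.seed(32)
  vals <- runif(500, 2, 9)
  model2 <- build_background(make_metrics(runif(500), vals))
  for (q in c(runif(20, 1, 10), sample(vals, 10))) {
    expect_equal(percentile_rank(model2, "mean_stretch_len", q),
                 brute_force_percentile(vals, q))
  }
})

test_that("outlier flagging applies the two-axis percentile rule", {
  set.seed(33)
  model <- build_background(make_metrics(runif(1000, 0.4, 0.6),
                                         runif(1000, 3, 5)))
  q <- make_metrics(c(0.9, 0.5, 0.9, 0.5), c(9, 4, 4, NA),
                    ids = c("both_hi", "mid", "gc_only", "no_stretch"))
  calls <- flag_outliers(q, model)
  expect_equal(calls$flagged, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(calls$gc_percentile[1], 100)
  expect_match(calls$rule[1], "mode=both")
  expect_match(calls$caveat[4], "not assessable")
  either <- flag_outliers(q, model, mode = "either")
  expect_equal(either$flagged, c(TRUE, FALSE, TRUE, FALSE))
  # threshold 100 flags only values at/above the background maximum
  strict <- flag_outliers(q, model, gc_pct = 100, stretch_pct = 100)
  expect_equal(strict$flagged, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(nrow(flag_outliers(q[0, ], model)), 0)
})

test_that("compare_groups computes the exact max-ECDF D", {
  m_eq <- make_metrics(rep(c(0.1, 0.2, 0.3, 0.4, 0.5), 2), 4,
                       group = rep(c("a", "b"), each = 5))
  res <- compare_groups(m_eq, "a", "b", n_perm = 99, seed = 5)
  expect_equal(res$D, 0)
  expect_equal(res$p_perm, 1)

  m_disj <- make_metrics(c(0.1, 0.15, 0.2, 0.25, 0.3,
                           0.7, 0.75, 0.8, 0.85, 0.9), 4,
                         group = rep(c("a", "b"), each = 5))
  expect_equal(compare_groups(m_disj, "a", "b", n_perm = 99, seed = 5)$D, 1)

  m_small <- make_metrics(c(1, 2, 3, 4, 9, 2, 3, 4, 5, 9) / 10, 4,
                          group = rep(c("a", "b"), each = 5))
  expect_equal(compare_groups(m_small, "a", "b", n_perm = 99, seed = 5)$D,
               0.2)
  expect_error(compare_groups(m_small, "a", "zzz", n_perm = 99, seed = 5),
               "unknown group")

  # exhaustive ECDF evaluation over the pooled support: {1,2,3,4} vs
  # {2,3,4,5} differ by 1/4 at every pooled point
  expect_equal(gcscreen:::ecdf_max_diff(1:4, 2:5), 0.25)

  # groups need at least 5 non-missing values each
  m4 <- make_metrics(c(1:4, 2:5) / 10, 4, group = rep(c("a", "b"), each = 4))
  expect_error(compare_groups(m4, "a", "b", n_perm = 99, seed = 1),
               ">= 5 non-missing")
})

test_that("D agrees with ks.test and is invariant to monotone transforms", {
  set.seed(34)
  for (i in 1:25) {
    x <- rnorm(sample(5:40, 1))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    m <- make_metrics(c(x, y), 4,
                      group = rep(c("a", "b"), c(length(x), length(y))))
    d <- compare_groups(m, "a", "b", n_perm = 99, seed = i)$D
    expect_equal(d, unname(suppressWarnings(
      stats::ks.test(x, y)$statistic)))
    m_t <- m
    m_t$gc_fraction <- exp(3 * m$gc_fraction)  # strictly monotone
    expect_equal(compare_groups(m_t, "a", "b", n_perm = 99, seed = i)$D, d)
  }
})

test_that("permutation p-value is seeded and reproducible", {
  set.seed(35)
  m <- make_metrics(runif(40), 4, group = rep(c("a", "b"), each = 20))
  r1 <- compare_groups(m, "a", "b", n_perm = 500, seed = 99)
  r2 <- compare_groups(m, "a", "b", n_perm = 500, seed = 99)
  expect_identical(r1, r2)
  # p uses the plus-one formula, so it can never be exactly zero
  expect_gte(r1$p_perm, 1 / 501)
})

test_that("ortholog contrast summarizes groups and gates small comparisons", {
  set.seed(36)
  avian <- synthetic_spec(8, 900, 0.72, 4.5, seed = 1, gene = "EPO",
                          group = "birds")
  mamm <- synthetic_spec(8, 900, 0.55, 3.2, seed = 2, gene = "EPO",
                         group = "mammals")
  records <- dplyr::bind_rows(simulate_sequence(avian),
                              simulate_sequence(mamm))
  records$id <- sprintf("r%02d", seq_len(nrow(records)))
  metrics <- composition_metrics(records)
  contrast <- ortholog_contrast(metrics, "EPO", n_perm = 199, seed = 3)
  expect_equal(sort(contrast$summary$group), c("birds", "mammals"))
  gc_birds <- contrast$summary$gc_mean[contrast$summary$group == "birds"]
  gc_mamm <- contrast$summary$gc_mean[contrast$summary$group == "mammals"]
  expect_gt(gc_birds, gc_mamm)
  expect_equal(contrast$comparisons$skipped, "")
  expect_error(ortholog_contrast(metrics, "NOSUCH"), "not found")

  # single group: summary only, no comparisons
  one <- ortholog_contrast(metrics[metrics$group == "birds", ], "EPO")
  expect_equal(nrow(one$comparisons), 0)
  # undersized groups are skipped with a reason, not errored
  small <- ortholog_contrast(metrics[c(1:3, 9:11), ], "EPO")
  expect_match(small$comparisons$skipped, "fewer than 5")
  expect_true(is.na(small$comparisons$D))
})
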