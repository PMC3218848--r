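test_that("constant features yield p = 1 and are never candidates", {
  r <- kw_class_test(rep(3.2, 8), rep(c("A", "B"), each = 4))
  expect_identical(r$p, 1)
  expect_false(r$passed)
})

test_that("KW statistic matches the frozen hand-computed example", {
  # A = (1,2,3), B = (4,5,6): rank sums 6 and 15, H = 27/7
  r <- kw_class_test(1:6, rep(c("A", "B"), each = 3))
  expect_equal(r$statistic, 27 / 7, tolerance = 1e-12)
  # the exhaustive permutation distribution puts 2 of 20 assignments at
  # this extreme
  expect_equal(oracle_kw_perm_p(1:6, rep(c("A", "B"), each = 3)), 2 / 20)
})

test_that("KW H agrees with the rank-formula oracle on all small inputs", {
  set.seed(42)
  designs <- list(c(3, 3), c(4, 4), c(2, 4), c(2, 3, 3), c(2, 2, 4),
                  c(2, 2, 2))
  for (sizes in designs) {
    classes <- rep(LETTERS[seq_along(sizes)], sizes)
    for (rep in 1:6) {
      values <- if (rep %% 2 == 0) {
        rnorm(sum(sizes))              # tie-free
      } else {
        sample(1:3, sum(sizes), TRUE)  # heavy ties, midranks + correction
      }
      if (length(unique(values)) == 1L) next
      expect_equal(kw_class_test(values, classes)$statistic,
                   oracle_kw_h(values, classes), tolerance = 1e-10)
    }
  }
})

test_that("Wilcoxon exact p equals the exhaustive permutation oracle", {
  # frozen extreme case: n = m = 4, two-sided p = 2/70
  r <- wilcoxon_pair(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_equal(r$p, 2 / 70, tolerance = 1e-12)
  expect_identical(r$direction, -1)
  expect_true(r$passed)

  set.seed(7)
  for (i in 1:12) {
    na <- sample(2:4, 1)
    nb <- sample(2:4, 1)
    a <- rnorm(na)
    b <- rnorm(nb)
    expect_equal(wilcoxon_pair(a, b)$p, oracle_wilcox_p(a, b),
                 tolerance = 1e-12, label = sprintf("case %d", i))
  }
})

test_that("identical groups give p = 1 and direction 0", {
  r <- wilcoxon_pair(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p, 1)
  expect_identical(r$direction, 0)
  expect_false(r$passed)
})

test_that("both rank tests are invariant under monotone transforms", {
  set.seed(11)
  values <- rlnorm(12)
  classes <- rep(c("A", "B", "C"), each = 4)
  for (f in list(exp, function(x) x^3, function(x) 5 * x + 2)) {
    expect_equal(kw_class_test(values, classes)$p,
                 kw_class_test(f(values), classes)$p, tolerance = 1e-12)
    w1 <- wilcoxon_pair(values[1:4], values[5:8])
    w2 <- wilcoxon_pair(f(values[1:4]), f(values[5:8]))
    expect_equal(w1$p, w2$p, tolerance = 1e-12)
    expect_identical(w1$direction, w2$direction)
  }
})

test_that("consistency gate passes only with unanimous direction", {
  d <- toy_consistency_data(shift = 10)
  v <- subclass_consistency(d$values, d$annotation, lefse_config(
    min_subclass_size = 3), class_pair = c("A", "B"))
  expect_true(v$passed)
  expect_identical(nrow(v$pairs), 4L)  # 2 x 2 cross-class comparisons
  expect_true(all(v$pairs$direction == -1))
  expect_identical(v$direction, -1)

  # flip one subclass of A above B: significant but discordant
  d2 <- d
  flip <- d2$annotation$subclass == "A_2"
  d2$values[flip] <- d2$values[flip] + 25
  v2 <- subclass_consistency(d2$values, d2$annotation, lefse_config(
    min_subclass_size = 3), class_pair = c("A", "B"))
  expect_false(v2$passed)
  expect_identical(v2$failing_reason, "sign_conflict")

  # no separation at all: p above alpha
  d3 <- toy_consistency_data(shift = 0)
  v3 <- subclass_consistency(d3$values, d3$annotation, lefse_config(
    min_subclass_size = 3), class_pair = c("A", "B"))
  expect_false(v3$passed)
  expect_identical(v3$failing_reason, "p_above_alpha")
})

test_that("small subclasses fall back to the median-sign comparison", {
  d <- toy_consistency_data(shift = 10, n_per_sub = 2L)
  v <- subclass_consistency(d$values, d$annotation,
                            lefse_config(min_subclass_size = 10),
                            class_pair = c("A", "B"))
  expect_true(all(v$pairs$test == "median_sign"))
  expect_true(v$passed)  # medians differ with a common sign
})

test_that("same-name pairing compares only matching strata", {
  ann <- sample_annotation(paste0("s", 1:16),
                           class = rep(c("A", "B"), each = 8),
                           subclass = rep(c("x", "y", "x", "y"), each = 4))
  values <- c(1:8, 11:18)  # B above A in both strata
  cfg <- lefse_config(pairing_mode = "same_name", min_subclass_size = 3)
  v <- subclass_consistency(values, ann, cfg, class_pair = c("A", "B"))
  expect_identical(nrow(v$pairs), 2L)
  expect_identical(v$pairs$subclass_a, v$pairs$subclass_b)

  ann_bad <- sample_annotation(paste0("s", 1:16),
                               class = rep(c("A", "B"), each = 8),
                               subclass = rep(c("x", "y", "x", "z"),
                                              each = 4))
  expect_error(subclass_consistency(values, ann_bad, cfg, c("A", "B")),
               "identical subclass name sets")
})

test_that("with subclasses equal to classes the gate is one Wilcoxon", {
  d <- toy_three_class(shifts = c(0, 3, 6))
  v <- subclass_consistency(d$values, d$annotation,
                            lefse_config(min_subclass_size = 3),
                            class_pair = c("A", "B"))
  expect_identical(nrow(v$pairs), 1L)
  idx_a <- d$annotation$class == "A"
  idx_b <- d$annotation$class == "B"
  w <- wilcoxon_pair(d$values[idx_a], d$values[idx_b])
  expect_equal(v$pairs$p_or_sign, w$p)
})

test_that("multiclass strategies: strict requires all pairs, nonstrict one class", {
  cfg_s <- lefse_config(min_subclass_size = 3)
  cfg_n <- lefse_config(min_subclass_size = 3,
                        multiclass_strategy = "nonstrict")
  sep <- toy_three_class(shifts = c(0, 5, 10))
  g <- multiclass_gate(sep$values, sep$annotation, cfg_s)
  expect_true(g$passed)
  expect_identical(length(g$passing_class_pairs), 3L)
  g2 <- multiclass_gate(sep$values, sep$annotation, cfg_n)
  expect_true(g2$passed)

  # only A separates; B and C overlap
  partial <- toy_three_class(shifts = c(10, 0, 0.1))
  gs <- multiclass_gate(partial$values, partial$annotation, cfg_s)
  gn <- multiclass_gate(partial$values, partial$annotation, cfg_n)
  expect_false(gs$passed)
  expect_true(gn$passed)
})

test_that("strict biomarkers are a subset of nonstrict on random data", {
  spec <- synthetic_spec("a", t = 60, n_features = 60, n_samples = 48,
                         seed = 5)
  syn <- generate_synthetic(spec)
  ann3 <- sample_annotation(syn$table$sample_ids,
                            class = rep(c("A", "B", "C"), each = 16))
  strict <- detect_features(syn$table, ann3, "lefse",
                            lefse_config(normalize = FALSE))
  nonstrict <- detect_features(syn$table, ann3, "lefse",
                               lefse_config(normalize = FALSE,
                                            multiclass_strategy = "nonstrict"))
  expect_true(all(strict %in% nonstrict))
})

test_that("lowering alpha never enlarges the detected set", {
  syn <- generate_synthetic(synthetic_spec("a", t = 40, n_features = 120,
                                           n_samples = 40, seed = 3))
  sets <- lapply(c(0.1, 0.05, 0.01), function(a) {
    detect_features(syn$table, syn$annotation, "lefse",
                    lefse_config(alpha_class = a, alpha_subclass = a,
                                 normalize = FALSE))
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("run_significance screens then gates, deterministically", {
  syn <- synthetic_colitis_table(seed = 2)
  cfg <- lefse_config(alpha_class = 0.01, alpha_subclass = 0.01)
  tab <- normalize_per_sample(syn$table)
  r1 <- run_significance(tab, syn$annotation, cfg)
  r2 <- run_significance(tab, syn$annotation, cfg)
  expect_identical(r1, r2)
  expect_true(all(r1$passed_consistency[r1$passed_consistency] ==
                    r1$passed_kw[r1$passed_consistency]))
  # constant table yields zero candidates
  const <- abundance_table(matrix(1, 3, 6),
                           feature_ids = paste0("f", 1:3))
  ann <- sample_annotation(const$sample_ids, rep(c("A", "B"), each = 3))
  rc <- run_significance(const, ann, lefse_config(normalize = FALSE))
  expect_identical(sum(rc$passed_kw), 0L)
})

test_that("stratified rank alignment removes stratum offsets that cross classes", {
  d <- toy_consistency_data(shift = 6, n_per_sub = 8)
  # strata cut across classes (same stratum observed in A and B), with a
  # large stratum-level offset masking the class shift in pooled ranks
  stratum <- ifelse(d$annotation$subclass %in% c("A_1", "B_1"),
                    "st1", "st2")
  values <- d$values + ifelse(stratum == "st1", 0, 50)
  plain <- kw_class_test(values, d$annotation$class)
  aligned <- kw_class_test(values, d$annotation$class, strata = stratum)
  expect_true(aligned$passed)
  expect_lt(aligned$p, plain$p)
})
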