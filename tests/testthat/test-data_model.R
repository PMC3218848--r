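test_that("a complete five-row file parses into table and annotation", {
  x <- read_lefse_table(toy_lines(), class_row = 1, subclass_row = 2,
                        subject_row = 3)
  expect_identical(dim(x$table), c(2L, 4L))
  expect_identical(x$table$feature_ids,
                   c("Bacteria|Firmicutes", "Bacteria|Bacteroidetes"))
  expect_identical(x$annotation$class, c("A", "A", "B", "B"))
  expect_identical(x$annotation$subclass, c("a1", "a2", "b1", "b2"))
  expect_identical(x$annotation$subject, c("s1", "s2", "s3", "s4"))
  expect_identical(unname(x$table$values[1, ]), c(1, 2, 3, 4))
})

test_that("omitting the subclass row defaults subclasses to classes", {
  lines <- toy_lines()[-2]
  x <- read_lefse_table(lines, class_row = 1, subject_row = 2)
  expect_identical(x$annotation$subclass, x$annotation$class)
  x2 <- read_lefse_table(lines[-2], class_row = 1)
  expect_identical(x2$annotation$subject, x2$annotation$sample_id)
})

test_that("malformed input is rejected with a stage-specific message", {
  bad_cell <- toy_lines()
  bad_cell[4] <- "Bacteria|Firmicutes\t1\tx\t3\t4"
  expect_error(read_lefse_table(bad_cell, class_row = 1, subclass_row = 2,
                                subject_row = 3),
               "non-numeric.*Bacteria\\|Firmicutes.*column 3")
  ragged <- c(toy_lines(), "Extra\t1\t2")
  expect_error(read_lefse_table(ragged, class_row = 1), "ragged")
  dup <- c(toy_lines(), "Bacteria|Firmicutes\t5\t6\t7\t8")
  expect_error(read_lefse_table(dup, class_row = 1, subclass_row = 2,
                                subject_row = 3), "duplicate feature id")
  expect_error(read_lefse_table(toy_lines(), class_row = 99),
               "class row")
  one_class <- c("class\tA\tA\tA\tA", "f\t1\t2\t3\t4")
  expect_error(read_lefse_table(one_class, class_row = 1),
               "fewer than 2 classes")
})

test_that("transposed input parses to the same table", {
  lines <- toy_lines()
  m <- do.call(rbind, strsplit(lines, "\t"))
  tlines <- apply(t(m), 1, paste, collapse = "\t")
  a <- read_lefse_table(lines, class_row = 1, subclass_row = 2,
                        subject_row = 3)
  b <- read_lefse_table(tlines, class_row = 1, subclass_row = 2,
                        subject_row = 3, transpose = TRUE)
  expect_identical(a$table$values, b$table$values)
  expect_identical(a$annotation, b$annotation)
})

test_that("per-sample normalization rescales, warns on zeros, idempotent", {
  # columns are samples: s1 = (2,3,5), s2 all-zero, s3 = (1,0,3)
  tab <- abundance_table(matrix(c(2, 3, 5,
                                  0, 0, 0,
                                  1, 0, 3), ncol = 3,
                                dimnames = list(
                                  paste0("f", 1:3), paste0("s", 1:3))))
  expect_warning(norm <- normalize_per_sample(tab), "all-zero")
  expect_equal(unname(norm$values[, 1]), c(0.2, 0.3, 0.5))
  expect_identical(unname(norm$values[, 2]), c(0, 0, 0))
  expect_equal(unname(norm$values[, 3]), c(0.25, 0, 0.75))
  expect_true(norm$normalized)
  # zero pattern preserved and idempotent
  expect_identical(norm$values == 0, tab$values == 0)
  expect_warning(norm2 <- normalize_per_sample(norm), "all-zero")
  expect_equal(norm2$values, norm$values)
  # custom total
  n100 <- suppressWarnings(normalize_per_sample(tab, total = 100))
  expect_equal(sum(n100$values[, 1]), 100)
})

test_that("negative abundances are rejected unless explicitly allowed", {
  m <- matrix(c(-1, 2), ncol = 1)
  expect_error(abundance_table(m), "non-negative")
  expect_silent(abundance_table(m, nonnegative = FALSE))
})

test_that("write/read round trip reproduces values bit-exactly", {
  x <- read_lefse_table(toy_lines(), class_row = 1, subclass_row = 2,
                        subject_row = 3)
  v <- x$table$values
  v[1, 1] <- 1 / 3  # force a non-terminating decimal
  tab <- abundance_table(v, feature_ids = x$table$feature_ids,
                         sample_ids = x$table$sample_ids)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_lefse_table(tab, x$annotation, f)
  y <- read_lefse_table(f, class_row = 1, subclass_row = 2, subject_row = 3)
  expect_identical(unname(y$table$values), unname(tab$values))
  expect_identical(y$table$feature_ids, tab$feature_ids)
  expect_identical(y$annotation$class, x$annotation$class)
})

test_that("design summary counts subclasses and cross-class comparisons", {
  ann <- sample_annotation(
    paste0("s", 1:12),
    class = rep(c("mucosal", "nonmucosal"), each = 6),
    subclass = rep(c("oral", "gut", "vagina", "skin", "nares", "ear"),
                   each = 2))
  d <- validate_design(ann, lefse_config(min_subclass_size = 3))
  expect_identical(d$classes, c("mucosal", "nonmucosal"))
  expect_identical(nrow(d$subclasses), 6L)
  expect_identical(d$n_pairs_all_pairs, 9L)  # 3 x 3 cross-class pairs
  expect_false(d$same_name_applicable)
  expect_identical(sort(d$small_subclasses), sort(unique(ann$subclass)))

  # stratified design: the same stratum name inside each class
  ann2 <- sample_annotation(paste0("s", 1:8),
                            class = rep(c("A", "B"), each = 4),
                            subclass = rep(c("x", "x"), each = 4))
  d2 <- validate_design(ann2, lefse_config(pairing_mode = "same_name"))
  expect_true(d2$same_name_applicable)
  expect_identical(d2$n_pairs_all_pairs, 1L)

  # under all-pairs semantics that repetition is a nesting violation
  ann3 <- sample_annotation(paste0("s", 1:4), class = c("A", "A", "B", "B"),
                            subclass = c("x", "x", "x", "y"))
  expect_error(validate_design(ann3, lefse_config()),
               "subclass spans multiple classes")
})
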