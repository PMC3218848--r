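# Small constructed inputs shared across test files.

toy_lines <- function() {
  c("class\tA\tA\tB\tB",
    "subclass\ta1\ta2\tb1\tb2",
    "subject\ts1\ts2\ts3\ts4",
    "Bacteria|Firmicutes\t1\t2\t3\t4",
    "Bacteria|Bacteroidetes\t4\t3\t2\t1")
}

# Two classes x two subclasses with a clean shift for the signal feature.
toy_consistency_data <- function(shift = 10, n_per_sub = 6L, seed = 1L) {
  n <- 4L * n_per_sub
  ann <- sample_annotation(
    paste0("s", seq_len(n)),
    class = rep(c("A", "B"), each = 2L * n_per_sub),
    subclass = rep(c("A_1", "A_2", "B_1", "B_2"), each = n_per_sub)
  )
  values <- lefse:::with_seed(seed, {
    rnorm(n) + ifelse(ann$class == "B", shift, 0)
  })
  list(values = values, annotation = ann)
}

# Three-class design with subclasses equal to classes.
toy_three_class <- function(n_per_class = 8L, shifts = c(0, 0, 0),
                            seed = 1L) {
  n <- 3L * n_per_class
  cls <- rep(c("A", "B", "C"), each = n_per_class)
  values <- lefse:::with_seed(seed, {
    rnorm(n, sd = 0.5) + rep(shifts, each = n_per_class)
  })
  list(values = values,
       annotation = sample_annotation(paste0("s", seq_len(n)), cls))
}
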