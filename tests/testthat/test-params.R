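test_that("transition builders produce the stated matrices", {
  # default: dissolving -> product at 10%, small cross-terms, rows sum to 1
  m <- build_transition_default(4)
  expect_equal(m[3, 4], 0.10)
  expect_equal(rowSums(m), rep(1, 4))
  expect_true(all(diag(m) > 0.8))
  off <- m - diag(diag(m))
  off[3, 4] <- 0
  expect_equal(max(off), 1e-3)

  # no conversion pair and eps = 0 gives the identity
  expect_equal(build_transition_default(5, dissolving = NULL, eps = 0),
               diag(5))

  # naive: every entry 1/N, zero variance
  for (n in c(2, 4, 5)) {
    nv <- build_transition_naive(n)
    expect_equal(nv, matrix(1 / n, n, n))
    expect_equal(stats::var(as.vector(nv)), 0)
    expect_equal(rowSums(nv), rep(1, n))
  }

  # naive-stable: diagonal 0.5, off-diagonal mass exactly 0.5 per row
  for (n in c(2, 3, 4, 7)) {
    ns <- build_transition_naive_stable(n)
    expect_equal(diag(ns), rep(0.5, n))
    expect_identical(unname(rowSums(ns - diag(diag(ns)))), rep(0.5, n))
  }
  expect_equal(build_transition_naive_stable(2), build_transition_naive(2))
  expect_equal(build_transition_naive_stable(4)[1, 2], 0.5 / 3)

  expect_error(build_transition_naive(1), "n_classes")
  expect_error(build_transition_default(4, dissolving = 4, product = 3),
               "indices")
  expect_error(build_transition_default(4, eps = 0.5), "off-diagonal")
})

test_that("uniform start vector is a probability distribution", {
  expect_equal(build_start_uniform(4), rep(0.25, 4))
  expect_equal(build_start_uniform(1), 1)
  expect_equal(sum(build_start_uniform(7)), 1)
})

test_that("emission derives from confusion counts by row normalization", {
  expect_equal(emission_from_confusion(diag(4) * 100), diag(4))
  cm <- rbind(c(10, 10, 0, 0), c(0, 5, 0, 0), c(1, 1, 1, 1), c(0, 0, 0, 3))
  em <- emission_from_confusion(cm)
  expect_equal(em[1, ], c(0.5, 0.5, 0, 0))
  expect_equal(rowSums(em), rep(1, 4))

  # random integer counts: rows sum to 1 and scaling back recovers counts
  set.seed(11)
  for (i in 1:20) {
    counts <- matrix(rpois(12, 40), 3, 4)
    if (any(rowSums(counts) == 0)) counts <- counts + 1
    em <- emission_from_confusion(counts)
    expect_equal(rowSums(em), rep(1, 3), tolerance = 1e-12)
    expect_identical(round(em * rowSums(counts)), round(counts + 0))
  }

  # a zero-sum row is an error naming the class
  bad <- confusion_matrix(rbind(c(1, 1), c(0, 0)),
                          row_labels = c("air", "gas"))
  expect_error(emission_from_confusion(bad), "gas")
})

test_that("confidence binning partitions (1/N, 1] as specified", {
  # N = 4, b = 3: bins (25,50], (50,75], (75,100] percent, lower-closed
  expect_identical(confidence_bin(0.6, 4, 3), 1L)
  expect_identical(confidence_bin(0.50, 4, 3), 1L)
  expect_identical(confidence_bin(1.0, 4, 3), 2L)
  expect_identical(confidence_bin(1.0, 7, 5), 4L)
  expect_identical(confidence_bin(0.26, 4, 3), 0L)
  expect_identical(confidence_bin(0.10, 4, 3), 0L) # degenerate, clamps

  # monotone non-decreasing in p and surjective onto 0..b-1
  for (n in 2:5) for (b in c(1, 2, 3, 5)) {
    p <- seq(1 / n + 1e-9, 1, length.out = 400)
    k <- confidence_bin(p, n, b)
    expect_true(all(diff(k) >= 0))
    expect_identical(sort(unique(k)), 0:(b - 1))
  }
  expect_error(confidence_bin(0, 4, 3), "confidence")
  expect_error(confidence_bin(1.2, 4, 3), "confidence")
  expect_error(confidence_bin(0.5, 4, 0), "n_bins")
})

test_that("composite observables enumerate (class, bin) pairs bijectively", {
  expect_identical(composite_observable(0, 0, 3), 0L)
  expect_identical(composite_observable(3, 2, 3), 11L)
  grid <- expand.grid(cls = 0:3, bin = 0:2)
  idx <- composite_observable(grid$cls, grid$bin, 3, n_classes = 4)
  expect_identical(sort(idx), 0:11)
  expect_error(composite_observable(4, 0, 3, n_classes = 4), "pred_class")
  expect_error(composite_observable(0, 3, 3), "bin_index")
})

test_that("diagonal adjustment makes every observable dominated by its own class", {
  n <- 4; b <- 3
  set.seed(21)
  # the pathology: a foreign class dominates one composite column
  em <- random_stochastic(n, n * b)
  em[3, 6] <- 0 # class 2's own low bin dominated by others
  em <- em / rowSums(em)
  adj <- adjust_emission_diagonal(em, n_bins = b)
  base <- rep(1:n, each = b)
  expect_identical(unname(apply(adj, 2, which.max)), base)
  expect_equal(rowSums(adj), rep(1, n), tolerance = 1e-9)

  # already dominant input is a fixed point; adjustment is idempotent
  good <- adjust_emission_diagonal(random_stochastic(n, n * b), n_bins = b)
  expect_equal(adjust_emission_diagonal(good, n_bins = b), good,
               tolerance = 1e-12)

  # post-condition on a batch of random matrices
  for (i in 1:25) {
    m <- random_stochastic(n, n * b, zero_frac = 0.2)
    if (any(colSums(m) == 0)) next
    a <- adjust_emission_diagonal(m, n_bins = b)
    expect_identical(unname(apply(a, 2, which.max)), base)
  }

  zero_col <- cbind(c(0, 0), diag(2) * 0.5, c(1, 0.5))
  zero_col <- zero_col / rowSums(zero_col)
  expect_error(adjust_emission_diagonal(zero_col, n_bins = 2), "zero")
})

test_that("hmm_spec validates row-stochasticity and shapes", {
  spec <- hmm_spec(build_transition_default(4), default_emission(4),
                   class_names = c("Air", "Base", "Dissolving", "Product"))
  expect_s3_class(spec, "hmm_spec")
  expect_identical(spec$n_classes, 4L)
  expect_identical(spec$n_bins, 1L)
  expect_output(print(spec), "HMM-T")

  bad <- build_transition_default(4); bad[1, 1] <- bad[1, 1] + 1e-6
  expect_error(hmm_spec(bad, default_emission(4)), "sum to 1")
  expect_error(hmm_spec(build_transition_naive(4), default_emission(3)),
               "row per hidden class")
  expect_error(hmm_spec(build_transition_naive(4), default_emission(4),
                        n_bins = 3), "columns")
  expect_error(hmm_spec(build_transition_naive(4), default_emission(4),
                        start = c(1, 0, 0)), "length")

  # all builder outputs satisfy the spec invariants
  for (n in 2:5) {
    expect_s3_class(hmm_spec(build_transition_default(n, dissolving = 0,
                                                      product = 1),
                             default_emission(n)), "hmm_spec")
    expect_s3_class(hmm_spec(build_transition_naive(n), default_emission(n)),
                    "hmm_spec")
    expect_s3_class(hmm_spec(build_transition_naive_stable(n),
                             default_emission(n)), "hmm_spec")
  }
})

test_that("rectangular confusion matrices carry bin structure", {
  cm <- confusion_matrix(matrix(1L, 4, 12), n_bins = 3)
  expect_identical(cm$n_classes, 4L)
  expect_identical(cm$col_labels[1:3], c("class0.low", "class0.mid", "class0.high"))
  expect_error(confusion_matrix(matrix(1, 4, 10), n_bins = 3), "columns")
  expect_error(confusion_matrix(matrix(-1, 2, 2)), "non-negative")
})
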