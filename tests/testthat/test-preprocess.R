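test_that("median-of-ratios size factors match the formula", {
  m <- matrix(c(10, 20, 30, 40, 20, 40, 60, 80), ncol = 2,
              dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  sf <- size_factors_median_of_ratios(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  ident <- cbind(s1 = c(5, 8, 2), s2 = c(5, 8, 2), s3 = c(5, 8, 2))
  rownames(ident) <- paste0("g", 1:3)
  expect_equal(unname(size_factors_median_of_ratios(ident)), c(1, 1, 1))

  # 5-gene x 3-sample toy against a hand enumeration of the medians
  set.seed(1)
  toy <- matrix(rpois(15, 50) + 1, 5, 3,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  geo <- apply(toy, 1, function(r) prod(r)^(1 / 3))
  manual <- apply(toy, 2, function(col) median(col / geo))
  expect_equal(unname(size_factors_median_of_ratios(toy)), unname(manual))

  expect_error(size_factors_median_of_ratios(
    matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))),
    "normalization failure")
})

test_that("scaling one sample leaves normalized profiles proportional", {
  set.seed(2)
  m <- matrix(rpois(60, 100) + 1, 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  norm1 <- sweep(m, 2, size_factors_median_of_ratios(m), "/")
  m2 <- m
  m2[, 3] <- m2[, 3] * 7
  norm2 <- sweep(m2, 2, size_factors_median_of_ratios(m2), "/")
  ratio <- norm2 / norm1
  expect_lt(diff(range(ratio)), 1e-10)  # one global constant
})

test_that("log transform with pseudo-count behaves on the stated examples", {
  expect_equal(log_with_pseudocount(matrix(0), 5)[1], log2(5))
  expect_equal(log_with_pseudocount(matrix(3), 5)[1], 3)
  z <- log_with_pseudocount(matrix(0, 3, 3), 5)
  expect_true(all(z == log2(5)))
  na_in <- matrix(c(1, NA, 3, 4), 2, 2)
  expect_true(is.na(log_with_pseudocount(na_in, 1)[2, 1]))
  expect_error(log_with_pseudocount(matrix(0), 0), "pseudo")
})

test_that("compound-minimum imputation fills NAs with the row minimum", {
  v <- matrix(c(NA, 2, 8,
                5, 1, 9), nrow = 2, byrow = TRUE,
              dimnames = list(c("m1", "m2"), paste0("s", 1:3)))
  om <- omics_matrix(v, "metabolome", c("control", "control", "treated"))
  imp <- impute_compound_minimum(om)
  expect_equal(unname(imp$values["m1", ]), c(2, 2, 8))
  expect_equal(unname(imp$values["m2", ]), c(5, 1, 9))  # untouched
  expect_false(any(imp$mask))

  # scattered NAs in a larger matrix: imputed minimum equals observed minimum
  set.seed(3)
  big <- matrix(2^rnorm(120, 10), 20, 6,
                dimnames = list(sprintf("m%02d", 1:20), paste0("s", 1:6)))
  obs_min <- apply(big, 1, min)
  big[sample(120, 15)] <- NA
  pre_min <- apply(big, 1, min, na.rm = TRUE)
  om2 <- omics_matrix(big, "metabolome", rep(c("control", "treated"), each = 3))
  imp2 <- impute_compound_minimum(om2)
  expect_equal(apply(imp2$values, 1, min), pre_min)
  # idempotent
  expect_identical(impute_compound_minimum(imp2)$values, imp2$values)

  # fully missing compound is dropped with a warning
  big[1, ] <- NA
  om3 <- omics_matrix(big, "metabolome", rep(c("control", "treated"), each = 3))
  expect_warning(imp3 <- impute_compound_minimum(om3), "dropping")
  expect_false("m01" %in% imp3$feature_ids)
  expect_identical(attr(imp3, "dropped"), "m01")
})

test_that("batch centering equalizes per-batch means and is a projection", {
  set.seed(4)
  m <- matrix(rnorm(400), 50, 8)
  dimnames(m) <- list(paste0("f", 1:50), paste0("s", 1:8))
  batch <- rep(c("A", "B"), each = 4)

  single <- batch_center(m, rep("A", 8))
  expect_equal(single, m)

  centered <- batch_center(m, batch)
  grand <- rowMeans(m)
  for (b in unique(batch)) {
    expect_true(all(abs(rowMeans(centered[, batch == b]) - grand) < 1e-10))
  }
  # two batches offset by a constant per feature end up with equal means
  delta <- rnorm(50)
  shifted <- m
  shifted[, batch == "B"] <- shifted[, batch == "B"] + delta
  cs <- batch_center(shifted, batch)
  expect_true(all(abs(rowMeans(cs[, batch == "A"]) -
                      rowMeans(cs[, batch == "B"])) < 1e-10))
  # projection: applying twice equals applying once
  expect_equal(batch_center(centered, batch), centered)
  expect_error(batch_center(m, c(batch[-1], NA)), "batch")
})

test_that("top-variable selection is ordered, tie-broken and stable", {
  m <- rbind(flat = rep(1, 4), a = c(0, 0, 0, 10), b = c(0, 0, 10, 10),
             c = c(5, 5, 5, 5.1))
  colnames(m) <- paste0("s", 1:4)
  expect_identical(top_variable_features(m, 1), "b")
  expect_identical(top_variable_features(m, 4), c("b", "a", "c", "flat"))

  # hand-computed variance order on a random toy
  set.seed(5)
  toy <- matrix(rnorm(100), 10, 10,
                dimnames = list(paste0("f", 1:10), paste0("s", 1:10)))
  v <- apply(toy, 1, var)
  expect_identical(top_variable_features(toy, 10),
                   names(sort(v, decreasing = TRUE)))
  # stable under column permutation
  perm <- toy[, sample(10)]
  expect_identical(top_variable_features(toy, 5), top_variable_features(perm, 5))
  # ties broken lexicographically
  tied <- rbind(zz = c(0, 1), aa = c(0, 1), mm = c(0, 1))
  colnames(tied) <- c("s1", "s2")
  expect_identical(top_variable_features(tied, 3), c("aa", "mm", "zz"))
  expect_error(top_variable_features(toy, 0), "positive")
  # the expression-ranked alternative orders by row mean
  expect_identical(top_expressed_features(toy, 10),
                   names(sort(rowMeans(toy), decreasing = TRUE)))
})

test_that("row z-scaling standardizes rows and zeroes constant ones", {
  expect_equal(unname(row_zscore(matrix(1:3, 1))[1, ]), c(-1, 0, 1))
  expect_true(all(row_zscore(matrix(7, 2, 5)) == 0))
  set.seed(6)
  m <- matrix(rnorm(300), 30, 10)
  z <- row_zscore(m)
  expect_true(all(abs(rowMeans(z)) < 1e-10))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-10))
})
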