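test_that("expression round-trips through CSV with metadata intact", {
  expr <- toy_expression()
  path <- file.path(withr::local_tempdir(), "expr.csv")
  write_expression(expr, path, format = "csv")
  back <- load_expression(path, format = "csv",
                          cell_types_path = paste0(path, ".cell_types.tsv"))
  expect_equal(back$values, expr$values)
  expect_equal(back$cell_types, expr$cell_types)
})

test_that("expression validation rejects duplicates and negatives", {
  v <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("g", "g")))
  expect_error(expression_matrix(v), class = "ccb_validation_error")
  v2 <- matrix(c(-1, 1, 1, 1), 2, 2,
               dimnames = list(c("a", "b"), c("g1", "g2")))
  expect_error(expression_matrix(v2), class = "ccb_validation_error")
  expect_error(load_expression(file.path(tempdir(), "nope.csv")),
               class = "ccb_io_error")
})

test_that("mtx triplet expression loading matches the dense file", {
  expr <- toy_expression()
  dir <- withr::local_tempdir()
  mtx <- file.path(dir, "expr.mtx")
  cciboost:::write_mtx(expr$values, mtx)
  writeLines(rownames(expr$values), paste0(mtx, ".rows"))
  writeLines(colnames(expr$values), paste0(mtx, ".cols"))
  ct <- file.path(dir, "types.tsv")
  write.table(data.frame(cell_id = rownames(expr$values),
                         cell_type = expr$cell_types),
              ct, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- load_expression(mtx, format = "mtx_triplet", cell_types_path = ct)
  expect_equal(back$values, expr$values)
  expect_equal(back$cell_types, expr$cell_types)
})

test_that("ligand-receptor database loads in order and de-duplicates", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "db.tsv")
  writeLines(c("ligand\treceptor", "L1\tR1", "L2\tR2", "L1\tR1"), path)
  expect_warning(db <- load_lr_database(path), "duplicated")
  expect_equal(nrow(db), 2L)
  expect_equal(db$ligand, c("L1", "L2"))

  writeLines("ligand\treceptor", path)
  empty <- load_lr_database(path)
  expect_equal(nrow(empty), 0L)
  expect_error(build_ccim(toy_expression(), empty),
               class = "ccb_empty_feature_space_error")

  writeLines(c("a\tb", "L1\tR1"), path)
  expect_error(load_lr_database(path), class = "ccb_format_error")
})

test_that("build_ccim scores are products of sender ligand and receiver receptor", {
  # two cells: A expresses only the ligand (2), B only the receptor (3)
  v <- matrix(c(2, 0,
                0, 3), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("L", "R")))
  expr <- expression_matrix(v)
  x <- build_ccim(expr, lr_database("L", "R"), include_self_pairs = TRUE)
  expect_equal(nrow(x$scores), 4L)
  got <- setNames(x$scores[, 1], paste(x$pairs$sender_id, x$pairs$receiver_id))
  expect_equal(got[["A B"]], 6)
  expect_equal(unname(got[c("A A", "B A", "B B")]), c(0, 0, 0))
})

test_that("pair enumeration is ordered and respects the self-pair flag", {
  expr <- toy_expression()
  db <- toy_db()
  with_self <- build_ccim(expr, db, include_self_pairs = TRUE)
  without <- build_ccim(expr, db, include_self_pairs = FALSE)
  expect_equal(nrow(with_self$scores), 9L)
  expect_equal(nrow(without$scores), 6L)
  expect_false(any(without$pairs$sender_id == without$pairs$receiver_id))
  # directedness: (A,B) and (B,A) are distinct rows
  key <- paste(with_self$pairs$sender_id, with_self$pairs$receiver_id)
  expect_true(all(c("A B", "B A") %in% key))
  expect_equal(anyDuplicated(key), 0L)
})

test_that("build_ccim agrees with a brute-force loop on random inputs", {
  set.seed(42)
  for (rep in 1:5) {
    n_cells <- sample(3:6, 1); n_genes <- sample(4:8, 1)
    v <- matrix(abs(rnorm(n_cells * n_genes)), n_cells, n_genes,
                dimnames = list(paste0("c", 1:n_cells), paste0("g", 1:n_genes)))
    expr <- expression_matrix(v)
    k <- sample(2:4, 1)
    db <- lr_database(sample(colnames(v), k), sample(colnames(v), k))
    x <- build_ccim(expr, db)
    oracle <- matrix(0, nrow(x$scores), ncol(x$scores))
    for (i in seq_len(nrow(x$scores))) {
      for (j in seq_len(ncol(x$scores))) {
        oracle[i, j] <- v[x$pairs$sender_id[i], x$features$ligand[j]] *
          v[x$pairs$receiver_id[i], x$features$receptor[j]]
      }
    }
    expect_equal(unname(x$scores), oracle)
  }
})

test_that("genes missing from the expression matrix drop their pairs with a warning", {
  expr <- toy_expression()
  db <- lr_database(c("L1", "LX"), c("R1", "RX"))
  expect_warning(x <- build_ccim(expr, db), "absent")
  expect_equal(nrow(x$features), 1L)
  db_all_missing <- lr_database("LX", "RX")
  expect_warning(
    expect_error(build_ccim(expr, db_all_missing),
                 class = "ccb_empty_feature_space_error"))
})

test_that("activity filter removes all-zero and low-occupancy columns", {
  x <- random_ccim(n = 20, p = 10, seed = 3)
  x$scores[, 2] <- 0                      # all-zero column
  x$scores[1:19, 5] <- 0                  # 5% occupancy
  x$scores[, 7] <- 1                      # constant nonzero: zero variance
  filtered <- filter_active_features(x, min_nonzero_fraction = 0.1)
  expect_equal(ncol(filtered$scores), 7L)
  expect_equal(filtered$features, x$features[-c(2, 5, 7), ],
               ignore_attr = "row.names")
  # threshold 0 removes only the zero-variance columns
  f0 <- filter_active_features(x, min_nonzero_fraction = 0)
  expect_equal(ncol(f0$scores), 8L)
  x$scores[] <- 0
  expect_error(filter_active_features(x), class = "ccb_empty_feature_space_error")
})

test_that("standardization gives exact zero mean / unit population SD and is idempotent", {
  x <- random_ccim(n = 30, p = 8, seed = 7)
  z <- standardize_features(x)
  expect_true(z$standardized)
  expect_lt(max(abs(colMeans(z$scores))), 1e-8)
  expect_lt(max(abs(sqrt(colMeans(sweep(z$scores, 2, colMeans(z$scores))^2)) - 1)), 1e-6)
  z2 <- standardize_features(z)
  expect_lt(max(abs(z2$scores - z$scores)), 1e-10)
  # constant column is a named error
  x$scores[, 3] <- 5
  err <- expect_error(standardize_features(x), class = "ccb_constant_feature_error")
  expect_match(conditionMessage(err), "L3_R3")
})

test_that("filter then standardize yields finite values on sparse random scores", {
  set.seed(11)
  for (rep in 1:10) {
    x <- random_ccim(n = 25, p = 12, seed = rep + 100)
    x$scores[runif(length(x$scores)) < 0.7] <- 0
    out <- tryCatch(
      standardize_features(filter_active_features(x, 0.05)),
      ccb_empty_feature_space_error = function(e) NULL)
    if (!is.null(out)) expect_true(all(is.finite(out$scores)))
  }
})

test_that("CCIM round-trips losslessly through csv and mtx", {
  x <- standardize_features(random_ccim(n = 20, p = 10, seed = 5))
  for (fmt in c("csv", "mtx")) {
    dir <- file.path(withr::local_tempdir(), fmt)
    write_ccim(x, dir, format = fmt)
    back <- read_ccim(dir)
    expect_lt(max(abs(back$scores - x$scores)), 1e-12)
    expect_equal(back$pairs, x$pairs)
    expect_equal(back$features, x$features)
    expect_true(back$standardized)
  }
})

test_that("truncated sidecars and empty CCIMs are refused", {
  x <- random_ccim(n = 10, p = 4, seed = 9)
  dir <- withr::local_tempdir()
  write_ccim(x, dir)
  pairs <- readLines(file.path(dir, "pairs.tsv"))
  writeLines(pairs[1:5], file.path(dir, "pairs.tsv"))
  expect_error(read_ccim(dir), class = "ccb_format_error")
  empty <- x
  empty$scores <- x$scores[0, , drop = FALSE]
  empty$pairs <- x$pairs[0, , drop = FALSE]
  expect_error(write_ccim(ccim(empty$scores, empty$pairs, empty$features),
                          withr::local_tempdir()),
               class = "ccb_empty_pair_set_error")
})
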