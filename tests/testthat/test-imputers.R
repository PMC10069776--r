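test_that("auxiliary screen keeps strong predictors and excludes the target", {
  set.seed(21)
  n <- 200
  x <- rnorm(n)
  specs <- list(trait_spec("y", "continuous"), trait_spec("x", "continuous"),
                trait_spec("noise", "continuous"))
  tt <- trait_table(sprintf("s%03d", 1:n), specs,
                    data.frame(y = 2 * x + rnorm(n), x = x, noise = rnorm(n)))
  kept <- select_auxiliary_traits(tt, "y")
  expect_true("x" %in% kept)
  expect_false("y" %in% kept)
})

test_that("auxiliary screen retains independent auxiliaries at roughly alpha", {
  retained <- 0L
  n_sim <- 400L
  for (i in seq_len(n_sim)) {
    set.seed(3000 + i)
    n <- 100
    specs <- list(trait_spec("y", "continuous"), trait_spec("a", "continuous"))
    tt <- trait_table(sprintf("s%03d", 1:n), specs,
                      data.frame(y = rnorm(n), a = rnorm(n)))
    if ("a" %in% select_auxiliary_traits(tt, "y")) retained <- retained + 1L
  }
  expect_lt(abs(retained / n_sim - 0.05), 0.035)
})

test_that("screen families match target dtypes, including polytomous targets", {
  set.seed(5)
  n <- 150
  z <- rnorm(n)
  act <- cut(z + rnorm(n, sd = 0.5), c(-Inf, -0.3, 0.7, Inf),
             labels = c("diurnal", "nocturnal", "cathemeral"))
  specs <- list(
    trait_spec("act", "multicategorical",
               categories = c("diurnal", "nocturnal", "cathemeral")),
    trait_spec("z", "continuous"),
    trait_spec("cnt", "count"),
    trait_spec("bin", "binary", categories = c("no", "yes")))
  tt <- trait_table(sprintf("s%03d", 1:n), specs,
                    data.frame(act = as.character(act), z = z,
                               cnt = rpois(n, exp(0.5 + 0.5 * z)),
                               bin = ifelse(z + rnorm(n) > 0, "yes", "no")))
  expect_true("z" %in% select_auxiliary_traits(tt, "act"))
  expect_true("z" %in% select_auxiliary_traits(tt, "cnt"))
  expect_true("z" %in% select_auxiliary_traits(tt, "bin"))
  expect_error(select_auxiliary_traits(tt, "nope"), "unknown target")
})

test_that("mean/mode fills means and lexicographic-tie modes", {
  specs <- list(trait_spec("v", "continuous"),
                trait_spec("c", "binary", categories = c("a", "b")))
  tt <- trait_table(paste0("s", 1:3), specs,
                    data.frame(v = c(1, 2, NA), c = c("a", "b", NA)))
  imp <- impute_mean_mode(tt)
  expect_equal(imp$table$data$v[3], 1.5)
  expect_identical(as.character(imp$table$data$c[3]), "a")  # tie -> smallest
  expect_identical(nrow(imp$imputed_cells), 2L)

  complete <- trait_table(paste0("s", 1:2), specs,
                          data.frame(v = c(1, 2), c = c("a", "b")))
  out <- impute_mean_mode(complete)
  expect_identical(nrow(out$imputed_cells), 0L)
  expect_tables_equal(out$table, complete)
})

knn_toy <- function() {
  specs <- list(trait_spec("y", "continuous"), trait_spec("p1", "continuous"),
                trait_spec("p2", "binary", categories = c("no", "yes")))
  trait_table(paste0("s", 1:5), specs,
              data.frame(y = c(10, 20, 30, 40, NA),
                         p1 = c(0, 1, 2, 3, 0),
                         p2 = c("no", "no", "yes", "yes", "no")))
}

test_that("KNN with k = 1 copies the identical donor", {
  tt <- knn_toy()
  imp <- impute_knn(tt, k_neighbors = 1)
  expect_equal(imp$table$data$y[5], 10)  # s1 matches s5 exactly
})

test_that("KNN nearest-donor sets match brute-force Gower enumeration", {
  tt <- knn_toy()
  # brute force over the two predictors, range-normalized
  p1 <- tt$data$p1
  d <- abs(p1 - p1[5]) / diff(range(p1))
  d <- (d + (as.character(tt$data$p2) != "no")) / 2
  ord <- order(d[1:4], 1:4)
  for (k in 1:4) {
    imp <- impute_knn(tt, k_neighbors = k)
    expect_equal(imp$table$data$y[5], median(tt$data$y[ord[1:k]]))
  }
})

test_that("KNN with k = all donors degenerates to the all-donor median/mode", {
  tt <- knn_toy()
  imp <- impute_knn(tt, k_neighbors = 4)
  expect_equal(imp$table$data$y[5], median(c(10, 20, 30, 40)))
  expect_error(impute_knn(tt, k_neighbors = 5), "exceeds")
})

test_that("iterative RF recovers a duplicated trait nearly exactly", {
  set.seed(77)
  n <- 200
  x <- rnorm(n)
  specs <- list(trait_spec("y", "continuous"), trait_spec("x", "continuous"),
                trait_spec("w", "continuous"))
  y <- x
  y[1:40] <- NA
  tt <- trait_table(sprintf("s%03d", 1:n), specs,
                    data.frame(y = y, x = x, w = rnorm(n)))
  preds <- suppressWarnings(select_all_auxiliary_traits(tt))
  expect_identical(preds$y, "x")  # the screen drops the noise column
  imp <- impute_missforest(tt, predictors = preds, n_trees = 100, seed = 2)
  rmse <- sqrt(mean((imp$table$data$y[1:40] - x[1:40])^2))
  expect_lt(rmse, 0.1)
})

test_that("iterative RF leaves complete tables unchanged", {
  tt <- knn_toy()
  tt$data$y[5] <- 50
  imp <- impute_missforest(tt, n_trees = 10, seed = 1)
  expect_identical(nrow(imp$imputed_cells), 0L)
  expect_tables_equal(imp$table, tt)
})

test_that("RF on pure-noise predictors is no better than mean imputation", {
  ratios <- numeric(40)
  for (i in seq_along(ratios)) {
    set.seed(500 + i)
    n <- 60
    specs <- list(trait_spec("y", "continuous"), trait_spec("n1", "continuous"),
                  trait_spec("n2", "continuous"))
    y_true <- rnorm(n)
    y <- y_true
    y[1:12] <- NA
    tt <- trait_table(sprintf("s%03d", 1:n), specs,
                      data.frame(y = y, n1 = rnorm(n), n2 = rnorm(n)))
    rf <- impute_missforest(tt, n_trees = 50, seed = i)
    mm <- impute_mean_mode(tt)
    mse <- function(imp) mean((imp$table$data$y[1:12] - y_true[1:12])^2)
    ratios[i] <- mse(rf) / mse(mm)
  }
  # no leakage: random forests cannot beat the baseline without information
  expect_gt(mean(ratios), 1 - 0.15)
})

test_that("MICE with m = 1 equals its single chain and stays in range", {
  set.seed(9)
  n <- 80
  x <- rnorm(n)
  specs <- list(trait_spec("y", "continuous"), trait_spec("x", "continuous"))
  y <- 2 * x + rnorm(n, sd = 0.2)
  y[1:15] <- NA
  tt <- trait_table(sprintf("s%03d", 1:n), specs, data.frame(y = y, x = x))
  imp <- impute_mice(tt, m_imputations = 1, seed = 4)
  expect_equal(imp$table$data$y[1:15],
               imp$per_imputation_values$y$m1, tolerance = 1e-12)
  # PMM imputations are members of the observed-value set
  expect_true(all(imp$per_imputation_values$y$m1 %in% y[16:n]))
  expect_true(all(imp$table$data$y[1:15] >= min(y[16:n]) &
                    imp$table$data$y[1:15] <= max(y[16:n])))
})

test_that("PMM with donor pool 1 copies the nearest-fitted-mean donor", {
  specs <- list(trait_spec("y", "continuous"), trait_spec("x", "continuous"))
  # y = x exactly on the observed rows: fitted means are the x values
  tt <- trait_table(paste0("s", 1:5), specs,
                    data.frame(y = c(1, 2, 3, 4, NA), x = c(1, 2, 3, 4, 3.2)))
  imp <- impute_mice(tt, m_imputations = 1, donor_pool_k = 1,
                     chain_iterations = 2, seed = 1)
  expect_equal(imp$table$data$y[5], 3)
})

test_that("MICE pools means for numerical and modes for categorical traits", {
  set.seed(31)
  n <- 120
  z <- rnorm(n)
  specs <- list(trait_spec("y", "continuous"),
                trait_spec("b", "binary", categories = c("no", "yes")),
                trait_spec("z", "continuous"))
  b <- ifelse(z + rnorm(n, sd = 0.5) > 0, "yes", "no")
  y <- z + rnorm(n, sd = 0.3)
  y[1:20] <- NA
  b[21:40] <- NA
  tt <- trait_table(sprintf("s%03d", 1:n), specs,
                    data.frame(y = y, b = b, z = z))
  imp <- impute_mice(tt, m_imputations = 5, seed = 8)
  pv <- imp$per_imputation_values
  expect_equal(imp$table$data$y[1:20], rowMeans(as.matrix(pv$y[, -1])),
               tolerance = 1e-12)
  pooled_b <- apply(as.matrix(pv$b[, -1]), 1, function(r)
    names(sort(table(r), decreasing = TRUE))[1])
  agree <- mean(as.character(imp$table$data$b[21:40]) == pooled_b)
  expect_gt(agree, 0.9)  # ties may legitimately differ in break direction
})

test_that("every imputer preserves observed cells and completes the table", {
  study <- simulate_study(n_taxa = 50, seed = 12)
  nc <- build_near_complete_case(study$table)
  truth <- apply_transforms(nc)
  plan <- mask_mcar(nc, 0.2, replicate_seed = 3)[[1]]
  masked <- apply_mask_plan(truth, plan)
  obs_mask <- !is.na(as.matrix(masked$data))
  for (imp in list(impute_mean_mode(masked),
                   impute_knn(masked),
                   impute_missforest(masked, n_trees = 30, seed = 2),
                   impute_mice(masked, m_imputations = 2, seed = 2))) {
    expect_false(anyNA(imp$table$data))
    for (tr in names(masked$specs)) {
      o <- obs_mask[, tr]
      if (is.factor(masked$data[[tr]]))
        expect_identical(as.character(imp$table$data[[tr]][o]),
                         as.character(masked$data[[tr]][o]))
      else expect_identical(imp$table$data[[tr]][o], masked$data[[tr]][o])
    }
    expect_identical(nrow(imp$imputed_cells), sum(!obs_mask))
  }
})

test_that("imputation is deterministic given table, config, and seed", {
  study <- simulate_study(n_taxa = 40, seed = 22)
  nc <- build_near_complete_case(study$table)
  truth <- apply_transforms(nc)
  plan <- mask_mcar(nc, 0.2, replicate_seed = 5)[[1]]
  masked <- apply_mask_plan(truth, plan)
  for (builder in list(
    function() impute_knn(masked),
    function() impute_missforest(masked, n_trees = 20, seed = 7),
    function() impute_mice(masked, m_imputations = 3, seed = 7))) {
    a <- builder(); b <- builder()
    expect_identical(a$table$data, b$table$data)
  }
})

test_that("eigenvector columns are appended complete and never imputed", {
  study <- simulate_study(n_taxa = 40, seed = 2)
  nc <- build_near_complete_case(study$table)
  evs <- extract_eigenvectors(study$tree, nc$species, source_label = "COI")
  aug <- augment_with_eigenvectors(nc, evs)
  ev_cols <- grep("^ev_", names(aug$data), value = TRUE)
  expect_identical(length(ev_cols),
                   ncol(evs$coordinates))
  expect_false(anyNA(aug$data[ev_cols]))
  expect_identical(missing_fractions(aug), missing_fractions(nc))
  imp <- impute_knn(apply_transforms(aug))
  expect_false(any(imp$imputed_cells$trait %in% ev_cols))
  expect_error(augment_with_eigenvectors(aug, evs), "duplicate column")
})

test_that("species without eigenvector coordinates are excluded with a notice", {
  study <- simulate_study(n_taxa = 40, seed = 2)
  nc <- build_near_complete_case(study$table)
  dropped_tree <- ape::drop.tip(study$tree, nc$species[1])
  evs <- extract_eigenvectors(dropped_tree, source_label = "gene")
  expect_message(aug <- augment_with_eigenvectors(nc, evs), "excluding 1 species")
  expect_false(nc$species[1] %in% aug$species)
})

test_that("parameter tuning minimizes error with deterministic tie-breaking", {
  study <- simulate_study(n_taxa = 60, seed = 33, pre_missing_fraction = 0)
  truth <- apply_transforms(study$table)
  plans <- lapply(1:3, function(r)
    mask_mcar(study$table, 0.2, replicate_seed = r)[[1]])
  grid <- list(imputation_config("knn", k_neighbors = 1),
               imputation_config("knn", k_neighbors = 5),
               imputation_config("knn", k_neighbors = 30))
  best <- tune_parameters(grid, truth, plans)
  errs <- attr(best, "errors")
  expect_identical(best$k_neighbors,
                   grid[[which.min(errs)]]$k_neighbors)
  single <- tune_parameters(grid[2], truth, plans)
  expect_identical(single$k_neighbors, 5L)
  # forced tie: identical configs -> smallest parameters / first declared wins
  tie <- tune_parameters(list(imputation_config("knn", k_neighbors = 5),
                              imputation_config("knn", k_neighbors = 5)),
                         truth, plans)
  expect_identical(tie$k_neighbors, 5L)
  expect_error(tune_parameters(list(), truth, plans), "empty")
})
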