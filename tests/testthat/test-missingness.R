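complete_numeric_table <- function(n = 100, p = 3, seed = 1) {
  set.seed(seed)
  specs <- lapply(paste0("t", seq_len(p)), trait_spec, dtype = "continuous")
  vals <- as.data.frame(matrix(rnorm(n * p), n,
                               dimnames = list(NULL, paste0("t", seq_len(p)))))
  trait_table(sprintf("s%03d", seq_len(n)), specs, vals)
}

test_that("MCAR masks round(p*n) cells per trait, nested across proportions", {
  tt <- complete_numeric_table(100)
  plans <- mask_mcar(tt, c(0.10, 0.20), replicate_seed = 11)
  for (trait in paste0("t", 1:3)) {
    expect_identical(sum(plans[[1]]$cells$trait == trait), 10L)
    expect_identical(sum(plans[[2]]$cells$trait == trait), 20L)
  }
  key <- function(p) paste(p$cells$species, p$cells$trait)
  expect_true(all(key(plans[[1]]) %in% key(plans[[2]])))
  expect_identical(length(setdiff(key(plans[[2]]), key(plans[[1]]))), 30L)
})

test_that("MCAR rejects invalid proportions and infeasible targets", {
  tt <- complete_numeric_table(50)
  expect_error(mask_mcar(tt, c(0)), "in \\(0, 1\\]")
  expect_error(mask_mcar(tt, c(0.2, 0.1)), "strictly increasing")
  tt$data$t1[1:40] <- NA
  expect_error(mask_mcar(tt, 0.4), "only .* observed cells")
})

test_that("MCAR plans never target already-missing cells and count exactly", {
  tt <- complete_numeric_table(60, seed = 3)
  tt$data$t1[1:6] <- NA  # pre-existing missingness
  plans <- mask_mcar(tt, c(0.1, 0.3), replicate_seed = 5)
  for (plan in plans) {
    masked <- apply_mask_plan(tt, plan)  # errors on already-missing targets
    per_trait <- table(plan$cells$trait)
    for (trait in names(per_trait)) {
      extra <- sum(is.na(masked$data[[trait]])) - sum(is.na(tt$data[[trait]]))
      expect_identical(as.integer(per_trait[[trait]]), extra)
    }
  }
})

test_that("masking is reproducible: same seed gives identical plans", {
  tt <- complete_numeric_table(80, seed = 2)
  a <- mask_mcar(tt, c(0.1, 0.2), replicate_seed = 99)
  b <- mask_mcar(tt, c(0.1, 0.2), replicate_seed = 99)
  expect_identical(a, b)
  c <- mask_mcar(tt, c(0.1, 0.2), replicate_seed = 100)
  expect_false(identical(a[[1]]$cells, c[[1]]$cells))
})

mar_reference_fixture <- function(n = 1000, beta0 = -1, beta1 = 2, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  aux2 <- rnorm(n)
  y <- rnorm(n)
  miss <- runif(n) < plogis(beta0 + beta1 * x)
  y[miss] <- NA
  specs <- list(trait_spec("target", "continuous"),
                trait_spec("x", "continuous"),
                trait_spec("aux2", "continuous"))
  trait_table(sprintf("s%04d", 1:n), specs,
              data.frame(target = y, x = x, aux2 = aux2))
}

test_that("MAR model recovers a generating covariate effect", {
  hits <- 0L
  for (i in 1:200) {
    ref <- mar_reference_fixture(seed = i)
    model <- fit_mar_model(ref, "target")
    if (model$eligible && "x" %in% model$predictors &&
        model$coefficients[["x"]] > 0) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("MAR screen has roughly nominal type-I behaviour under independence", {
  verdicts <- 0L
  n_sim <- 200L
  for (i in 1:n_sim) {
    set.seed(1000 + i)
    n <- 1000
    specs <- list(trait_spec("target", "continuous"),
                  trait_spec("a1", "continuous"),
                  trait_spec("a2", "continuous"))
    y <- rnorm(n)
    y[runif(n) < 0.2] <- NA  # missingness independent of the auxiliaries
    ref <- trait_table(sprintf("s%04d", 1:n), specs,
                       data.frame(target = y, a1 = rnorm(n), a2 = rnorm(n)))
    if (!fit_mar_model(ref, "target")$eligible) verdicts <- verdicts + 1L
  }
  expected <- (1 - 0.05)^2  # two independent auxiliaries
  expect_lt(abs(verdicts / n_sim - expected), 0.08)
})

test_that("MAR masking errors on fully observed targets", {
  ref <- complete_numeric_table(50)
  expect_error(fit_mar_model(ref, "t1"), "fully observed")
})

test_that("MAR intercept calibration hits the expected count within 1", {
  ref <- mar_reference_fixture(seed = 42)
  model <- fit_mar_model(ref, "target")
  tt <- complete_numeric_table(200, seed = 9)
  names(tt$data) <- c("target", "x", "aux2")
  names(tt$specs) <- c("target", "x", "aux2")
  for (i in seq_along(tt$specs)) tt$specs[[i]]$name <- names(tt$specs)[i]
  plan <- mask_mar(tt, model, target_proportion = 0.2, replicate_seed = 3)
  lp <- traitimpute:::mar_linear_predictor(tt, model)
  achieved <- sum(plogis(lp + plan$intercept_shift))
  expect_lt(abs(achieved - round(0.2 * 200)), 1)
})

test_that("MAR masks fall preferentially on rows with high missingness odds", {
  ref <- mar_reference_fixture(seed = 7)
  model <- fit_mar_model(ref, "target")
  tt <- complete_numeric_table(100, seed = 11)
  names(tt$data) <- c("target", "x", "aux2")
  names(tt$specs) <- c("target", "x", "aux2")
  for (i in seq_along(tt$specs)) tt$specs[[i]]$name <- names(tt$specs)[i]
  lp <- traitimpute:::mar_linear_predictor(tt, model)
  hits <- numeric(100)
  for (r in 1:500) {
    plan <- mask_mar(tt, model, 0.2, replicate_seed = r)
    hits[match(plan$cells$species, tt$species)] <-
      hits[match(plan$cells$species, tt$species)] + 1
  }
  expect_gt(stats::cor(lp, hits, method = "spearman"), 0.5)
})

test_that("MNAR masks exactly the configured tail", {
  tt <- complete_numeric_table(100, p = 1, seed = 5)
  tt$data$t1 <- as.numeric(1:100)
  plan <- mask_mnar(tt, "t1", list(side = "lower", fraction = 0.10))
  expect_identical(nrow(plan$cells), 10L)
  expect_setequal(match(plan$cells$species, tt$species), 1:10)
  plan_up <- mask_mnar(tt, "t1", list(side = "upper", fraction = 0.10))
  expect_setequal(match(plan_up$cells$species, tt$species), 91:100)
})

test_that("MNAR center-on-zero masks the smallest absolute values", {
  tt <- complete_numeric_table(101, p = 1, seed = 5)
  tt$data$t1 <- as.numeric(-50:50)
  plan <- mask_mnar(tt, "t1", list(side = "center_on_zero", fraction = 0.10))
  vals <- tt$data$t1[match(plan$cells$species, tt$species)]
  # brute force: the cells at or below the 0.10 quantile of |value|
  cut <- quantile(abs(tt$data$t1), 0.10, type = 7)
  expect_setequal(vals, tt$data$t1[abs(tt$data$t1) <= cut])
  expect_true(all(abs(vals) <= cut))
})

test_that("MNAR deletes a whole category, or a seeded sample of it", {
  specs <- list(trait_spec("act", "multicategorical",
                           categories = c("diurnal", "nocturnal", "cathemeral")))
  set.seed(8)
  vals <- sample(c("diurnal", "nocturnal", "cathemeral"), 60, TRUE,
                 prob = c(0.6, 0.3, 0.1))
  tt <- trait_table(sprintf("s%02d", 1:60), specs, data.frame(act = vals))
  plan <- mask_mnar(tt, "act", list(category = "nocturnal", fraction = 1))
  expect_identical(nrow(plan$cells), sum(vals == "nocturnal"))
  masked <- apply_mask_plan(tt, plan)
  expect_false(any(masked$data$act == "nocturnal", na.rm = TRUE))
  half <- mask_mnar(tt, "act", list(category = "nocturnal", fraction = 0.5),
                    replicate_seed = 2)
  expect_identical(nrow(half$cells),
                   as.integer(round(0.5 * sum(vals == "nocturnal"))))
  expect_identical(half, mask_mnar(tt, "act",
                                   list(category = "nocturnal", fraction = 0.5),
                                   replicate_seed = 2))
  expect_error(mask_mnar(tt, "act", list(category = "fossorial")),
               "unknown category")
})

test_that("mask plans serialize to CSV and survive a round trip", {
  tt <- complete_numeric_table(30)
  plans <- mask_mcar(tt, c(0.1, 0.2), replicate_seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mask_plans(plans, path)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_identical(nrow(back), sum(vapply(plans, function(p) nrow(p$cells), 0L)))
  expect_setequal(unique(back$mechanism), "MCAR")
  expect_setequal(back$species[back$proportion == "0.1"],
                  plans[[1]]$cells$species)
})
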