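scored_fixture <- function() {
  specs <- list(trait_spec("v", "continuous"),
                trait_spec("c", "binary", categories = c("a", "b")))
  truth <- trait_table(paste0("s", 1:4), specs,
                       data.frame(v = c(0, 2, 5, 7),
                                  c = c("a", "b", "a", "b")))
  plan <- traitimpute:::new_mask_plan(
    data.frame(species = c("s1", "s2", "s1", "s2", "s3", "s4"),
               trait = c("v", "v", "c", "c", "c", "c"),
               stringsAsFactors = FALSE), "MCAR", 0.5, 1L, 1L)
  imputed <- truth
  imputed$data$v[1:2] <- c(1, 1)
  imputed$data$c <- factor(c("a", "a", "b", "b"), levels = c("a", "b"))
  imp <- traitimpute:::new_imputed_table(imputed, plan$cells,
                                         imputation_config("mean_mode"))
  list(truth = truth, plan = plan, imp = imp)
}

test_that("MSE and PFC follow their counting definitions", {
  f <- scored_fixture()
  expect_equal(score_numeric(f$imp, f$truth, f$plan, "v"), 1.0)
  expect_equal(score_categorical(f$imp, f$truth, f$plan, "c"), 0.5)
  perfect <- f$imp
  perfect$table <- f$truth
  expect_equal(score_numeric(perfect, f$truth, f$plan, "v"), 0)
  expect_equal(score_categorical(perfect, f$truth, f$plan, "c"), 0)
  wrong <- f$imp
  wrong$table$data$c <- factor(c("b", "a", "b", "a"), levels = c("a", "b"))
  expect_equal(score_categorical(wrong, f$truth, f$plan, "c"), 1)
})

test_that("metric/dtype pairing is enforced", {
  f <- scored_fixture()
  expect_error(score_numeric(f$imp, f$truth, f$plan, "c"), "MSE.*categorical")
  expect_error(score_categorical(f$imp, f$truth, f$plan, "v"), "PFC.*numerical")
})

test_that("mean-imputation MSE matches its closed form to 1e-12", {
  set.seed(14)
  n <- 60
  specs <- list(trait_spec("v", "continuous"))
  truth <- trait_table(sprintf("s%02d", 1:n), specs,
                       data.frame(v = rnorm(n, 5, 2)))
  plan <- mask_mcar(truth, 0.25, replicate_seed = 8)[[1]]
  masked <- apply_mask_plan(truth, plan)
  imp <- impute_mean_mode(masked)
  got <- score_numeric(imp, truth, plan, "v")
  masked_idx <- match(plan$cells$species, truth$species)
  obs_mean <- mean(truth$data$v[-masked_idx])
  expect_equal(got, mean((truth$data$v[masked_idx] - obs_mean)^2),
               tolerance = 1e-12)
})

test_that("replicate aggregation averages within groups, order-invariantly", {
  rec <- function(value, rep) data.frame(
    mechanism = "MCAR", proportion = "0.1", method = "knn",
    phylogeny_source = "none", trait = "v", metric = "MSE", value = value,
    replicate = rep, stringsAsFactors = FALSE)
  records <- rbind(rec(0.1, 1), rec(0.3, 2))
  out <- aggregate_replicates(records)
  expect_equal(out$mean_error, 0.2)
  expect_identical(out$n_replicates, 2L)
  expect_equal(out$se, sd(c(0.1, 0.3)) / sqrt(2))
  shuffled <- aggregate_replicates(records[2:1, ])
  expect_equal(out, shuffled)
  single <- aggregate_replicates(rec(0.42, 1))
  expect_equal(single$mean_error, 0.42)
})

test_that("error ratio is the without/with quotient, undefined at zero", {
  expect_equal(error_ratio(0.2, 0.1), 2.0)
  expect_equal(error_ratio(0.15, 0.15), 1.0)
  expect_equal(error_ratio(0.1, 0.2), 0.5)  # phylogeny made things worse
  expect_warning(r <- error_ratio(0.1, 0), "undefined")
  expect_true(is.na(r))
})

mean_row <- function(mech, method, source, trait, err, prop = "n/a") {
  data.frame(mechanism = mech, proportion = prop, method = method,
             phylogeny_source = source, trait = trait,
             metric = "MSE", mean_error = err, n_replicates = 10L,
             se = 0.01, stringsAsFactors = FALSE)
}

test_that("majority vote picks the combo winning most traits under MAR", {
  tab <- do.call(rbind, c(
    lapply(paste0("t", 1:5), function(tr)
      mean_row("MAR", "rf", "coi", tr, 0.1)),
    lapply(paste0("t", 1:5), function(tr)
      mean_row("MAR", "knn", "none", tr, ifelse(tr %in% c("t4", "t5"), 0.05, 0.2)))))
  out <- majority_vote(tab)
  expect_identical(out$best_combo$method, "rf")
  expect_identical(out$best_combo$phylogeny_source, "coi")
  expect_identical(names(out$votes), "MAR")
})

test_that("an exact MAR tie falls through to MNAR, recorded in the trace", {
  traits <- paste0("t", 1:6)
  mar <- do.call(rbind, c(
    lapply(traits[1:3], function(tr) rbind(mean_row("MAR", "rf", "coi", tr, 0.1),
                                           mean_row("MAR", "knn", "none", tr, 0.2))),
    lapply(traits[4:6], function(tr) rbind(mean_row("MAR", "rf", "coi", tr, 0.2),
                                           mean_row("MAR", "knn", "none", tr, 0.1)))))
  mnar <- do.call(rbind, lapply(traits, function(tr)
    rbind(mean_row("MNAR", "rf", "coi", tr, 0.1),
          mean_row("MNAR", "knn", "none", tr, 0.2))))
  out <- majority_vote(rbind(mar, mnar))
  expect_identical(out$best_combo$method, "rf")
  expect_identical(names(out$tie_break_trace), c("MAR", "MNAR"))
  expect_identical(sort(out$tie_break_trace$MAR$leaders),
                   c("knn+none", "rf+coi"))
})

test_that("a single configured combo wins trivially; persistent ties error", {
  single <- mean_row("MAR", "mice", "none", "t1", 0.3)
  out <- majority_vote(single)
  expect_identical(out$best_combo$method, "mice")
  tied <- rbind(mean_row("MAR", "rf", "coi", "t1", 0.1),
                mean_row("MAR", "knn", "none", "t1", 0.2),
                mean_row("MAR", "rf", "coi", "t2", 0.2),
                mean_row("MAR", "knn", "none", "t2", 0.1))
  expect_error(majority_vote(tied), "persistent tie")
})

test_that("MCAR votes are summed over proportions in the final tie-break", {
  mar <- rbind(mean_row("MAR", "rf", "coi", "t1", 0.1),
               mean_row("MAR", "knn", "none", "t1", 0.2),
               mean_row("MAR", "rf", "coi", "t2", 0.2),
               mean_row("MAR", "knn", "none", "t2", 0.1))
  mcar <- do.call(rbind, lapply(c("0.1", "0.2"), function(p) rbind(
    mean_row("MCAR", "rf", "coi", "t1", 0.1, p),
    mean_row("MCAR", "knn", "none", "t1", 0.2, p),
    mean_row("MCAR", "rf", "coi", "t2", 0.1, p),
    mean_row("MCAR", "knn", "none", "t2", 0.3, p))))
  out <- majority_vote(rbind(mar, mcar))
  expect_identical(out$best_combo$method, "rf")
  expect_identical(names(out$tie_break_trace), c("MAR", "MCAR"))
})

test_that("error-ratio tables pair with/without-phylogeny rows correctly", {
  tab <- rbind(mean_row("MAR", "rf", "none", "t1", 0.2),
               mean_row("MAR", "rf", "coi", "t1", 0.1),
               mean_row("MAR", "rf", "rag1", "t1", 0.4))
  ratios <- error_ratio_table(tab)
  expect_identical(nrow(ratios), 2L)
  expect_equal(ratios$ratio[ratios$tree == "coi"], 2.0)
  expect_equal(ratios$ratio[ratios$tree == "rag1"], 0.5)
})

test_that("dataset comparison reproduces textbook summary statistics", {
  specs <- list(trait_spec("v", "continuous"),
                trait_spec("c", "binary", categories = c("a", "b")))
  tt <- trait_table(paste0("s", 1:4), specs,
                    data.frame(v = c(1, 2, 3, 4), c = c("a", "a", "b", "b")))
  out <- compare_datasets(tt, tt, tt)
  num <- out$numerical[out$numerical$dataset == "original", ]
  stat <- function(s) num$value[num$statistic == s]
  expect_equal(stat("mean"), 2.5)
  expect_equal(stat("sd"), 1.290994, tolerance = 1e-6)
  expect_equal(stat("se_mean"), 0.6454972, tolerance = 1e-6)
  expect_equal(stat("ci95_half_width"), qt(0.975, 3) * 0.6454972,
               tolerance = 1e-6)
  expect_equal(stat("range"), 3)
  # identical input tables give identical rows per dataset
  wide <- split(out$numerical$value, out$numerical$dataset)
  expect_equal(wide$original, wide$complete_case)
  expect_equal(wide$original, wide$imputed)
  cats <- out$categorical[out$categorical$dataset == "imputed", ]
  expect_equal(sum(cats$proportion), 1)
})
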