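# Candidate imputation methods: mean/mode baseline, k-nearest neighbour on
# Gower dissimilarities, iterative random-forest imputation, and chained
# equations with predictive mean matching; plus auxiliary-trait screening,
# eigenvector augmentation, and grid tuning.

#' Configure a candidate imputation method
#'
#' @param method One of `"mean_mode"`, `"knn"`, `"rf"`, `"mice"`.
#' @param k_neighbors Neighbours aggregated by `knn` (default 5).
#' @param n_trees,max_iterations Forest size and iteration cap of the
#'   iterative random-forest imputer (defaults 100 and 10).
#' @param m_imputations,donor_pool_k,chain_iterations Number of chained
#'   imputations pooled, predictive-mean-matching donor-pool size, and
#'   cycles per chain for `mice` (defaults 5, 5, 5).
#' @param phylogeny_source Label of the tree whose eigenvectors are
#'   appended, or `"none"`. The mean/mode baseline admits `"none"` only.
#' @param seed Seed for the method's own randomness.
#' @return An object of class `imputation_config`.
#' @export
imputation_config <- function(method = c("mean_mode", "knn", "rf", "mice"),
                              k_neighbors = 5L, n_trees = 100L,
                              max_iterations = 10L, m_imputations = 5L,
                              donor_pool_k = 5L, chain_iterations = 5L,
                              phylogeny_source = "none", seed = 1L) {
  method <- match.arg(method)
  params <- c(k_neighbors = k_neighbors, n_trees = n_trees,
              max_iterations = max_iterations, m_imputations = m_imputations,
              donor_pool_k = donor_pool_k, chain_iterations = chain_iterations)
  if (any(params < 1)) stopf("imputation parameters must be positive integers")
  if (method == "mean_mode" && phylogeny_source != "none")
    stopf("mean/mode imputation has no phylogenetic variant")
  structure(list(method = method, k_neighbors = as.integer(k_neighbors),
                 n_trees = as.integer(n_trees),
                 max_iterations = as.integer(max_iterations),
                 m_imputations = as.integer(m_imputations),
                 donor_pool_k = as.integer(donor_pool_k),
                 chain_iterations = as.integer(chain_iterations),
                 phylogeny_source = phylogeny_source, seed = seed),
            class = "imputation_config")
}

#' @export
print.imputation_config <- function(x, ...) {
  extras <- switch(x$method,
    knn = sprintf("k = %d", x$k_neighbors),
    rf = sprintf("%d trees, <= %d iterations", x$n_trees, x$max_iterations),
    mice = sprintf("m = %d, donor pool %d, %d cycles", x$m_imputations,
                   x$donor_pool_k, x$chain_iterations),
    "")
  cat(sprintf("imputation_config: %s%s, phylogeny = %s\n", x$method,
              if (nzchar(extras)) paste0(" (", extras, ")") else "",
              x$phylogeny_source))
  invisible(x)
}

combo_label <- function(config) paste(config$method, config$phylogeny_source,
                                      sep = "+")

new_imputed_table <- function(table, imputed_cells, config,
                              per_imputation_values = NULL) {
  structure(list(table = table, imputed_cells = imputed_cells,
                 per_imputation_values = per_imputation_values,
                 config = config),
            class = "imputed_table")
}

#' @export
print.imputed_table <- function(x, ...) {
  cat(sprintf("imputed_table: %d cells imputed by %s (phylogeny = %s)\n",
              nrow(x$imputed_cells), x$config$method,
              x$config$phylogeny_source))
  invisible(x)
}

missing_cells_df <- function(tt) {
  traits <- evaluable_traits(tt)
  do.call(rbind, c(list(data.frame(species = character(0), trait = character(0),
                                   stringsAsFactors = FALSE)),
                   lapply(traits, function(trait) {
    idx <- which(is.na(tt$data[[trait]]))
    data.frame(species = tt$species[idx],
               trait = rep(trait, length(idx)), stringsAsFactors = FALSE)
  })))
}

# Predictor columns for one target: the screened auxiliary traits (or all
# other traits when no screen is supplied) plus every eigenvector column —
# eigenvectors are appended wholesale and bypass the significance screen.
# A target whose screen retained nothing falls back to all other traits,
# so conditional imputers degrade gracefully instead of failing.
predictors_for <- function(tt, target, predictors = NULL) {
  base <- if (is.null(predictors)) setdiff(evaluable_traits(tt), target)
          else setdiff(predictors[[target]] %||% character(0), target)
  out <- c(base, trait_names(tt, "eigenvector"))
  if (!length(out)) out <- setdiff(evaluable_traits(tt), target)
  out
}

impute_order <- function(tt) {
  traits <- evaluable_traits(tt)
  miss <- vapply(tt$data[traits], function(x) sum(is.na(x)), 0L)
  traits[miss > 0L][order(miss[miss > 0L], traits[miss > 0L])]
}

#' Screen auxiliary traits for association with a target trait
#'
#' Fits one single-covariate regression per auxiliary trait on the rows
#' where both are observed — linear, Poisson, logistic, or polytomous
#' logistic according to the target's dtype — and retains the auxiliary
#' when any of its coefficients has p-value below `alpha`. Count targets
#' are screened by Poisson regression on the original (count) scale.
#'
#' @param tt A [trait_table()] (untransformed for count targets).
#' @param target Target trait name.
#' @param alpha Significance level (default 0.05).
#' @param min_overlap Minimum rows jointly observed (default 20).
#' @return Character vector of retained auxiliary trait names.
#' @export
select_auxiliary_traits <- function(tt, target, alpha = 0.05,
                                    min_overlap = 20L) {
  spec <- tt$specs[[target]]
  if (is.null(spec)) stopf("unknown target trait '%s'", target)
  aux <- setdiff(evaluable_traits(tt), target)
  y_all <- tt$data[[target]]
  keep <- character(0)
  for (a in aux) {
    x_all <- tt$data[[a]]
    ok <- !is.na(y_all) & !is.na(x_all)
    if (sum(ok) < min_overlap)
      stopf("target '%s' and auxiliary '%s' share only %d observed rows (need >= %d)",
            target, a, sum(ok), min_overlap)
    y <- y_all[ok]
    x <- x_all[ok]
    if (is.factor(x)) x <- droplevels(x)
    if (length(unique(x)) < 2L) {
      warnf("auxiliary '%s' is constant on the overlap with '%s'; skipped", a, target)
      next
    }
    pvals <- tryCatch(
      screen_pvalues(y, x, spec$dtype),
      error = function(e) {
        warnf("screen of '%s' against '%s' failed (%s); skipped",
              a, target, conditionMessage(e))
        NULL
      })
    if (!is.null(pvals) && any(pvals < alpha, na.rm = TRUE)) keep <- c(keep, a)
  }
  keep
}

screen_pvalues <- function(y, x, dtype) {
  df <- data.frame(y = y, x = x)
  switch(dtype,
    continuous = {
      co <- summary(stats::lm(y ~ x, data = df))$coefficients
      co[-1L, 4L]
    },
    count = {
      fit <- stats::glm(y ~ x, data = df, family = stats::poisson())
      summary(fit)$coefficients[-1L, 4L]
    },
    binary = {
      fit <- stats::glm(y ~ x, data = df, family = stats::binomial())
      summary(fit)$coefficients[-1L, 4L]
    },
    multicategorical = {
      df$y <- droplevels(df$y)
      fit <- nnet::multinom(y ~ x, data = df, trace = FALSE)
      co <- summary(fit)$coefficients
      se <- summary(fit)$standard.errors
      if (is.null(dim(co))) { co <- rbind(co); se <- rbind(se) }
      z <- co[, -1L, drop = FALSE] / se[, -1L, drop = FALSE]
      2 * stats::pnorm(-abs(as.vector(z)))
    })
}

#' Screen auxiliaries for every trait at once
#'
#' @inheritParams select_auxiliary_traits
#' @return Named list mapping each ordinary trait to its retained
#'   auxiliary set.
#' @export
select_all_auxiliary_traits <- function(tt, alpha = 0.05, min_overlap = 20L) {
  traits <- evaluable_traits(tt)
  stats::setNames(lapply(traits, function(trait)
    select_auxiliary_traits(tt, trait, alpha, min_overlap)), traits)
}

#' Mean/mode imputation
#'
#' Baseline imputer: numerical missing cells get the mean of the trait's
#' observed cells (on the model scale), categorical cells its modal
#' category (ties broken by the smallest label).
#'
#' @param tt A [trait_table()].
#' @param config Optional [imputation_config()] recorded as provenance.
#' @return An `imputed_table`.
#' @export
impute_mean_mode <- function(tt, config = imputation_config("mean_mode")) {
  cells <- missing_cells_df(tt)
  for (trait in unique(cells$trait)) {
    x <- tt$data[[trait]]
    if (all(is.na(x))) stopf("trait '%s' is fully missing", trait)
    fill <- if (is.factor(x)) modal_value(x) else mean(x, na.rm = TRUE)
    x[is.na(x)] <- fill
    tt$data[[trait]] <- x
  }
  new_imputed_table(tt, cells, config)
}

# Gower dissimilarities between one query row and a set of donor rows over
# the given columns: numeric contributions |xi - xj| / range (ranges taken
# over the whole table's observed values), categorical mismatch 0/1,
# averaged over the components available in both rows.
gower_to_donors <- function(data, cols, ranges, query, donors) {
  num <- matrix(0, length(donors), 0)
  contrib <- matrix(NA_real_, length(donors), length(cols))
  for (j in seq_along(cols)) {
    x <- data[[cols[j]]]
    qv <- x[query]
    if (is.na(qv)) next
    dv <- x[donors]
    if (is.factor(x)) {
      contrib[, j] <- ifelse(is.na(dv), NA_real_,
                             as.numeric(as.character(dv) != as.character(qv)))
    } else {
      rg <- ranges[[cols[j]]]
      contrib[, j] <- if (rg > 0) abs(dv - qv) / rg else
        ifelse(is.na(dv), NA_real_, 0)
    }
  }
  rowMeans(contrib, na.rm = TRUE)
}

#' k-nearest-neighbour imputation with Gower dissimilarity
#'
#' For each missing cell, donor rows (rows observed for the target trait)
#' are ranked by Gower dissimilarity over the target's predictor columns —
#' range-normalized numeric contributions, 0/1 categorical mismatches,
#' averaged over the components available in both rows — and the value is
#' the median (numerical) or mode (categorical) of the `k_neighbors`
#' nearest donors. Distance ties are broken by donor order, making the
#' imputation deterministic.
#'
#' @param tt A [trait_table()].
#' @param predictors Optional named list of screened predictor sets per
#'   target (see [select_all_auxiliary_traits()]); eigenvector columns are
#'   always appended.
#' @param k_neighbors Number of donors aggregated (default 5).
#' @param config Optional [imputation_config()]; its `k_neighbors` wins
#'   when supplied.
#' @return An `imputed_table`.
#' @export
impute_knn <- function(tt, predictors = NULL, k_neighbors = 5L,
                       config = NULL) {
  config <- config %||% imputation_config("knn", k_neighbors = k_neighbors)
  k <- config$k_neighbors
  cells <- missing_cells_df(tt)
  out <- tt
  ranges <- lapply(tt$data, function(x)
    if (is.factor(x)) NA_real_ else diff(range(x, na.rm = TRUE)))
  for (trait in unique(cells$trait)) {
    x <- tt$data[[trait]]
    donors <- which(!is.na(x))
    if (!length(donors)) stopf("trait '%s': no donor rows", trait)
    if (k > length(donors))
      stopf("trait '%s': k = %d exceeds the %d donor rows", trait, k,
            length(donors))
    preds <- predictors_for(tt, trait, predictors)
    all_cols <- c(setdiff(evaluable_traits(tt), trait),
                  trait_names(tt, "eigenvector"))
    for (row in which(is.na(x))) {
      d <- gower_to_donors(tt$data, preds, ranges, row, donors)
      # rows observing none of the screened predictors fall back to every
      # available column; rows observing nothing at all to all donors
      if (all(is.nan(d)))
        d <- gower_to_donors(tt$data, all_cols, ranges, row, donors)
      vals <- if (all(is.nan(d))) x[donors] else {
        d[is.nan(d)] <- Inf
        x[donors[order(d, seq_along(d))[seq_len(k)]]]
      }
      out$data[row, trait] <- if (is.factor(x)) modal_value(vals)
                              else stats::median(vals)
    }
  }
  new_imputed_table(out, cells, config)
}

#' Iterative random-forest imputation
#'
#' The missForest-style algorithm: missing cells are initialized by
#' mean/mode; traits are visited in order of increasing missingness; in
#' each iteration a random forest (regression for numerical traits,
#' classification for categorical) is refitted for each trait on the rows
#' where it was originally observed, using the currently completed
#' predictor columns, and its missing cells are re-predicted. Iteration
#' stops when the combined difference criterion — the sum of squared
#' changes over numerical imputed cells normalized by their sum of
#' squares, plus the proportion of changed categorical imputed cells —
#' increases for every trait family present (the previous iterate is
#' returned), or at `max_iterations`.
#'
#' @inheritParams impute_knn
#' @param n_trees Trees per forest (default 100).
#' @param max_iterations Iteration cap (default 10).
#' @param seed Seed for forest randomness.
#' @return An `imputed_table`.
#' @export
impute_missforest <- function(tt, predictors = NULL, n_trees = 100L,
                              max_iterations = 10L, seed = 1L,
                              config = NULL) {
  config <- config %||% imputation_config("rf", n_trees = n_trees,
                                          max_iterations = max_iterations,
                                          seed = seed)
  cells <- missing_cells_df(tt)
  if (nrow(cells) == 0L) return(new_imputed_table(tt, cells, config))
  if (length(tt$specs) < 2L) stopf("random-forest imputation needs >= 2 columns")
  order_traits <- impute_order(tt)
  mis_idx <- lapply(order_traits, function(trait) which(is.na(tt$data[[trait]])))
  names(mis_idx) <- order_traits
  completed <- impute_mean_mode(tt)$table
  numeric_traits <- order_traits[!vapply(tt$data[order_traits], is.factor, TRUE)]
  categorical_traits <- setdiff(order_traits, numeric_traits)
  prev_num <- Inf; prev_cat <- Inf
  prev_completed <- completed
  with_seed(seed, {
    for (iter in seq_len(config$max_iterations)) {
      before <- completed
      for (trait in order_traits) {
        preds <- predictors_for(tt, trait, predictors)
        if (!length(preds)) stopf("trait '%s': no predictors available", trait)
        obs <- which(!is.na(tt$data[[trait]]))
        xdf <- completed$data[preds]
        y <- tt$data[[trait]][obs]
        if (is.factor(y)) y <- droplevels(y)
        if (is.factor(y) && nlevels(y) < 2L) {
          # every observed cell is one class (e.g. MNAR deleted a whole
          # category): the only consistent prediction is that class
          completed$data[mis_idx[[trait]], trait] <-
            factor(levels(y), levels = levels(completed$data[[trait]]))
          next
        }
        fit <- tryCatch(
          suppressWarnings(
            randomForest::randomForest(x = xdf[obs, , drop = FALSE], y = y,
                                       ntree = config$n_trees)),
          error = function(e) stopf("random forest failed for trait '%s': %s",
                                    trait, conditionMessage(e)))
        pred <- stats::predict(fit, xdf[mis_idx[[trait]], , drop = FALSE])
        if (is.factor(completed$data[[trait]]))
          pred <- factor(as.character(pred),
                         levels = levels(completed$data[[trait]]))
        completed$data[mis_idx[[trait]], trait] <- pred
      }
      # difference criteria over imputed cells only
      num_crit <- if (length(numeric_traits)) {
        newv <- unlist(lapply(numeric_traits, function(tr)
          completed$data[mis_idx[[tr]], tr]))
        oldv <- unlist(lapply(numeric_traits, function(tr)
          before$data[mis_idx[[tr]], tr]))
        sum((newv - oldv)^2) / max(sum(newv^2), .Machine$double.eps)
      } else NULL
      cat_crit <- if (length(categorical_traits)) {
        changed <- unlist(lapply(categorical_traits, function(tr)
          as.character(completed$data[mis_idx[[tr]], tr]) !=
            as.character(before$data[mis_idx[[tr]], tr])))
        mean(changed)
      } else NULL
      num_up <- is.null(num_crit) || num_crit > prev_num
      cat_up <- is.null(cat_crit) || cat_crit > prev_cat
      if (num_up && cat_up && iter > 1L) {
        completed <- prev_completed
        break
      }
      prev_completed <- completed
      prev_num <- num_crit %||% Inf
      prev_cat <- cat_crit %||% Inf
    }
  })
  new_imputed_table(completed, cells, config)
}

#' Chained-equations imputation with predictive mean matching
#'
#' Multivariate imputation by chained equations: each of `m_imputations`
#' chains initializes missing cells with random draws from the trait's
#' observed values, then cycles `chain_iterations` times over the
#' incomplete traits (in order of increasing missingness), re-imputing
#' each from the current completions of its predictors. Continuous and
#' count traits use predictive mean matching: a linear model fitted on the
#' observed rows defines a donor pool of the `donor_pool_k` observed
#' values whose fitted means are closest to the missing row's prediction,
#' and the imputed value is drawn uniformly from that pool (so it is
#' always an observed value of the trait). Binary traits draw from a
#' fitted logistic model, multi-categorical traits from a fitted
#' polytomous (multinomial) logistic model. Chains are pooled to a single
#' table by the mean (numerical) or mode (categorical) across chains.
#'
#' @inheritParams impute_knn
#' @param m_imputations Number of chains pooled (default 5).
#' @param donor_pool_k Donor-pool size for predictive mean matching
#'   (default 5).
#' @param chain_iterations Cycles per chain (default 5).
#' @param seed Seed; each chain uses an independent derived stream.
#' @return An `imputed_table` whose `per_imputation_values` holds, per
#'   trait, the m pre-pooling values of every imputed cell.
#' @export
impute_mice <- function(tt, predictors = NULL, m_imputations = 5L,
                        donor_pool_k = 5L, chain_iterations = 5L, seed = 1L,
                        config = NULL) {
  config <- config %||% imputation_config(
    "mice", m_imputations = m_imputations, donor_pool_k = donor_pool_k,
    chain_iterations = chain_iterations, seed = seed)
  cells <- missing_cells_df(tt)
  if (nrow(cells) == 0L)
    return(new_imputed_table(tt, cells, config, per_imputation_values = list()))
  order_traits <- impute_order(tt)
  mis_idx <- lapply(order_traits, function(trait) which(is.na(tt$data[[trait]])))
  names(mis_idx) <- order_traits
  chains <- lapply(seq_len(config$m_imputations), function(s)
    with_seed(derive_seed(config$seed, "chain", s),
              run_mice_chain(tt, predictors, order_traits, mis_idx, config)))
  pooled <- tt
  per_values <- list()
  for (trait in order_traits) {
    idx <- mis_idx[[trait]]
    vals <- vapply(chains, function(ch) {
      v <- ch$data[idx, trait]
      if (is.factor(v)) as.character(v) else as.numeric(v)
    }, vector(if (is.factor(tt$data[[trait]])) "character" else "numeric",
              length(idx)))
    vals <- matrix(vals, nrow = length(idx))
    if (is.factor(tt$data[[trait]])) {
      pick <- apply(vals, 1L, modal_value)
      pooled$data[idx, trait] <- factor(pick, levels = levels(tt$data[[trait]]))
    } else {
      pooled$data[idx, trait] <- rowMeans(vals)
    }
    per_values[[trait]] <- data.frame(species = tt$species[idx], vals,
                                      stringsAsFactors = FALSE)
    names(per_values[[trait]]) <- c("species",
                                    paste0("m", seq_len(config$m_imputations)))
  }
  new_imputed_table(pooled, cells, config, per_imputation_values = per_values)
}

run_mice_chain <- function(tt, predictors, order_traits, mis_idx, config) {
  completed <- tt
  for (trait in order_traits) {
    obs_vals <- tt$data[[trait]][!is.na(tt$data[[trait]])]
    completed$data[mis_idx[[trait]], trait] <-
      sample(obs_vals, length(mis_idx[[trait]]), replace = TRUE)
  }
  for (iter in seq_len(config$chain_iterations)) {
    for (trait in order_traits) {
      preds <- predictors_for(tt, trait, predictors)
      if (!length(preds)) stopf("trait '%s': no predictors available", trait)
      obs <- which(!is.na(tt$data[[trait]]))
      mis <- mis_idx[[trait]]
      df <- completed$data[preds]
      y <- tt$data[[trait]][obs]
      completed$data[mis, trait] <-
        mice_draw(y, df, obs, mis, tt$data[[trait]], config)
    }
  }
  completed
}

mice_draw <- function(y, df, obs, mis, target_col, config) {
  dat <- cbind(df, .y = NA)
  dat$.y[obs] <- if (is.factor(target_col)) NA else as.numeric(y)
  if (is.factor(target_col)) {
    lev <- levels(droplevels(y))
    if (length(lev) < 2L) return(factor(rep(lev, length(mis)),
                                        levels = levels(target_col)))
    if (length(lev) == 2L) {
      yb <- as.integer(droplevels(y) == lev[2L])
      fit <- suppressWarnings(stats::glm(
        stats::reformulate(names(df), response = ".yb"),
        data = cbind(df[obs, , drop = FALSE], .yb = yb),
        family = stats::binomial()))
      p <- suppressWarnings(stats::predict(fit, df[mis, , drop = FALSE],
                                           type = "response"))
      draw <- lev[1L + stats::rbinom(length(mis), 1L, p)]
    } else {
      fit <- tryCatch(
        nnet::multinom(stats::reformulate(names(df), response = ".yf"),
                       data = cbind(df[obs, , drop = FALSE],
                                    .yf = droplevels(y)),
                       trace = FALSE),
        error = function(e) stopf("multinomial fit failed: %s",
                                  conditionMessage(e)))
      p <- stats::predict(fit, df[mis, , drop = FALSE], type = "probs")
      if (is.null(dim(p))) p <- matrix(p, nrow = length(mis), byrow = FALSE)
      if (ncol(p) != length(lev)) p <- matrix(p, nrow = length(mis))
      draw <- apply(p, 1L, function(pr) sample(lev, 1L, prob = pr))
    }
    factor(draw, levels = levels(target_col))
  } else {
    yn <- as.numeric(y)
    fit <- suppressWarnings(stats::lm(
      stats::reformulate(names(df), response = ".yn"),
      data = cbind(df[obs, , drop = FALSE], .yn = yn)))
    if (anyNA(stats::coef(fit)))
      warnf("singular design matrix: aliased predictor(s) dropped")
    fitted_obs <- suppressWarnings(stats::predict(fit, df[obs, , drop = FALSE]))
    pred_mis <- suppressWarnings(stats::predict(fit, df[mis, , drop = FALSE]))
    k <- min(config$donor_pool_k, length(obs))
    vapply(pred_mis, function(p) {
      pool <- order(abs(fitted_obs - p), seq_along(fitted_obs))[seq_len(k)]
      yn[pool[sample.int(k, 1L)]]
    }, 0)
  }
}

#' Append phylogenetic eigenvectors as predictors
#'
#' Adds the eigenvector coordinates of an [extract_eigenvectors()] result
#' to a table as fully observed continuous predictor columns flagged
#' `role = "eigenvector"`: they are never imputed, never evaluated, and
#' bypass the auxiliary-trait significance screen. Species without
#' eigenvector coordinates are excluded from the returned (phylogenetic)
#' table with a message.
#'
#' @param tt A [trait_table()].
#' @param evs An `eigenvector_set`.
#' @return The augmented [trait_table()].
#' @export
augment_with_eigenvectors <- function(tt, evs) {
  cols <- colnames(evs$coordinates)
  cols <- paste0("ev_", tolower(evs$source_label), "_", seq_along(cols))
  clash <- intersect(cols, names(tt$specs))
  if (length(clash)) stopf("duplicate column name '%s'", clash[1L])
  common <- intersect(tt$species, evs$species)
  dropped <- setdiff(tt$species, evs$species)
  if (length(dropped)) {
    message(sprintf("excluding %d species without eigenvector coordinates: %s",
                    length(dropped),
                    paste(utils::head(dropped, 5L), collapse = ", ")))
    tt <- subset_trait_table(tt, common)
  }
  coords <- evs$coordinates[match(tt$species, evs$species), , drop = FALSE]
  for (j in seq_along(cols)) {
    tt$specs[[cols[j]]] <- trait_spec(cols[j], "continuous",
                                      role = "eigenvector")
    tt$data[[cols[j]]] <- as.numeric(coords[, j])
  }
  tt
}

#' Impute with a configured method
#'
#' Dispatcher mapping an [imputation_config()] to the matching imputer.
#' Phylogenetic augmentation is the caller's responsibility (see
#' [augment_with_eigenvectors()]); the config's `phylogeny_source` is
#' provenance.
#'
#' @param tt A [trait_table()].
#' @param config An [imputation_config()].
#' @param predictors Optional named list of screened predictor sets.
#' @return An `imputed_table`.
#' @export
impute_with <- function(tt, config, predictors = NULL) {
  switch(config$method,
         mean_mode = impute_mean_mode(tt, config = config),
         knn = impute_knn(tt, predictors, config = config),
         rf = impute_missforest(tt, predictors, config = config),
         mice = impute_mice(tt, predictors, config = config))
}

#' Tune imputation parameters on masked replicates
#'
#' Runs every candidate configuration over the supplied masked replicates,
#' scores each against the truth (MSE for numerical traits, PFC for
#' categorical), and returns the configuration with the lowest error
#' averaged over traits and replicates. Ties go to the smallest parameter
#' values, then declaration order.
#'
#' @param configs List of [imputation_config()]s (the grid).
#' @param truth Complete (or near-complete) [trait_table()] on the model
#'   scale.
#' @param plans List of `mask_plan`s defining the replicates.
#' @param predictors Optional screened predictor sets.
#' @param evs Optional named list of `eigenvector_set`s keyed by
#'   `phylogeny_source`.
#' @return The winning [imputation_config()], with the per-config mean
#'   errors attached as attribute `"errors"`.
#' @export
tune_parameters <- function(configs, truth, plans, predictors = NULL,
                            evs = NULL) {
  if (!length(configs)) stopf("empty parameter grid")
  errors <- vapply(configs, function(cfg) {
    vals <- unlist(lapply(plans, function(plan) {
      masked <- apply_mask_plan(truth, plan)
      if (cfg$phylogeny_source != "none") {
        if (is.null(evs[[cfg$phylogeny_source]]))
          stopf("no eigenvector set for source '%s'", cfg$phylogeny_source)
        masked <- augment_with_eigenvectors(masked, evs[[cfg$phylogeny_source]])
      }
      imp <- impute_with(masked, cfg, predictors)
      recs <- evaluate_imputation(imp, truth, plan)
      recs$value
    }))
    mean(vals)
  }, 0)
  params <- vapply(configs, function(cfg)
    c(cfg$k_neighbors, cfg$n_trees, cfg$max_iterations, cfg$m_imputations,
      cfg$donor_pool_k, cfg$chain_iterations), numeric(6))
  ord <- do.call(order, c(list(errors), as.data.frame(t(params)),
                          list(seq_along(configs))))
  best <- configs[[ord[1L]]]
  attr(best, "errors") <- errors
  best
}
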