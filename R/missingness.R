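# Missingness simulation: MCAR with nested proportions, MAR driven by
# logistic models fitted to a reference table, and MNAR tail/category
# deletion.

new_mask_plan <- function(cells, mechanism, proportion_label, replicate_id,
                          seed) {
  rownames(cells) <- NULL
  structure(list(cells = cells, mechanism = mechanism,
                 proportion_label = proportion_label,
                 replicate_id = replicate_id, seed = seed),
            class = "mask_plan")
}

#' @export
print.mask_plan <- function(x, ...) {
  cat(sprintf("mask_plan [%s, p = %s, replicate %s]: %d cells\n",
              x$mechanism, as.character(x$proportion_label),
              as.character(x$replicate_id), nrow(x$cells)))
  invisible(x)
}

#' Serialize / restore mask plans
#'
#' Plans are written as plain CSV (mechanism, proportion, replicate, seed,
#' species, trait) so that any simulated-missingness replicate can be
#' replayed exactly.
#'
#' @param plans A `mask_plan` or list of them.
#' @param csv_path Output path.
#' @export
write_mask_plans <- function(plans, csv_path) {
  if (inherits(plans, "mask_plan")) plans <- list(plans)
  rows <- do.call(rbind, lapply(plans, function(p) {
    data.frame(mechanism = p$mechanism,
               proportion = as.character(p$proportion_label),
               replicate = p$replicate_id, seed = p$seed,
               species = p$cells$species, trait = p$cells$trait,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, csv_path, row.names = FALSE, quote = FALSE)
  invisible(csv_path)
}

#' Apply a mask plan to a table
#'
#' @param tt A [trait_table()].
#' @param plan A `mask_plan` whose cells are all observed in `tt`.
#' @return The table with the plan's cells set to missing.
#' @export
apply_mask_plan <- function(tt, plan) {
  i <- match(plan$cells$species, tt$species)
  if (anyNA(i)) stopf("mask plan names unknown species '%s'",
                      plan$cells$species[which(is.na(i))[1L]])
  for (r in seq_len(nrow(plan$cells))) {
    trait <- plan$cells$trait[r]
    if (is.na(tt$data[i[r], trait]))
      stopf("mask plan targets an already-missing cell (%s, %s)",
            plan$cells$species[r], trait)
    tt$data[i[r], trait] <- NA
  }
  tt
}

#' Simulate MCAR missingness at nested proportions
#'
#' For each trait, exactly `round(p * n)` observed cells (n = number of
#' rows; pre-existing missing cells count toward neither the target nor
#' the pool) are masked per proportion, rounding half away from zero.
#' Within a replicate the plan at a higher proportion is a strict superset
#' of the plan at each lower one, so error differences across proportions
#' are not confounded by which species were masked.
#'
#' @param tt A [trait_table()].
#' @param proportions Strictly increasing vector of proportions in (0, 1].
#' @param traits Traits to mask (default: all ordinary traits).
#' @param replicate_seed Seed fixing the replicate's masking order.
#' @param replicate_id Identifier carried into the plans.
#' @return List of `mask_plan`s, one per proportion, nested.
#' @export
mask_mcar <- function(tt, proportions, traits = NULL, replicate_seed = 1L,
                      replicate_id = 1L) {
  traits <- traits %||% evaluable_traits(tt)
  if (any(proportions <= 0 | proportions > 1))
    stopf("proportions must lie in (0, 1]")
  if (any(diff(proportions) <= 0)) stopf("proportions must be strictly increasing")
  n <- length(tt$species)
  counts <- round_half_up(proportions * n)
  orders <- with_seed(replicate_seed, {
    lapply(traits, function(trait) {
      obs <- which(!is.na(tt$data[[trait]]))
      if (length(obs) < counts[length(counts)])
        stopf("trait '%s': only %d observed cells for a target of %d",
              trait, length(obs), counts[length(counts)])
      sample(obs)
    })
  })
  names(orders) <- traits
  lapply(seq_along(proportions), function(j) {
    cells <- do.call(rbind, lapply(traits, function(trait) {
      take <- orders[[trait]][seq_len(counts[j])]
      data.frame(species = tt$species[take], trait = trait,
                 stringsAsFactors = FALSE)
    }))
    new_mask_plan(cells, "MCAR", proportions[j], replicate_id, replicate_seed)
  })
}

#' Fit a missingness model for MAR simulation
#'
#' Logistic regression of the missingness indicator of `target_trait` on
#' the other traits of a reference table (rows with all auxiliary traits
#' observed), keeping only auxiliaries with at least one coefficient
#' p-value below `alpha` and refitting on the retained set. When no
#' auxiliary is significantly associated with missingness, the trait is
#' ineligible for MAR simulation and the returned model says so.
#'
#' @param reference A [trait_table()] containing real missingness in
#'   `target_trait` (typically the original, pre-filtering dataset).
#' @param target_trait Trait whose missingness is modelled.
#' @param alpha Significance level of the predictor screen (default 0.05).
#' @return An object of class `mar_model`: `target_trait`, `predictors`,
#'   `coefficients` (named, including `(Intercept)`), `alpha`, `eligible`.
#' @export
fit_mar_model <- function(reference, target_trait, alpha = 0.05) {
  traits <- evaluable_traits(reference)
  if (!(target_trait %in% traits)) stopf("unknown target trait '%s'", target_trait)
  y <- as.integer(is.na(reference$data[[target_trait]]))
  if (sum(y) == 0L) stopf("trait '%s' is fully observed in the reference", target_trait)
  aux <- setdiff(traits, target_trait)
  df <- reference$data[aux]
  complete <- stats::complete.cases(df)
  df <- df[complete, , drop = FALSE]
  y <- y[complete]
  if (length(unique(y)) < 2L)
    stopf("no missingness among complete-predictor rows for '%s'", target_trait)
  fit_once <- function(preds) {
    stats::glm(stats::reformulate(preds, response = "..miss"),
               data = cbind(df, ..miss = y), family = stats::binomial())
  }
  drop_separated <- function(preds, fit) {
    co <- stats::coef(fit)
    bad <- unique(unlist(lapply(preds, function(p) {
      idx <- grep(paste0("^`?", p), names(co))
      if (length(idx) && any(abs(co[idx]) > 15, na.rm = TRUE)) p
    })))
    bad
  }
  fit <- fit_once(aux)
  sep <- drop_separated(aux, fit)
  if (length(sep)) {
    warnf("dropping predictor(s) with apparent separation: %s",
          paste(sep, collapse = ", "))
    aux <- setdiff(aux, sep)
    if (!length(aux))
      return(structure(list(target_trait = target_trait,
                            predictors = character(0), coefficients = NULL,
                            alpha = alpha, eligible = FALSE),
                       class = "mar_model"))
    fit <- fit_once(aux)
  }
  coefs <- summary(fit)$coefficients
  keep <- unique(unlist(lapply(aux, function(p) {
    idx <- grep(paste0("^`?", p), rownames(coefs))
    if (length(idx) && any(coefs[idx, 4L] < alpha, na.rm = TRUE)) p
  })))
  if (!length(keep))
    return(structure(list(target_trait = target_trait,
                          predictors = character(0), coefficients = NULL,
                          alpha = alpha, eligible = FALSE),
                     class = "mar_model"))
  refit <- fit_once(keep)
  structure(list(target_trait = target_trait, predictors = keep,
                 coefficients = stats::coef(refit), alpha = alpha,
                 eligible = TRUE, fit = refit),
            class = "mar_model")
}

#' @export
print.mar_model <- function(x, ...) {
  if (!x$eligible) {
    cat(sprintf("mar_model '%s': no significant predictor of missingness (alpha = %g)\n",
                x$target_trait, x$alpha))
  } else {
    cat(sprintf("mar_model '%s': predictors %s\n", x$target_trait,
                paste(x$predictors, collapse = ", ")))
  }
  invisible(x)
}

#' Simulate MAR missingness from a fitted missingness model
#'
#' Per-row missingness probabilities come from the fitted logistic model;
#' the intercept is shifted by a scalar, solved numerically, so that the
#' expected number of masked cells equals `round(target_proportion * n)`.
#' Cells are then drawn by independent Bernoulli trials. Rows lacking an
#' observed value of any model predictor (or of the target itself) are
#' ineligible and never masked.
#'
#' @param tt Table to mask (typically the near complete-case table).
#' @param model A `mar_model` from [fit_mar_model()]; must be eligible.
#' @param target_proportion Overall proportion of rows to mask in
#'   expectation (default 0.20).
#' @param replicate_seed Seed for the Bernoulli draws.
#' @param replicate_id Identifier carried into the plan.
#' @return A `mask_plan` for the model's target trait.
#' @export
mask_mar <- function(tt, model, target_proportion = 0.20, replicate_seed = 1L,
                     replicate_id = 1L) {
  if (!inherits(model, "mar_model")) stopf("model must be a mar_model")
  if (!model$eligible)
    stopf("trait '%s' is ineligible for MAR (no significant predictor)",
          model$target_trait)
  lp <- mar_linear_predictor(tt, model)
  eligible <- which(!is.na(lp) & !is.na(tt$data[[model$target_trait]]))
  n <- length(tt$species)
  m <- round_half_up(target_proportion * n)
  if (m > length(eligible))
    stopf("target of %d masked cells infeasible with %d eligible rows",
          m, length(eligible))
  lpe <- lp[eligible]
  expected <- function(delta) sum(stats::plogis(lpe + delta)) - m
  shift <- stats::uniroot(expected, c(-50, 50), tol = 1e-10)$root
  probs <- stats::plogis(lpe + shift)
  drawn <- with_seed(replicate_seed, stats::runif(length(probs)) < probs)
  cells <- data.frame(species = tt$species[eligible[drawn]],
                      trait = model$target_trait, stringsAsFactors = FALSE)
  plan <- new_mask_plan(cells, "MAR", "n/a", replicate_id, replicate_seed)
  plan$intercept_shift <- shift
  plan$expected_count <- m
  plan
}

mar_linear_predictor <- function(tt, model) {
  df <- tt$data[model$predictors]
  ok <- stats::complete.cases(df)
  lp <- rep(NA_real_, nrow(df))
  if (any(ok)) {
    mm <- stats::model.matrix(stats::reformulate(model$predictors),
                              data = df[ok, , drop = FALSE])
    beta <- model$coefficients[colnames(mm)]
    beta[is.na(beta)] <- 0
    lp[ok] <- drop(mm %*% beta)
  }
  lp
}

#' Simulate MNAR missingness by tail or category deletion
#'
#' Numerical traits: deletes exactly the observed cells whose (optionally
#' transformed) values lie at or below the `fraction` quantile of the
#' chosen tail — `"lower"`, `"upper"` (values at or above the upper
#' quantile), or `"center_on_zero"` which ranks by absolute value and so
#' removes the band nearest zero (emulating, e.g., loss of near-equatorial
#' latitude records). Categorical traits: deletes the configured fraction
#' of observed cells of one named category (all of them by default),
#' sampled uniformly when `fraction < 1`, with an optional `cap` on the
#' number of cells.
#'
#' @param tt A [trait_table()].
#' @param trait Trait to mask.
#' @param tail_spec List; numerical traits: `side` (`"lower"`, `"upper"`,
#'   `"center_on_zero"`), `fraction` (default 0.10); categorical traits:
#'   `category`, `fraction` (default 1), `cap` (optional). Defaults to the
#'   trait's declared `mnar` spec, else lower tail / rarest category.
#' @param replicate_seed Seed (used only when sampling within a category).
#' @param replicate_id Identifier carried into the plan.
#' @return A `mask_plan`.
#' @export
mask_mnar <- function(tt, trait, tail_spec = NULL, replicate_seed = 1L,
                      replicate_id = 1L) {
  spec <- tt$specs[[trait]]
  if (is.null(spec)) stopf("unknown trait '%s'", trait)
  tail_spec <- tail_spec %||% spec$mnar
  x <- tt$data[[trait]]
  obs <- which(!is.na(x))
  if (is_numerical(spec)) {
    side <- tail_spec$side %||% "lower"
    fraction <- tail_spec$fraction %||% 0.10
    v <- as.numeric(x[obs])
    ranked <- switch(side,
                     lower = v,
                     upper = -v,
                     center_on_zero = abs(v),
                     stopf("unknown tail side '%s'", side))
    cut <- stats::quantile(ranked, fraction, type = 7, names = FALSE)
    take <- obs[ranked <= cut]
    if (!length(take)) stopf("empty tail for trait '%s'", trait)
  } else {
    category <- tail_spec$category %||%
      names(sort(table(as.character(x[obs]))))[1L]
    if (!(category %in% spec$categories))
      stopf("unknown category '%s' for trait '%s'", category, trait)
    fraction <- tail_spec$fraction %||% 1
    incat <- obs[as.character(x[obs]) == category]
    if (!length(incat)) stopf("no observed cells in category '%s'", category)
    m <- round_half_up(fraction * length(incat))
    if (!is.null(tail_spec$cap)) m <- min(m, tail_spec$cap)
    take <- if (m >= length(incat)) incat else
      with_seed(replicate_seed, sort(sample(incat, m)))
  }
  cells <- data.frame(species = tt$species[take], trait = trait,
                      stringsAsFactors = FALSE)
  new_mask_plan(cells, "MNAR", "n/a", replicate_id, replicate_seed)
}

# Union of per-trait plans into one mechanism-level plan.
combine_mask_plans <- function(plans, mechanism, replicate_id, seed) {
  cells <- unique(do.call(rbind, lapply(plans, `[[`, "cells")))
  new_mask_plan(cells, mechanism, "n/a", replicate_id, seed)
}
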