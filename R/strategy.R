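# End-to-end strategy: enumerate the combination design, simulate
# missingness replicates, impute under every setting, score, aggregate,
# and select the best-suited method by majority vote.

#' Enumerate the combination design
#'
#' Cartesian product of imputation method x phylogeny source (the
#' mean/mode baseline has no phylogenetic variant) x mechanism setting,
#' where each MCAR proportion is its own setting and MAR / MNAR contribute
#' one setting each, in stable order. With four methods, four trees and
#' MCAR at 0.10/0.20/0.30/0.40 plus MAR and MNAR this yields 96 settings.
#'
#' @param methods Character vector of candidate methods.
#' @param tree_labels Labels of the available trees (may be empty).
#' @param mcar_proportions Strictly increasing MCAR proportions.
#' @param mechanisms Subset of `c("MCAR", "MAR", "MNAR")`.
#' @return Data frame with columns method, phylogeny_source, mechanism,
#'   proportion (`"n/a"` for MAR/MNAR).
#' @export
enumerate_settings <- function(methods = c("mean_mode", "knn", "rf", "mice"),
                               tree_labels = character(0),
                               mcar_proportions = c(0.10, 0.20, 0.30, 0.40),
                               mechanisms = c("MCAR", "MAR", "MNAR")) {
  if (!length(methods)) stopf("need at least one method")
  if (!length(mechanisms)) stopf("need at least one mechanism")
  mechanisms <- match.arg(mechanisms, several.ok = TRUE)
  if ("MCAR" %in% mechanisms && any(diff(mcar_proportions) <= 0))
    stopf("MCAR proportions must be strictly increasing")
  mech <- do.call(rbind, lapply(mechanisms, function(m) {
    if (m == "MCAR")
      data.frame(mechanism = "MCAR",
                 proportion = as.character(mcar_proportions),
                 stringsAsFactors = FALSE)
    else data.frame(mechanism = m, proportion = "n/a", stringsAsFactors = FALSE)
  }))
  combos <- do.call(rbind, lapply(methods, function(met) {
    sources <- if (met == "mean_mode") "none" else c("none", tree_labels)
    data.frame(method = met, phylogeny_source = sources,
               stringsAsFactors = FALSE)
  }))
  out <- merge(combos, mech, by = NULL)
  out[order(match(out$method, methods), out$phylogeny_source,
            match(out$mechanism, c("MCAR", "MAR", "MNAR")),
            suppressWarnings(as.numeric(out$proportion))), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}

#' Run the real-data-driven method-selection strategy
#'
#' Fits the full four-step strategy to a trait table: (1) builds the near
#' complete-case table and simulates missingness replicates under the
#' requested mechanisms — nested-proportion MCAR; MAR from logistic
#' missingness models fitted to a reference table; MNAR tail/category
#' deletion; (2) imputes every replicate under every (method, phylogeny
#' source) combination, appending PCoA eigenvectors of each tree's
#' patristic distances for the phylogenetic variants; (3) scores imputed
#' cells against the held-out truth (MSE on the model scale for numerical
#' traits, PFC for categorical) and averages over replicates; (4) selects
#' the best-suited combination by majority vote with MAR-first
#' tie-breaking. Masking is shared across methods within a replicate so
#' methods are compared on identical missingness.
#'
#' @param table A [trait_table()]; the target dataset.
#' @param trees Named list of `phylo` trees (may be empty for a
#'   phylogeny-free study).
#' @param methods Candidate methods (default all four).
#' @param mcar_proportions Nested MCAR proportions (default
#'   0.10/0.20/0.30/0.40).
#' @param mechanisms Mechanisms to simulate (default all three).
#' @param n_replicates Replicates per setting (default 100).
#' @param alpha Significance level for the auxiliary-trait screen and the
#'   MAR predictor screen (default 0.05).
#' @param ev_threshold Cumulative-variance threshold for eigenvector
#'   retention (default 0.65).
#' @param mar_reference Reference [trait_table()] carrying real
#'   missingness for fitting MAR models; defaults to `table` itself.
#' @param mar_target_proportion Calibrated expected MAR missingness per
#'   trait (default 0.20).
#' @param max_missing_per_trait,min_observed_other Near complete-case
#'   constraints (defaults 0.10 and 3).
#' @param method_params Named list of per-method argument overrides passed
#'   to [imputation_config()] (e.g.
#'   `list(knn = list(k_neighbors = 3))`).
#' @param seed Master seed; every replicate and method stream is derived
#'   from it deterministically.
#' @param outdir Optional directory for CSV/JSON artifacts (evaluation
#'   records, mean errors, error ratios, winner, manifest).
#' @param verbose Print progress (default `FALSE`).
#' @return Object of class `impute_strategy`; see
#'   [print.impute_strategy()], [summary.impute_strategy()],
#'   [predict.impute_strategy()].
#' @export
impute_strategy <- function(table, trees = list(),
                            methods = c("mean_mode", "knn", "rf", "mice"),
                            mcar_proportions = c(0.10, 0.20, 0.30, 0.40),
                            mechanisms = c("MCAR", "MAR", "MNAR"),
                            n_replicates = 100L, alpha = 0.05,
                            ev_threshold = 0.65, mar_reference = NULL,
                            mar_target_proportion = 0.20,
                            max_missing_per_trait = 0.10,
                            min_observed_other = 3L,
                            method_params = list(), seed = 1L,
                            outdir = NULL, verbose = FALSE) {
  stopifnot(n_replicates >= 1L)
  if (length(trees) && is.null(names(trees)))
    stopf("trees must be a named list")
  say <- function(...) if (verbose) message(sprintf(...))
  nc <- build_near_complete_case(table, max_missing_per_trait,
                                 min_observed_other)
  say("near complete-case table: %d of %d species",
      length(nc$species), length(table$species))
  predictors <- select_all_auxiliary_traits(nc, alpha = alpha)
  truth <- apply_transforms(nc)
  evs <- lapply(names(trees), function(lab) {
    common <- intersect(nc$species, trees[[lab]]$tip.label)
    missing_sp <- setdiff(nc$species, common)
    if (length(missing_sp))
      say("tree '%s' lacks %d species; they are excluded from its runs",
          lab, length(missing_sp))
    extract_eigenvectors(trees[[lab]], common, threshold = ev_threshold,
                         source_label = lab)
  })
  names(evs) <- names(trees)

  # MAR missingness models, fitted once per trait and reused across replicates
  mar_models <- list()
  if ("MAR" %in% mechanisms) {
    ref <- mar_reference %||% table
    for (trait in evaluable_traits(nc)) {
      model <- tryCatch(fit_mar_model(ref, trait, alpha = alpha),
                        error = function(e) NULL)
      if (!is.null(model) && model$eligible) mar_models[[trait]] <- model
      else say("trait '%s' skipped under MAR (%s)", trait,
               if (is.null(model)) "no missingness in reference"
               else "no significant predictor")
    }
    if (!length(mar_models)) {
      say("no trait eligible for MAR; mechanism dropped")
      mechanisms <- setdiff(mechanisms, "MAR")
    }
  }

  settings <- enumerate_settings(methods, names(trees), mcar_proportions,
                                 mechanisms)
  combos <- unique(settings[c("method", "phylogeny_source")])

  # mask plans shared across method/source combinations within a replicate
  plans <- list()
  for (rep_id in seq_len(n_replicates)) {
    if ("MCAR" %in% mechanisms) {
      mc <- mask_mcar(nc, mcar_proportions,
                      replicate_seed = derive_seed(seed, "mask", "MCAR", rep_id),
                      replicate_id = rep_id)
      for (j in seq_along(mcar_proportions))
        plans[[plan_key("MCAR", mcar_proportions[j], rep_id)]] <- mc[[j]]
    }
    if ("MAR" %in% mechanisms) {
      sub <- lapply(names(mar_models), function(trait)
        mask_mar(nc, mar_models[[trait]], mar_target_proportion,
                 replicate_seed = derive_seed(seed, "mask", "MAR", trait, rep_id),
                 replicate_id = rep_id))
      plans[[plan_key("MAR", "n/a", rep_id)]] <-
        combine_mask_plans(sub, "MAR", rep_id,
                           derive_seed(seed, "mask", "MAR", rep_id))
    }
    if ("MNAR" %in% mechanisms) {
      sub <- lapply(evaluable_traits(nc), function(trait)
        mask_mnar(nc, trait,
                  replicate_seed = derive_seed(seed, "mask", "MNAR", trait, rep_id),
                  replicate_id = rep_id))
      plans[[plan_key("MNAR", "n/a", rep_id)]] <-
        combine_mask_plans(sub, "MNAR", rep_id,
                           derive_seed(seed, "mask", "MNAR", rep_id))
    }
  }

  records <- list()
  failures <- list()
  for (s in seq_len(nrow(settings))) {
    st <- settings[s, ]
    say("setting %d/%d: %s + %s, %s@%s", s, nrow(settings), st$method,
        st$phylogeny_source, st$mechanism, st$proportion)
    for (rep_id in seq_len(n_replicates)) {
      plan <- plans[[plan_key(st$mechanism, st$proportion, rep_id)]]
      cfg <- build_config(st$method, st$phylogeny_source, method_params,
                          derive_seed(seed, "impute", st$method,
                                      st$phylogeny_source, st$mechanism,
                                      st$proportion, rep_id))
      res <- tryCatch({
        masked <- apply_mask_plan(truth, plan)
        if (st$phylogeny_source != "none")
          masked <- suppressMessages(
            augment_with_eigenvectors(masked, evs[[st$phylogeny_source]]))
        imp <- impute_with(masked, cfg, predictors)
        evaluate_imputation(imp, truth, plan)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <- data.frame(
          method = st$method, phylogeny_source = st$phylogeny_source,
          mechanism = st$mechanism, proportion = st$proportion,
          replicate = rep_id, error = conditionMessage(res),
          stringsAsFactors = FALSE)
        warnf("setting (%s+%s, %s@%s) replicate %d failed: %s", st$method,
              st$phylogeny_source, st$mechanism, st$proportion, rep_id,
              conditionMessage(res))
      } else {
        records[[length(records) + 1L]] <- res
      }
    }
  }
  records <- do.call(rbind, records)
  mean_table <- aggregate_replicates(records)
  ratios <- error_ratio_table(mean_table)
  summary_obj <- majority_vote(mean_table)
  best_config <- build_config(summary_obj$best_combo$method,
                              summary_obj$best_combo$phylogeny_source,
                              method_params, derive_seed(seed, "apply"))
  out <- structure(list(
    records = records, mean_table = mean_table, error_ratios = ratios,
    summary = summary_obj, best_config = best_config, settings = settings,
    combos = combos, n_replicates = n_replicates, seed = seed,
    near_complete_case = nc, truth = truth, predictors = predictors,
    eigenvector_sets = evs, mar_models = mar_models, trees = trees,
    failures = if (length(failures)) do.call(rbind, failures) else NULL,
    parameters = list(alpha = alpha, ev_threshold = ev_threshold,
                      mcar_proportions = mcar_proportions,
                      mechanisms = mechanisms,
                      mar_target_proportion = mar_target_proportion,
                      method_params = method_params),
    call = match.call()), class = "impute_strategy")
  if (!is.null(outdir)) write_strategy_artifacts(out, outdir)
  out
}

plan_key <- function(mechanism, proportion, rep_id)
  paste(mechanism, proportion, rep_id, sep = "|")

build_config <- function(method, phylogeny_source, method_params, seed) {
  args <- c(list(method = method, phylogeny_source = phylogeny_source,
                 seed = seed), method_params[[method]] %||% list())
  do.call(imputation_config, args)
}

#' @export
print.impute_strategy <- function(x, ...) {
  cat("Real-data-driven imputation method selection\n")
  cat(sprintf("  %d species (near complete-case), %d traits, %d trees\n",
              length(x$near_complete_case$species),
              length(evaluable_traits(x$near_complete_case)),
              length(x$trees)))
  cat(sprintf("  %d settings x %d replicates = %d runs (%d failed)\n",
              nrow(x$settings), x$n_replicates,
              nrow(x$settings) * x$n_replicates,
              if (is.null(x$failures)) 0L else nrow(x$failures)))
  print(x$summary)
  invisible(x)
}

#' @export
summary.impute_strategy <- function(object, ...) {
  structure(list(summary = object$summary, mean_table = object$mean_table,
                 error_ratios = object$error_ratios,
                 failures = object$failures),
            class = "summary.impute_strategy")
}

#' @export
print.summary.impute_strategy <- function(x, ...) {
  print(x$summary)
  cat("\nMean error per (mechanism, method, phylogeny source, trait):\n")
  print(x$mean_table, row.names = FALSE)
  if (!is.null(x$error_ratios)) {
    cat("\nError ratios (error without phylogeny / error with):\n")
    print(x$error_ratios, row.names = FALSE)
  }
  invisible(x)
}

#' Apply the selected best-suited method to the original table
#'
#' Subsets the original table to species with at least one observed trait
#' (and present in the winning tree, for a phylogenetic winner), skips
#' traits already complete in that subset, imputes the remaining missing
#' cells with the winning configuration, and reports a comparison between
#' original, imputed, and complete-case data on the original scale.
#'
#' @param object A fitted `impute_strategy`.
#' @param original The original incomplete [trait_table()] (default: the
#'   table the strategy was fitted to).
#' @param ... Unused.
#' @return List of class `strategy_application`: `imputed` (an
#'   `imputed_table` on the original scale), `comparison`
#'   ([compare_datasets()] output), `subset_missingness` (per-trait
#'   missing fractions of the imputed subset, 2 decimals), and
#'   `skipped_traits` (complete in the subset, not imputed).
#' @export
predict.impute_strategy <- function(object, original = NULL, ...) {
  original <- original %||% eval(object$call$table, parent.frame())
  cfg <- object$best_config
  observed_any <- rowSums(vapply(
    evaluable_traits(original),
    function(tr) !is.na(original$data[[tr]]),
    logical(length(original$species)))) > 0
  species <- original$species[observed_any]
  if (cfg$phylogeny_source != "none") {
    tree <- object$trees[[cfg$phylogeny_source]]
    if (is.null(tree)) stopf("tree '%s' unavailable", cfg$phylogeny_source)
    species <- intersect(species, tree$tip.label)
  }
  if (!length(species)) stopf("empty subset: no species to impute")
  subset <- subset_trait_table(original, species)
  skipped <- evaluable_traits(subset)[missing_fractions(subset) == 0]
  work <- apply_transforms(subset)
  if (cfg$phylogeny_source != "none") {
    evs <- extract_eigenvectors(object$trees[[cfg$phylogeny_source]],
                                species,
                                threshold = object$parameters$ev_threshold,
                                source_label = cfg$phylogeny_source)
    work <- augment_with_eigenvectors(work, evs)
  }
  imp <- impute_with(work, cfg, object$predictors)
  completed <- invert_transforms(imp$table)
  imp$table <- completed
  comparison <- compare_datasets(subset, completed, object$near_complete_case)
  structure(list(
    imputed = imp, comparison = comparison,
    subset_missingness = round(missing_fractions(subset), 2L),
    skipped_traits = skipped, species = species,
    config = cfg), class = "strategy_application")
}

#' @export
print.strategy_application <- function(x, ...) {
  cat(sprintf("best-suited method applied to %d species (%s + %s)\n",
              length(x$species), x$config$method, x$config$phylogeny_source))
  cat("  per-trait missingness of the imputed subset:\n")
  for (tr in names(x$subset_missingness))
    cat(sprintf("    %-18s %.2f%s\n", tr, x$subset_missingness[[tr]],
                if (tr %in% x$skipped_traits) "  (complete; not imputed)" else ""))
  invisible(x)
}

write_strategy_artifacts <- function(strategy, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(strategy$records, file.path(outdir, "evaluation_records.csv"),
                   row.names = FALSE)
  utils::write.csv(strategy$mean_table, file.path(outdir, "mean_errors.csv"),
                   row.names = FALSE)
  if (!is.null(strategy$error_ratios))
    utils::write.csv(strategy$error_ratios, file.path(outdir, "error_ratios.csv"),
                     row.names = FALSE)
  winner <- list(best_combo = strategy$summary$best_combo,
                 votes = strategy$summary$votes,
                 tie_break_trace = lapply(strategy$summary$tie_break_trace,
                                          function(t) list(votes = as.list(t$votes),
                                                           leaders = t$leaders)))
  jsonlite::write_json(winner, file.path(outdir, "strategy_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest <- list(seed = strategy$seed, n_replicates = strategy$n_replicates,
                   n_settings = nrow(strategy$settings),
                   parameters = strategy$parameters,
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
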