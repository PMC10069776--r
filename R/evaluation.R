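# Error metrics over deliberately masked cells, replicate aggregation,
# error ratios, majority-vote method selection, and dataset-comparison
# summaries.

#' Mean squared error of imputed numerical cells
#'
#' Computed only over cells that were deliberately masked by the plan and
#' have an observed true value, on the scale the imputation operated on
#' (the model scale when the table was log-transformed).
#'
#' @param imputed An `imputed_table`.
#' @param truth The unmasked [trait_table()] (same scale as the imputation).
#' @param plan The `mask_plan` that produced the missingness.
#' @param trait A numerical trait name.
#' @return Mean of squared (imputed - truth) over evaluable cells.
#' @export
score_numeric <- function(imputed, truth, plan, trait) {
  if (is.factor(truth$data[[trait]]))
    stopf("MSE requested for categorical trait '%s'", trait)
  cells <- evaluable_cells(imputed, truth, plan, trait)
  mean((cells$imputed - cells$truth)^2)
}

#' Proportion falsely classified for categorical cells
#'
#' @inheritParams score_numeric
#' @param trait A categorical trait name.
#' @return Fraction of evaluable masked cells whose imputed label differs
#'   from the true label.
#' @export
score_categorical <- function(imputed, truth, plan, trait) {
  if (!is.factor(truth$data[[trait]]))
    stopf("PFC requested for numerical trait '%s'", trait)
  cells <- evaluable_cells(imputed, truth, plan, trait)
  mean(as.character(cells$imputed) != as.character(cells$truth))
}

evaluable_cells <- function(imputed, truth, plan, trait) {
  sel <- plan$cells$trait == trait &
    plan$cells$species %in% imputed$table$species
  species <- plan$cells$species[sel]
  ti <- match(species, truth$species)
  keep <- !is.na(truth$data[ti, trait])
  species <- species[keep]
  if (!length(species)) stopf("no evaluable cells for trait '%s'", trait)
  data.frame(
    species = species,
    imputed = imputed$table$data[match(species, imputed$table$species), trait],
    truth = truth$data[match(species, truth$species), trait],
    stringsAsFactors = FALSE)
}

#' Score every trait touched by a mask plan
#'
#' @inheritParams score_numeric
#' @param mechanism,proportion_label,method,phylogeny_source,replicate_id
#'   Provenance columns; defaults are taken from the plan and the imputed
#'   table's config.
#' @return Data frame of evaluation records: one row per (trait, metric)
#'   with columns mechanism, proportion, method, phylogeny_source, trait,
#'   metric, value, replicate.
#' @export
evaluate_imputation <- function(imputed, truth, plan,
                                mechanism = plan$mechanism,
                                proportion_label = plan$proportion_label,
                                method = imputed$config$method,
                                phylogeny_source = imputed$config$phylogeny_source,
                                replicate_id = plan$replicate_id) {
  traits <- intersect(unique(plan$cells$trait), evaluable_traits(truth))
  rows <- lapply(traits, function(trait) {
    categorical <- is.factor(truth$data[[trait]])
    value <- if (categorical) score_categorical(imputed, truth, plan, trait)
             else score_numeric(imputed, truth, plan, trait)
    data.frame(mechanism = mechanism,
               proportion = as.character(proportion_label), method = method,
               phylogeny_source = phylogeny_source, trait = trait,
               metric = if (categorical) "PFC" else "MSE", value = value,
               replicate = replicate_id, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Average evaluation records over replicates
#'
#' @param records Data frame of evaluation records (see
#'   [evaluate_imputation()]).
#' @return Data frame with one row per (mechanism, proportion, method,
#'   phylogeny_source, trait): the metric, its mean over replicates, the
#'   replicate count, and the standard error of the mean.
#' @export
aggregate_replicates <- function(records) {
  if (!nrow(records)) stopf("no records to aggregate")
  key <- c("mechanism", "proportion", "method", "phylogeny_source", "trait",
           "metric")
  groups <- split(records, records[key], drop = TRUE)
  out <- lapply(groups, function(g) {
    cbind(g[1L, key, drop = FALSE],
          mean_error = mean(g$value), n_replicates = nrow(g),
          se = if (nrow(g) > 1L) stats::sd(g$value) / sqrt(nrow(g)) else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$mechanism, out$proportion, out$method, out$phylogeny_source,
            out$trait), , drop = FALSE]
}

#' Error ratio of non-phylogenetic to phylogenetic imputation
#'
#' A value above 1 means adding phylogenetic information improved the
#' imputation; below 1, that it hurt.
#'
#' @param err_without Error rate without phylogeny (MSE or PFC).
#' @param err_with Error rate with phylogeny.
#' @return `err_without / err_with`, or `NA` with a warning when
#'   `err_with` is zero (the ratio is undefined, not infinite).
#' @export
error_ratio <- function(err_without, err_with) {
  if (any(err_without < 0, err_with < 0)) stopf("error rates must be >= 0")
  if (err_with == 0) {
    warnf("error ratio undefined: error with phylogeny is zero")
    return(NA_real_)
  }
  err_without / err_with
}

#' Error ratios for every (method, trait, mechanism, tree) combination
#'
#' @param mean_table Output of [aggregate_replicates()].
#' @return Data frame with columns mechanism, proportion, method, tree,
#'   trait, metric, error_without, error_with, ratio.
#' @export
error_ratio_table <- function(mean_table) {
  with_phylo <- mean_table[mean_table$phylogeny_source != "none", , drop = FALSE]
  if (!nrow(with_phylo)) return(NULL)
  base <- mean_table[mean_table$phylogeny_source == "none", , drop = FALSE]
  key <- function(d) paste(d$mechanism, d$proportion, d$method, d$trait)
  i <- match(key(with_phylo), key(base))
  ok <- !is.na(i)
  with_phylo <- with_phylo[ok, , drop = FALSE]
  i <- i[ok]
  ratio <- ifelse(with_phylo$mean_error == 0, NA_real_,
                  base$mean_error[i] / with_phylo$mean_error)
  data.frame(mechanism = with_phylo$mechanism,
             proportion = with_phylo$proportion, method = with_phylo$method,
             tree = with_phylo$phylogeny_source, trait = with_phylo$trait,
             metric = with_phylo$metric,
             error_without = base$mean_error[i],
             error_with = with_phylo$mean_error, ratio = ratio,
             stringsAsFactors = FALSE)
}

#' Select the best-suited method by majority vote
#'
#' Under the MAR records, each trait votes for the (method, phylogeny)
#' combination with its lowest mean error; the combination with the most
#' votes wins. An exact tie repeats the vote using the MNAR records, then
#' MCAR (votes summed over proportions); a tie that survives all three
#' mechanisms is an error. Traits never simulated under MAR simply cast no
#' MAR vote. Near-ties are not special: only exact vote ties trigger the
#' fall-through, but every stage is recorded in the returned trace.
#'
#' @param mean_table Output of [aggregate_replicates()].
#' @return Object of class `strategy_summary`: `best_combo` (list with
#'   `method` and `phylogeny_source`), `votes` (per mechanism), and
#'   `tie_break_trace`.
#' @export
majority_vote <- function(mean_table) {
  if (!nrow(mean_table)) stopf("empty mean table")
  combos <- unique(mean_table[c("method", "phylogeny_source")])
  combos <- combos[order(combos$method, combos$phylogeny_source), , drop = FALSE]
  combo_id <- function(d) paste(d$method, d$phylogeny_source, sep = "+")
  all_ids <- combo_id(combos)
  vote_under <- function(mech, candidates) {
    sub <- mean_table[mean_table$mechanism == mech &
                        combo_id(mean_table) %in% candidates, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    votes <- stats::setNames(numeric(length(candidates)), candidates)
    for (trait in unique(sub$trait)) {
      rows <- sub[sub$trait == trait, , drop = FALSE]
      per_combo <- tapply(rows$mean_error, combo_id(rows), mean)
      winner <- names(per_combo)[order(per_combo, names(per_combo))][1L]
      votes[winner] <- votes[winner] + 1L
    }
    votes
  }
  trace <- list()
  candidates <- all_ids
  for (mech in c("MAR", "MNAR", "MCAR")) {
    votes <- vote_under(mech, candidates)
    if (is.null(votes)) next
    top <- names(votes)[votes == max(votes)]
    trace[[mech]] <- list(votes = votes, leaders = top)
    if (length(top) == 1L) {
      parts <- strsplit(top, "+", fixed = TRUE)[[1L]]
      return(structure(list(
        best_combo = list(method = parts[1L], phylogeny_source = parts[2L]),
        votes = lapply(trace, `[[`, "votes"), tie_break_trace = trace),
        class = "strategy_summary"))
    }
    candidates <- top
  }
  if (length(candidates) == 1L) {
    parts <- strsplit(candidates, "+", fixed = TRUE)[[1L]]
    return(structure(list(
      best_combo = list(method = parts[1L], phylogeny_source = parts[2L]),
      votes = lapply(trace, `[[`, "votes"), tie_break_trace = trace),
      class = "strategy_summary"))
  }
  stopf("persistent tie between combinations: %s",
        paste(candidates, collapse = ", "))
}

#' @export
print.strategy_summary <- function(x, ...) {
  cat(sprintf("best-suited method: %s (phylogeny: %s)\n",
              x$best_combo$method, x$best_combo$phylogeny_source))
  for (mech in names(x$votes)) {
    v <- x$votes[[mech]]
    cat(sprintf("  %s votes: %s\n", mech,
                paste(sprintf("%s=%d", names(v), v), collapse = ", ")))
  }
  invisible(x)
}

#' Compare original, imputed, and complete-case datasets
#'
#' Per-trait summary of how imputation changed the dataset's
#' characteristics relative to using only complete cases. Numerical traits
#' (on the original scale) are summarized by N, min, max, range, median,
#' mean, SE of the mean, the 0.95 confidence half-width (Student-t
#' quantile with N - 1 df times the SE), variance, and SD; categorical
#' traits by category counts and proportions.
#'
#' @param original Original incomplete [trait_table()].
#' @param imputed `imputed_table` (or completed [trait_table()]) of the
#'   original data.
#' @param complete_case The complete-case [trait_table()].
#' @return List with elements `numerical` (long data frame: trait, dataset,
#'   statistic, value) and `categorical` (trait, dataset, category, count,
#'   proportion).
#' @export
compare_datasets <- function(original, imputed, complete_case) {
  if (inherits(imputed, "imputed_table")) imputed <- imputed$table
  tabs <- list(complete_case = complete_case, original = original,
               imputed = imputed)
  num_rows <- list(); cat_rows <- list()
  for (ds in names(tabs)) {
    tt <- tabs[[ds]]
    for (trait in evaluable_traits(tt)) {
      x <- tt$data[[trait]]
      x <- x[!is.na(x)]
      if (!length(x)) next
      if (is.factor(x)) {
        counts <- table(as.character(x))
        cat_rows[[length(cat_rows) + 1L]] <- data.frame(
          trait = trait, dataset = ds, category = names(counts),
          count = as.integer(counts),
          proportion = as.numeric(counts) / sum(counts),
          stringsAsFactors = FALSE)
      } else {
        n <- length(x)
        se <- stats::sd(x) / sqrt(n)
        stats_v <- c(N = n, min = min(x), max = max(x),
                     range = max(x) - min(x), median = stats::median(x),
                     mean = mean(x), se_mean = se,
                     ci95_half_width = stats::qt(0.975, n - 1L) * se,
                     variance = stats::var(x), sd = stats::sd(x))
        num_rows[[length(num_rows) + 1L]] <- data.frame(
          trait = trait, dataset = ds, statistic = names(stats_v),
          value = as.numeric(stats_v), stringsAsFactors = FALSE)
      }
    }
  }
  list(numerical = do.call(rbind, num_rows),
       categorical = do.call(rbind, cat_rows))
}
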