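# Synthetic trees and mixed-type trait tables with controlled phylogenetic
# signal, inter-trait correlation, and pre-existing missingness. The
# defaults emulate the structure of a squamate life-history table: two
# continuous size traits, two count clutch-size traits, a signed
# latitude-like centroid, a rare binary insularity trait, and a three-level
# activity-time trait with one dominant category.

#' Default synthetic trait definitions
#'
#' Seven traits mirroring a mixed-type reptile life-history table. Latent
#' values evolve by Brownian motion with per-trait signal `lambda`; links
#' map latents to observations: identity for continuous traits,
#' 1 + Poisson(exp(a + b z)) for (strictly positive, right-skewed) counts,
#' and rank thresholds at fixed quantiles for categorical traits (0.80 for
#' the binary trait; 0.55 and 0.85 for the three-level trait, giving one
#' dominant and one rare category).
#'
#' @param signal_lambda Phylogenetic signal in \[0, 1\] applied to every
#'   trait (default 0.9; scalar or vector of 7).
#' @return List of per-trait definitions consumed by [simulate_traits()].
#' @export
default_trait_definitions <- function(signal_lambda = 0.9) {
  lam <- rep(signal_lambda, length.out = 7L)
  list(
    list(name = "svl_female", dtype = "continuous", signal_lambda = lam[1L],
         link = list(type = "identity", location = 4.2, scale = 0.6,
                     exponentiate = TRUE),
         transform = "natural_log", mnar = list(side = "lower", fraction = 0.10)),
    list(name = "svl_max", dtype = "continuous", signal_lambda = lam[2L],
         link = list(type = "identity", location = 4.35, scale = 0.6,
                     exponentiate = TRUE),
         transform = "natural_log", mnar = list(side = "lower", fraction = 0.10)),
    list(name = "latitude", dtype = "continuous", signal_lambda = lam[3L],
         link = list(type = "identity", location = 0, scale = 25),
         transform = "none",
         mnar = list(side = "center_on_zero", fraction = 0.10)),
    list(name = "clutch_largest", dtype = "count", signal_lambda = lam[4L],
         link = list(type = "exp_poisson", location = 1.2, scale = 0.5),
         transform = "natural_log", mnar = list(side = "upper", fraction = 0.10)),
    list(name = "clutch_smallest", dtype = "count", signal_lambda = lam[5L],
         link = list(type = "exp_poisson", location = 0.1, scale = 0.5),
         transform = "natural_log", mnar = list(side = "upper", fraction = 0.10)),
    list(name = "insular", dtype = "binary", signal_lambda = lam[6L],
         link = list(type = "threshold", quantiles = 0.80),
         categories = c("no", "yes"), transform = "none",
         mnar = list(category = "yes", fraction = 1)),
    list(name = "activity_time", dtype = "multicategorical",
         signal_lambda = lam[7L],
         link = list(type = "threshold", quantiles = c(0.55, 0.85)),
         categories = c("diurnal", "nocturnal", "cathemeral"),
         transform = "none", mnar = list(category = "nocturnal", fraction = 1))
  )
}

#' Default inter-trait correlation of the latent traits
#'
#' Strong correlation between the two size traits (0.9) and the two clutch
#' traits (0.7), moderate size-clutch correlation (0.4), and a weakly
#' informative latitude (0.2 with sizes); unit diagonal, positive
#' definite.
#'
#' @return A 7 x 7 correlation matrix named after
#'   [default_trait_definitions()].
#' @export
default_trait_correlation <- function() {
  traits <- c("svl_female", "svl_max", "latitude", "clutch_largest",
              "clutch_smallest", "insular", "activity_time")
  r <- diag(7)
  dimnames(r) <- list(traits, traits)
  set_pair <- function(a, b, v) {
    r[a, b] <<- v; r[b, a] <<- v
  }
  set_pair("svl_female", "svl_max", 0.9)
  set_pair("clutch_largest", "clutch_smallest", 0.7)
  set_pair("svl_female", "clutch_largest", 0.4)
  set_pair("svl_female", "clutch_smallest", 0.4)
  set_pair("svl_max", "clutch_largest", 0.4)
  set_pair("svl_max", "clutch_smallest", 0.4)
  set_pair("svl_female", "latitude", 0.2)
  set_pair("svl_max", "latitude", 0.2)
  set_pair("insular", "svl_female", 0.3)
  set_pair("insular", "svl_max", 0.3)
  set_pair("activity_time", "svl_female", 0.3)
  set_pair("activity_time", "clutch_largest", 0.3)
  r
}

#' Simulate a random ultrametric tree
#'
#' Birth-death (or pure-birth) simulation conditioned on the number of
#' surviving tips, via [ape::rphylo()]; the result is rooted, ultrametric,
#' with strictly positive branch lengths, and reproducible by seed.
#'
#' @param n_taxa Number of tips (>= 3).
#' @param birth,death Speciation and extinction rates (defaults 1 and 0,
#'   i.e. a Yule tree).
#' @param seed RNG seed.
#' @param max_retries Resimulation cap for degenerate outcomes.
#' @return An [ape] `phylo` tree.
#' @export
simulate_tree <- function(n_taxa, birth = 1, death = 0, seed = 1L,
                          max_retries = 10L) {
  if (n_taxa < 3L) stopf("n_taxa must be >= 3")
  with_seed(seed, {
    for (i in seq_len(max_retries)) {
      tree <- tryCatch(ape::rphylo(n_taxa, birth, death, fossils = FALSE),
                       error = function(e) NULL)
      if (!is.null(tree) && length(tree$tip.label) == n_taxa &&
          all(tree$edge.length > 0)) return(validate_tree(tree))
    }
    stopf("tree simulation failed after %d retries", max_retries)
  })
}

#' Simulate correlated mixed-type traits on a tree
#'
#' Latent values follow multivariate Brownian motion: each trait's latent
#' vector is drawn with covariance lambda-rescaled toward a star phylogeny
#' (off-diagonal entries of the tree's Brownian covariance multiplied by
#' the trait's `signal_lambda`, tip variances standardized to 1), then
#' traits are mixed by the Cholesky factor of the latent correlation
#' matrix — rescaling before mixing, so equal-lambda settings have exactly
#' the marginal signal asked for. Observations come from each trait's
#' link: identity (optionally exponentiated, giving log-normal positive
#' traits), 1 + Poisson with a log link, or rank thresholds at fixed
#' quantiles for categorical traits. Finally `pre_missing_fraction` of
#' each trait's cells is masked completely at random, re-drawn if needed
#' so that every incomplete species keeps observed values for at least
#' three other traits.
#'
#' @param tree A `phylo` tree.
#' @param traits Trait definitions (default
#'   [default_trait_definitions()]).
#' @param correlation Latent correlation matrix (default
#'   [default_trait_correlation()] when using the default traits, identity
#'   otherwise); symmetric, unit diagonal, positive semi-definite.
#' @param pre_missing_fraction Pre-existing MCAR missingness per trait, at
#'   most 0.10 (default 0.05).
#' @param seed RNG seed.
#' @return A [trait_table()] whose rows follow `tree$tip.label`.
#' @export
simulate_traits <- function(tree, traits = default_trait_definitions(),
                            correlation = NULL, pre_missing_fraction = 0.05,
                            seed = 1L) {
  validate_tree(tree)
  n <- length(tree$tip.label)
  q <- length(traits)
  if (pre_missing_fraction < 0 || pre_missing_fraction > 0.10)
    stopf("pre_missing_fraction must lie in [0, 0.10]")
  if (is.null(correlation)) {
    correlation <- if (q == 7L &&
                       identical(vapply(traits, `[[`, "", "name"),
                                 rownames(default_trait_correlation())))
      default_trait_correlation() else diag(q)
  }
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
      !isTRUE(all.equal(unname(diag(correlation)), rep(1, q))))
    stopf("correlation must be symmetric with unit diagonal")
  eigmin <- min(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values)
  if (eigmin < -1e-8) stopf("correlation matrix is not positive semi-definite")
  cmat <- ape::vcv(tree)
  cmat <- cmat / max(diag(cmat))  # unit tip variance on an ultrametric tree
  with_seed(seed, {
    z <- vapply(seq_len(q), function(j) {
      v <- traits[[j]]$signal_lambda * cmat
      diag(v) <- diag(cmat)
      drop(t(chol(v + diag(1e-10, n))) %*% stats::rnorm(n))
    }, numeric(n))
    x <- z %*% chol(correlation + diag(1e-10, q))
    values <- list()
    specs <- list()
    for (j in seq_len(q)) {
      tr <- traits[[j]]
      link <- tr$link
      lat <- x[, j]
      obs <- switch(link$type,
        identity = {
          v <- link$location + link$scale * lat
          if (isTRUE(link$exponentiate)) exp(v) else v
        },
        exp_poisson = 1 + stats::rpois(n, exp(link$location + link$scale * lat)),
        threshold = {
          cuts <- c(0, link$quantiles, 1)
          band <- findInterval((rank(lat, ties.method = "first") - 0.5) / n,
                               cuts, rightmost.closed = TRUE)
          tr$categories[band]
        },
        stopf("unknown link type '%s'", link$type))
      values[[tr$name]] <- obs
      specs[[tr$name]] <- trait_spec(tr$name, tr$dtype,
                                     categories = tr$categories,
                                     transform = tr$transform %||% "none",
                                     mnar = tr$mnar)
    }
    tt <- trait_table(tree$tip.label, specs,
                      as.data.frame(values, stringsAsFactors = FALSE))
    if (pre_missing_fraction > 0)
      tt <- add_pre_missingness(tt, pre_missing_fraction)
    tt
  })
}

# MCAR pre-missingness respecting the near-complete-case side condition:
# every incomplete row keeps >= 3 observed other traits.
add_pre_missingness <- function(tt, fraction, min_observed_other = 3L,
                                max_tries = 100L) {
  traits <- evaluable_traits(tt)
  n <- length(tt$species)
  m <- round_half_up(fraction * n)
  if (m == 0L) return(tt)
  for (try in seq_len(max_tries)) {
    mask <- matrix(FALSE, n, length(traits))
    for (j in seq_along(traits)) mask[sample.int(n, m), j] <- TRUE
    n_miss <- rowSums(mask)
    ok <- n_miss == 0L | (length(traits) - n_miss) >= min_observed_other
    if (all(ok)) {
      for (j in seq_along(traits)) tt$data[mask[, j], traits[j]] <- NA
      return(tt)
    }
  }
  stopf("could not place pre-existing missingness within %d tries", max_tries)
}

#' Simulate a complete synthetic study (tree + traits)
#'
#' Convenience wrapper producing the tree and table used throughout the
#' documentation and tests: a Yule tree of `n_taxa` tips and the default
#' seven-trait table at a common signal strength.
#'
#' @inheritParams simulate_tree
#' @inheritParams simulate_traits
#' @param signal_lambda Common phylogenetic signal (default 0.9).
#' @return List with elements `tree` and `table`.
#' @export
simulate_study <- function(n_taxa = 152L, signal_lambda = 0.9,
                           pre_missing_fraction = 0.05, seed = 1L) {
  tree <- simulate_tree(n_taxa, seed = derive_seed(seed, "tree"))
  table <- simulate_traits(tree,
                           default_trait_definitions(signal_lambda),
                           pre_missing_fraction = pre_missing_fraction,
                           seed = derive_seed(seed, "traits"))
  list(tree = tree, table = table)
}

#' Impose covariate-driven (MAR) missingness on a table
#'
#' Deletes observed cells of each target trait with probability
#' `plogis(qlogis(proportion) + slope * z)`, where z is the standardized
#' driver trait — emulating, e.g., the sampling bias by which
#' small-bodied species are less studied. Used to build a synthetic
#' reference table whose missingness models MAR simulation can recover.
#'
#' @param tt A [trait_table()].
#' @param targets Traits receiving missingness (default: every trait
#'   except the driver).
#' @param driver Numerical trait whose values drive missingness (default
#'   `"svl_female"`).
#' @param proportion Marginal missingness probability at the driver's mean
#'   (default 0.2).
#' @param slope Log-odds change per driver SD (default -1: low driver
#'   values more likely missing).
#' @param seed RNG seed.
#' @return The table with MAR missingness added.
#' @export
add_mar_missingness <- function(tt, targets = NULL, driver = "svl_female",
                                proportion = 0.2, slope = -1, seed = 1L) {
  if (is.null(tt$specs[[driver]]) || is.factor(tt$data[[driver]]))
    stopf("driver must be a numerical trait")
  targets <- targets %||% setdiff(evaluable_traits(tt), driver)
  z <- as.numeric(scale(tt$data[[driver]]))
  with_seed(seed, {
    for (trait in targets) {
      p <- stats::plogis(stats::qlogis(proportion) + slope * z)
      hit <- !is.na(tt$data[[trait]]) & !is.na(z) &
        stats::runif(length(z)) < p
      tt$data[hit, trait] <- NA
    }
  })
  tt
}

#' Simulate a reference table with realistic MAR missingness
#'
#' A larger companion table from the same trait-generating process,
#' carrying covariate-driven missingness, standing in for the original
#' full dataset that MAR missingness models are fitted to. It is
#' synthetic: no real trait records are involved.
#'
#' @inheritParams simulate_study
#' @inheritParams add_mar_missingness
#' @return A [trait_table()] with MAR missingness.
#' @export
simulate_reference <- function(n_taxa = 400L, signal_lambda = 0.9,
                               proportion = 0.2, slope = -1, seed = 1L) {
  tree <- simulate_tree(n_taxa, seed = derive_seed(seed, "ref-tree"))
  tt <- simulate_traits(tree, default_trait_definitions(signal_lambda),
                        pre_missing_fraction = 0,
                        seed = derive_seed(seed, "ref-traits"))
  add_mar_missingness(tt, proportion = proportion, slope = slope,
                      seed = derive_seed(seed, "ref-mar"))
}

#' A fixed 12-species worked example
#'
#' Byte-stable miniature dataset used in documentation and golden tests:
#' twelve species, four traits (one continuous, one count, one binary, one
#' three-level categorical, with two missing cells), and a matching
#' 12-leaf ultrametric tree.
#'
#' @return List with elements `table` (a [trait_table()]) and `tree`
#'   (a `phylo`).
#' @export
make_worked_example <- function() {
  newick <- paste0(
    "(((sp01:1,sp02:1):2,(sp03:2,(sp04:1,sp05:1):1):1):3,",
    "((sp06:2,(sp07:1,sp08:1):1):2,((sp09:1,sp10:1):2,",
    "(sp11:2,sp12:2):1):1):2);")
  tree <- validate_tree(ape::read.tree(text = newick))
  specs <- list(
    trait_spec("body_size", "continuous", transform = "natural_log",
               mnar = list(side = "lower", fraction = 0.10)),
    trait_spec("clutch", "count", transform = "natural_log",
               mnar = list(side = "upper", fraction = 0.10)),
    trait_spec("insular", "binary", categories = c("no", "yes"),
               mnar = list(category = "yes", fraction = 1)),
    trait_spec("activity", "multicategorical",
               categories = c("diurnal", "nocturnal", "cathemeral"),
               mnar = list(category = "nocturnal", fraction = 1)))
  data <- data.frame(
    body_size = c(52.1, 48.7, 61.3, 58.9, 60.2, 105.4, 98.1, NA,
                  33.5, 35.2, 31.8, 34.4),
    clutch = c(2, 2, 3, 3, 3, 6, 5, 6, 1, 2, NA, 1),
    insular = c("no", "no", "no", "no", "yes", "no", "no", "yes",
                "no", "no", "yes", "no"),
    activity = c("diurnal", "diurnal", "diurnal", "nocturnal", "diurnal",
                 "nocturnal", "nocturnal", "diurnal", "cathemeral",
                 "diurnal", "diurnal", "nocturnal"),
    stringsAsFactors = FALSE)
  list(table = trait_table(sprintf("sp%02d", 1:12), specs, data),
       tree = tree)
}
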