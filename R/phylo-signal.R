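# Phylogenetic signal estimators: Pagel's lambda for continuous traits and
# Fritz & Purvis' D for binary traits.

new_signal_estimate <- function(metric, value, ...) {
  structure(c(list(metric = metric, value = value), list(...)),
            class = "signal_estimate")
}

#' @export
print.signal_estimate <- function(x, ...) {
  if (isTRUE(x$unidentifiable)) {
    cat(sprintf("signal_estimate [%s]: unidentifiable (%s)\n",
                x$metric, x$reason))
    return(invisible(x))
  }
  cat(sprintf("signal_estimate [%s]: %.4f", x$metric, x$value))
  if (!is.null(x$p_value_no_signal))
    cat(sprintf("  P(no signal) = %.4g", x$p_value_no_signal))
  if (!is.null(x$p_value_brownian))
    cat(sprintf("  P(Brownian) = %.4g", x$p_value_brownian))
  cat("\n")
  invisible(x)
}

# Align a named trait vector against tree tips (order of `species`).
align_trait <- function(trait, species) {
  if (!is.null(names(trait))) {
    unknown <- setdiff(species, names(trait))
    if (length(unknown)) stopf("trait lacks value for species '%s'", unknown[1L])
    trait <- trait[species]
  } else if (length(trait) != length(species)) {
    stopf("unnamed trait vector must match the number of tips")
  }
  if (anyNA(trait)) stopf("trait must be observed for all supplied species")
  trait
}

#' Pagel's lambda for a continuous trait
#'
#' Maximum-likelihood estimate of the branch-length multiplier lambda in
#' \[0, 1\] under a multivariate normal model: the phylogenetic covariance
#' matrix has its off-diagonal entries scaled by lambda while tip variances
#' stay unchanged; the mean and Brownian rate are profiled out analytically.
#' lambda = 0 corresponds to a star phylogeny (no signal), lambda = 1 to
#' plain Brownian motion. The no-signal p-value comes from a likelihood
#' ratio test of the estimate against lambda = 0 with the one-sided
#' boundary mixture 0.5 chi2_0 + 0.5 chi2_1.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param trait Numeric vector, named by species (or ordered as
#'   `tree$tip.label`); must be fully observed and non-constant.
#' @param tol Convergence tolerance of the bounded profile-likelihood
#'   search (default 1e-6).
#' @return A `signal_estimate` with `metric = "lambda"`, the estimate,
#'   `p_value_no_signal`, and the two profile log-likelihoods. A star tree
#'   (all tip covariances zero) yields an unidentifiable flag instead of a
#'   numeric estimate.
#' @export
pagels_lambda <- function(tree, trait, tol = 1e-6) {
  validate_tree(tree)
  y <- as.numeric(align_trait(trait, tree$tip.label))
  if (stats::var(y) == 0) stopf("constant trait: lambda is undefined")
  cmat <- ape::vcv(tree)
  n <- length(y)
  offdiag <- cmat[upper.tri(cmat)]
  if (all(abs(offdiag) <= 1e-12 * max(diag(cmat))))
    return(new_signal_estimate("lambda", NA_real_, unidentifiable = TRUE,
                               reason = "star tree: covariance does not depend on lambda"))
  profile_ll <- function(lambda) {
    v <- lambda * cmat
    diag(v) <- diag(cmat)
    ch <- tryCatch(chol(v), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    logdet <- 2 * sum(log(diag(ch)))
    vi1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
    viy <- backsolve(ch, forwardsolve(t(ch), y))
    mu <- sum(vi1 * y) / sum(vi1)
    r <- y - mu
    vir <- viy - mu * vi1
    sigma2 <- sum(r * vir) / n
    -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdet + n)
  }
  opt <- stats::optimize(profile_ll, c(0, 1), maximum = TRUE, tol = tol)
  cand_l <- c(0, opt$maximum, 1)
  cand_ll <- c(profile_ll(0), opt$objective, profile_ll(1))
  best <- which.max(cand_ll)
  lr <- 2 * (cand_ll[best] - cand_ll[1L])
  p <- if (lr <= 0) 1 else 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  new_signal_estimate("lambda", cand_l[best], p_value_no_signal = p,
                      loglik = cand_ll[best], loglik_lambda0 = cand_ll[1L],
                      unidentifiable = FALSE)
}

# Linear operator mapping tip states to equal-weight averaged ancestral
# node values: postorder sweep assigning each internal node the mean of its
# direct children's values. Returns the edge matrix plus a function
# applying the sweep to a tips x nsim matrix, giving per-simulation sums of
# absolute changes along all edges.
sum_of_changes_fun <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  # process internal nodes deepest-first so children are always ready
  edge_cw <- ape::reorder.phylo(tree, "cladewise")$edge
  depth <- integer(n_node)
  for (i in seq_len(nrow(edge_cw)))
    depth[edge_cw[i, 2L]] <- depth[edge_cw[i, 1L]] + 1L
  internal <- (n_tip + 1L):n_node
  postorder <- internal[order(depth[internal], decreasing = TRUE)]
  function(tipmat) {
    v <- matrix(NA_real_, n_node, ncol(tipmat))
    v[seq_len(n_tip), ] <- tipmat
    for (node in postorder) {
      kids <- children[[as.character(node)]]
      v[node, ] <- colMeans(v[kids, , drop = FALSE])
    }
    colSums(abs(v[tree$edge[, 1L], , drop = FALSE] -
                  v[tree$edge[, 2L], , drop = FALSE]))
  }
}

#' Fritz & Purvis' D for a binary trait
#'
#' Measures whether the observed sum of character changes of a binary trait
#' along a phylogeny differs from expectation under Brownian motion. The
#' sum of changes d is computed by estimating ancestral values through
#' equal-weight averaging of descendant values (tips upward) and summing
#' absolute differences along all edges. D scales d_obs between the mean d
#' of tip-shuffled traits (no signal, D = 1) and the mean d of thresholded
#' Brownian simulations matching the observed prevalence (D = 0); D > 1
#' indicates overdispersion, D < 0 strong conservatism.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param trait Binary trait: 2-level factor, logical, or 0/1 numeric,
#'   named by species (or in tip order); both categories must be present.
#' @param n_random Number of tip-label shuffles (>= 10, default 1000).
#' @param n_brownian Number of threshold-Brownian simulations (>= 10,
#'   default 1000).
#' @param seed Seed for the two null distributions.
#' @return A `signal_estimate` with `metric = "D"`, the estimate,
#'   `p_value_no_signal` (lower-tail probability of d_obs under shuffling)
#'   and `p_value_brownian` (upper-tail probability under Brownian nulls).
#' @export
fritz_purvis_D <- function(tree, trait, n_random = 1000L, n_brownian = 1000L,
                           seed = 1L) {
  validate_tree(tree)
  if (n_random < 10L || n_brownian < 10L)
    stopf("n_random and n_brownian must each be >= 10")
  trait <- align_trait(trait, tree$tip.label)
  if (is.factor(trait) || is.character(trait)) {
    lev <- sort(unique(as.character(trait)))
    if (length(lev) != 2L) stopf("trait must have exactly 2 observed categories")
    x <- as.numeric(as.character(trait) == lev[2L])
  } else {
    x <- as.numeric(trait)
    if (!all(x %in% c(0, 1))) stopf("numeric binary trait must be 0/1")
  }
  n <- length(x)
  n1 <- sum(x)
  if (n1 == 0 || n1 == n) stopf("both categories must be present")
  d_of <- sum_of_changes_fun(tree)
  d_obs <- d_of(matrix(x, ncol = 1L))
  with_seed(seed, {
    shuffles <- vapply(seq_len(n_random), function(i) sample(x), numeric(n))
    d_r <- d_of(shuffles)
    ch <- chol(ape::vcv(tree))
    bm <- t(ch) %*% matrix(stats::rnorm(n * n_brownian), n, n_brownian)
    # threshold each simulation at the observed prevalence
    thresh <- apply(bm, 2L, function(col) {
      as.numeric(rank(col, ties.method = "first") > n - n1)
    })
    d_b <- d_of(thresh)
  })
  denom <- mean(d_r) - mean(d_b)
  if (abs(denom) < .Machine$double.eps)
    stopf("degenerate null distributions: random and Brownian d coincide")
  new_signal_estimate("D", (d_obs - mean(d_b)) / denom,
                      p_value_no_signal = mean(d_r <= d_obs),
                      p_value_brownian = mean(d_b >= d_obs),
                      n_permutations = n_random, n_simulations = n_brownian)
}
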