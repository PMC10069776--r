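# Shared fixtures, built in code.

toy_specs <- function() {
  list(
    trait_spec("size", "continuous", transform = "natural_log"),
    trait_spec("clutch", "count"),
    trait_spec("insular", "binary", categories = c("no", "yes")),
    trait_spec("activity", "multicategorical",
               categories = c("diurnal", "nocturnal", "cathemeral")))
}

toy_table <- function() {
  trait_table(
    paste0("sp", 1:6), toy_specs(),
    data.frame(size = c(10, 12, 8, NA, 15, 11),
               clutch = c(2, 3, 1, 4, NA, 2),
               insular = c("no", "yes", "no", "no", "yes", "no"),
               activity = c("diurnal", "diurnal", "nocturnal", "diurnal",
                            "cathemeral", "diurnal"),
               stringsAsFactors = FALSE))
}

write_toy_csv <- function(path, rows) {
  writeLines(c("species,size,clutch,insular,activity", rows), path)
}

# balanced 8-leaf tree with unit branch lengths at every level
small_tree <- function() {
  ape::read.tree(text = paste0(
    "(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);"))
}

# Continuous trait with covariance lambda-rescaled toward a star tree,
# generated directly from the multivariate-normal definition (independent
# of the package's own estimators).
with_bm_trait <- function(tree, lambda = 1, seed = 1) {
  cmat <- ape::vcv(tree)
  v <- lambda * cmat
  diag(v) <- diag(cmat)
  set.seed(seed)
  y <- drop(t(chol(v)) %*% rnorm(nrow(v)))
  names(y) <- rownames(cmat)
  y
}

expect_tables_equal <- function(a, b) {
  expect_identical(a$species, b$species)
  expect_identical(names(a$specs), names(b$specs))
  for (tr in names(a$specs)) {
    xa <- a$data[[tr]]; xb <- b$data[[tr]]
    if (is.factor(xa)) expect_identical(as.character(xa), as.character(xb))
    else expect_equal(xa, xb, tolerance = 1e-12)
  }
}
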