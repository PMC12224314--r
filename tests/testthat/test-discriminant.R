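# Kruskal-Wallis screening, shrinkage LDA, biplot export, heatmap ordering

test_that("KW reproduces the hand-computed perfectly separated case", {
  k <- kruskal_wallis(1:9, rep(c("a", "b", "c"), each = 3))
  expect_equal(k$H, 7.2, tolerance = 1e-12)
  expect_equal(k$p, exp(-3.6), tolerance = 1e-12)
  expect_identical(k$df, 2L)
})

test_that("KW handles degenerate input and is invariant under monotone transforms", {
  k <- kruskal_wallis(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_identical(k$H, 0); expect_identical(k$p, 1)

  set.seed(21)
  for (i in 1:20) {
    x <- sample(rep(1:4, times = 3))  # ties present
    g <- rep(c("a", "b", "c"), each = 4)
    h0 <- kruskal_wallis(x, g)$H
    expect_equal(kruskal_wallis(exp(x), g)$H, h0, tolerance = 1e-10)
    expect_equal(kruskal_wallis(rank(x), g)$H, h0, tolerance = 1e-10)
  }
  expect_error(kruskal_wallis(1:4, c("a", "b", "a", "b"), vocabulary = "a"), "vocabulary")
})

test_that("KW agrees with the reference implementation on 200 random tied instances", {
  set.seed(22)
  for (i in 1:200) {
    n_g <- sample(2:4, 1L)
    sizes <- sample(3:6, n_g, replace = TRUE)
    g <- rep(letters[seq_len(n_g)], times = sizes)
    x <- sample(1:5, sum(sizes), replace = TRUE)  # heavy ties
    if (length(unique(x)) == 1L) next
    ours <- kruskal_wallis(x, g)
    ref <- stats::kruskal.test(x, factor(g))
    expect_lt(abs(ours$H - unname(ref$statistic)), 1e-10)
    expect_lt(abs(ours$p - ref$p.value), 1e-10)
  }
})

test_that("screening retains strictly below the threshold and drops constants", {
  design <- tiny_protein_design()
  g <- design$substrate
  vals <- rbind(sep = 1:9,                      # perfectly separated, p ~ 0.027
                const = rep(2, 9),              # degenerate, p = 1
                noise = c(5, 3, 4, 4, 5, 3, 3, 5, 4))
  colnames(vals) <- design$experiment_id
  out <- screen_features(vals, g, threshold = 0.05)
  expect_true("sep" %in% out$retained)
  expect_false("const" %in% out$retained)
  # boundary: p exactly equal to the threshold is dropped (strict <)
  p_sep <- out$results$p[out$results$feature == "sep"]
  at_boundary <- screen_features(vals, g, threshold = p_sep)
  expect_false("sep" %in% at_boundary$retained)
  # BH flag only adjusts, never loosens, single-feature retention
  bh <- screen_features(vals, g, threshold = 0.05, adjust = "BH")
  expect_true(all(bh$retained %in% out$retained))
})

test_that("1-feature 2-group LDA orders centroids like the group means", {
  x <- matrix(c(0, 0.1, -0.1, 1, 1.1, 0.9), 1, 6,
              dimnames = list("f1", paste0("e", 1:6)))
  g <- rep(c("lo", "hi"), each = 3)
  m <- fit_lda(x, g)
  expect_identical(ncol(m$scores), 1L)
  expect_gt(m$centroids["hi", 1], m$centroids["lo", 1])
})

test_that("full-rank LDA matches the dense generalized-eigenproblem oracle", {
  set.seed(31)
  for (i in 1:10) {
    X <- matrix(rnorm(18 * 2), 18, 2)
    g <- rep(c("a", "b", "c"), each = 6)
    X[g == "b", 1] <- X[g == "b", 1] + 1.5
    X[g == "c", 2] <- X[g == "c", 2] - 2
    colnames(X) <- c("f1", "f2")
    m <- fit_lda(t(X), g, lambda = 0)
    oracle <- lda_eigen_oracle(X, g)
    expect_equal(unname(m$eigenvalues), oracle$eigenvalues, tolerance = 1e-8)
    expect_equal(unname(m$coef), unname(oracle$coef), tolerance = 1e-8)
  }
})

test_that("standardized coefficients and scores are invariant to per-feature rescaling", {
  set.seed(32)
  X <- matrix(rnorm(12 * 3), 3, 12,
              dimnames = list(paste0("f", 1:3), paste0("e", 1:12)))
  g <- rep(c("a", "b", "c"), each = 4)
  X[1, g == "a"] <- X[1, g == "a"] + 2
  X[2, g == "c"] <- X[2, g == "c"] + 1
  m1 <- fit_lda(X, g, lambda = 0)
  X2 <- X; X2[1, ] <- X2[1, ] * 10
  m2 <- fit_lda(X2, g, lambda = 0)
  expect_equal(m1$std_coef, m2$std_coef, tolerance = 1e-8)
  expect_equal(m1$scores, m2$scores, tolerance = 1e-8)
})

test_that("canonical scaling and model invariants hold", {
  set.seed(33)
  X <- matrix(rnorm(5 * 15), 5, 15,
              dimnames = list(paste0("f", 1:5), paste0("e", 1:15)))
  g <- rep(c("a", "b", "c"), each = 5)
  X[1, g == "a"] <- X[1, g == "a"] + 3
  m <- fit_lda(X, g, lambda = 0)
  # axes bounded by g - 1; proportions sum to 1; eigenvalues sorted, >= 0
  expect_lte(ncol(m$scores), 2L)
  expect_equal(sum(m$proportion), 1)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  expect_true(all(m$eigenvalues >= 0))
  # pooled within-group covariance of scores is the identity
  Wsc <- matrix(0, 2, 2)
  for (lev in unique(g)) {
    S <- m$scores[g == lev, , drop = FALSE]
    Wsc <- Wsc + crossprod(sweep(S, 2L, colMeans(S)))
  }
  expect_equal(Wsc / (15 - 3), diag(2), tolerance = 1e-6, ignore_attr = TRUE)
  # standardized coefficient = raw x pooled within-group sd
  expect_equal(m$std_coef, m$coef * m$within_sd, tolerance = 1e-12)
  # centroids are the group means of the case scores
  expect_equal(m$centroids["a", ], colMeans(m$scores[g == "a", ]), tolerance = 1e-10)
})

test_that("the wide shape (110 features, 9 cases, 3 groups) fits with exactly 2 axes", {
  set.seed(34)
  X <- matrix(rnorm(110 * 9), 110, 9,
              dimnames = list(sprintf("f%03d", 1:110), paste0("e", 1:9)))
  g <- rep(c("dentine", "enamel", "titanium"), each = 3)
  X[1:20, g == "dentine"] <- X[1:20, g == "dentine"] + 1
  m <- fit_lda(X, g)
  expect_identical(ncol(m$scores), 2L)
  expect_gt(m$lambda, 0)  # singular within-scatter forced shrinkage
  expect_true(all(is.finite(m$scores)))
  expect_error(fit_lda(X, rep("one", 9)), ">= 2 groups")
})

test_that("biplot coordinates: LD2 zero-fill, centroid identity, vector lengths", {
  set.seed(35)
  X <- matrix(rnorm(3 * 8), 3, 8,
              dimnames = list(paste0("f", 1:3), paste0("e", 1:8)))
  g <- rep(c("a", "b"), each = 4)
  X[1, g == "b"] <- X[1, g == "b"] + 2
  bc <- biplot_coordinates(fit_lda(X, g, lambda = 0))
  expect_true(all(bc$cases$LD2 == 0))
  expect_true(all(bc$centroids$LD2 == 0))
  expect_equal(bc$features$length, abs(bc$features$LD1), tolerance = 1e-12)

  m3 <- fit_lda(matrix(rnorm(2 * 9), 2, 9,
                       dimnames = list(c("f1", "f2"), paste0("e", 1:9))),
                rep(c("a", "b", "c"), each = 3), lambda = 0)
  bc3 <- biplot_coordinates(m3)
  for (lev in c("a", "b", "c"))
    expect_equal(unlist(bc3$centroids[bc3$centroids$group == lev, c("LD1", "LD2")]),
                 colMeans(m3$scores[m3$groups == lev, , drop = FALSE]),
                 tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("complete-linkage ordering: nearest pair first, duplicates at height 0, oracle heights", {
  pts <- matrix(c(0, 1, 10), ncol = 1)
  out <- hclust_complete_order(pts)
  expect_equal(out$row_heights[1], 1)        # {0,1} merge first
  dup <- rbind(c(1, 2), c(1, 2), c(5, 9))
  expect_equal(hclust_complete_order(dup)$row_heights[1], 0)

  set.seed(36)
  for (i in 1:5) {
    pts <- matrix(rnorm(16), 8, 2)
    ours <- sort(hclust_complete_order(pts)$row_heights)
    expect_equal(ours, brute_complete_linkage_heights(pts), tolerance = 1e-10)
  }
})

test_that("screen-then-fit retains planted discriminants with adequate effect sizes", {
  found <- total <- 0L
  for (seed in 1:25) {
    cfg <- synthetic_config(n_proteins = 80L, n_asvs = 10L,
                            n_discriminant_proteins = 20L,
                            n_discriminant_asvs = 2L, n_couplings = 0L,
                            seed = seed)
    pr <- simulate_proteome(cfg)
    eff <- pr$truth$protein_effects
    # planted proteins separating every substrate pair by >= 2 within-group
    # sds: with 3 readings per substrate the KW chi-square tail only reaches
    # p < 0.05 when all three groups separate, so this is the effect-size
    # notion under which the screen can have power at all
    min_gap <- apply(eff, 1L, function(e) min(diff(sort(e))))
    strong <- rownames(eff)[min_gap >= 2 * cfg$reading_log10_sd]
    strong <- intersect(strong, rownames(pr$table$values))
    if (length(strong) == 0L) next
    imp <- fit_imputation_constant(pr$table)
    tab <- if (imp$applicable) apply_imputation(pr$table, imp$c) else pr$table
    sc <- screen_features(log10(tab$values), tab$design$substrate, threshold = 0.05)
    found <- found + length(intersect(strong, sc$retained))
    total <- total + length(strong)
  }
  expect_gte(found / total, 0.8)
})
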