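# substrate-matched pairing, Pearson/MI association, thresholds, top-k

two_side_fixture <- function(nx = 2L, ny = 3L, substrates = "dentine") {
  xd <- experiment_design(paste0("x", seq_len(nx * length(substrates))),
                          rep(substrates, each = nx))
  yd <- experiment_design(paste0("y", seq_len(ny * length(substrates))),
                          rep(substrates, each = ny),
                          timepoint = "2h")
  list(xd = xd, yd = yd)
}

test_that("pairing cardinality: full Cartesian product within each substrate", {
  f <- two_side_fixture(2L, 3L)
  expect_identical(nrow(pair_index(f$xd, f$yd)), 6L)

  xd <- experiment_design(paste0("x", 1:5), c(rep("dentine", 2), rep("enamel", 3)))
  yd <- experiment_design(paste0("y", 1:6), rep(c("dentine", "enamel"), each = 3),
                          timepoint = "2h")
  expect_identical(nrow(pair_index(xd, yd)), 2L * 3L + 3L * 3L)

  xo <- experiment_design("x1", "dentine")
  yo <- experiment_design("y1", "titanium", timepoint = "2h")
  expect_error(pair_index(xo, yo), "no common substrate")
})

test_that("pair multisets equal the brute-force substrate-filtered double loop", {
  set.seed(41)
  for (i in 1:20) {
    subs <- c("dentine", "enamel", "titanium")
    xd <- experiment_design(paste0("x", 1:8), sample(subs, 8, replace = TRUE))
    yd <- experiment_design(paste0("y", 1:7), sample(subs, 7, replace = TRUE),
                            timepoint = "2h")
    common <- intersect(unique(xd$substrate), unique(yd$substrate))
    if (length(common) == 0L) next
    ours <- pair_index(xd, yd)
    brute <- brute_pairs(xd, yd)
    expect_identical(nrow(ours), nrow(brute))
    expect_identical(sort(paste(ours$i, ours$j)), sort(paste(brute$i, brute$j)))
  }
})

test_that("pearson_r on exact lines and the hand case", {
  up <- data.frame(l = 1:5, a = 2 * (1:5) + 3)
  expect_equal(pearson_r(up), 1, tolerance = 1e-12)
  down <- data.frame(l = 1:5, a = -0.5 * (1:5))
  expect_equal(pearson_r(down), -1, tolerance = 1e-12)
  d <- data.frame(l = c(1, 2, 3), a = c(2, 1, 3))
  expect_equal(pearson_r(d), cor(d$l, d$a), tolerance = 1e-12)
  expect_equal(pearson_r(d), 0.5, tolerance = 1e-12)  # direct formula
  expect_true(is.na(pearson_r(data.frame(l = c(1, 1, 1), a = 1:3))))
  expect_error(pearson_r(data.frame(l = 1:2, a = 1:2)), ">= 3")
})

test_that("mutual information: monotone limit, independence bound, exact symmetry", {
  n <- 5000L
  l <- seq_len(n)
  a <- l^3  # deterministic strictly monotone
  mi_det <- mutual_information(data.frame(l = l, a = a))
  b <- max(2L, min(10L, floor(sqrt(n / 5))))
  expect_lt(abs(mi_det - log(b)), 0.05)

  set.seed(42)
  ind <- data.frame(l = rnorm(10000), a = rnorm(10000))
  expect_lte(mutual_information(ind), 0.02)

  set.seed(43)
  d <- data.frame(l = rnorm(200), a = rnorm(200))
  expect_identical(mutual_information(d),
                   mutual_information(data.frame(l = d$a, a = d$l)))
  expect_error(mutual_information(d[1:5, ]), ">= 10")
  expect_warning(mutual_information(d[1:30, ], bins = 20L), "biased")
})

test_that("bulk association agrees with per-pair construction", {
  set.seed(44)
  xd <- tiny_protein_design(2L)
  yd <- tiny_asv_design(2L)
  xv <- matrix(rnorm(3 * 6, 10), 3, 6, dimnames = list(paste0("P", 1:3), xd$experiment_id))
  yv <- matrix(rnorm(4 * 6, 5), 4, 6, dimnames = list(paste0("A", 1:4), yd$experiment_id))
  x <- feature_matrix(xv, xd); y <- feature_matrix(yv, yd)
  res <- associate_features(x, y, mi = TRUE)
  expect_identical(nrow(res), 12L)
  for (k in sample(nrow(res), 4L)) {
    ps <- build_pair_set(x, y, res$x_feature[k], res$y_feature[k])
    expect_identical(nrow(ps$pairs), res$n_pairs[k])
    expect_equal(res$r[k], pearson_r(ps), tolerance = 1e-12)
    expect_equal(res$mi[k], mutual_information(ps), tolerance = 1e-12)
  }
})

test_that("thresholding is strict and labels the strong tier; counts match brute force", {
  res <- data.frame(x_feature = paste0("P", 1:5), y_feature = paste0("A", 1:5),
                    n_pairs = 27L,
                    r = c(0.7, -0.85, 0.95, 0.1, NA))
  edges <- threshold_associations(res, tau = 0.7, strong = 0.8)
  expect_identical(nrow(edges), 2L)          # 0.7 exactly excluded; NA excluded
  e <- edges[edges$r < 0, ]
  expect_identical(e$sign, -1); expect_true(e$strong)
  set.seed(45)
  rr <- data.frame(x_feature = "P", y_feature = paste0("A", 1:500), n_pairs = 27L,
                   r = runif(500, -1, 1))
  expect_identical(nrow(threshold_associations(rr, tau = 0.6)),
                   sum(abs(rr$r) > 0.6))
})

test_that("top-k signed selection sorts, breaks ties lexicographically and warns when short", {
  res <- data.frame(x_feature = c("P2", "P1", "P3", "P4"),
                    y_feature = c("A1", "A1", "A2", "A3"),
                    r = c(0.9, 0.8, -0.95, 0.1))
  tk <- top_k_signed(res, k = 1L)
  expect_equal(tk$positive$r, 0.9)
  expect_equal(tk$negative$r, -0.95)
  # ties: same r -> lexicographic by (x_feature, y_feature)
  tie <- data.frame(x_feature = c("Pb", "Pa"), y_feature = c("A", "A"),
                    r = c(0.5, 0.5))
  expect_identical(suppressWarnings(top_k_signed(tie, k = 1L))$positive$x_feature, "Pa")
  expect_warning(top_k_signed(tie, k = 1L), "negative")
  set.seed(46)
  rnd <- data.frame(x_feature = sprintf("P%03d", 1:50), y_feature = "A",
                    r = runif(50, -1, 1))
  tk3 <- suppressWarnings(top_k_signed(rnd, k = 3L))
  expect_equal(tk3$positive$r, sort(rnd$r[rnd$r > 0], decreasing = TRUE)[1:3])
  expect_equal(tk3$negative$r, sort(rnd$r[rnd$r < 0])[1:3])
})

test_that("cross-timepoint association: identical profiles give r = 1 and the cardinality identity", {
  subs <- c("dentine", "enamel", "titanium")
  d2 <- tiny_asv_design(2L, "2h"); d24 <- tiny_asv_design(3L, "24h")
  base <- c(dentine = 5, enamel = 50, titanium = 500)
  v2 <- matrix(base[d2$substrate], 1, 6, dimnames = list("A1", d2$experiment_id))
  v24 <- matrix(base[d24$substrate], 1, 9, dimnames = list("A1", d24$experiment_id))
  out <- cross_timepoint_association(feature_matrix(v2, d2),
                                     feature_matrix(v24, d24), tau = 0.5)
  expect_identical(out$results$n_pairs[1], 3L * (2L * 3L))
  expect_equal(out$results$r[1], 1, tolerance = 1e-12)
  expect_identical(nrow(out$edges), 1L)
})

test_that("with full persistence, planted self-pairs dominate the cross-timepoint list", {
  cfg <- synthetic_config(n_proteins = 50L, n_asvs = 40L,
                          n_discriminant_proteins = 12L, n_discriminant_asvs = 10L,
                          n_couplings = 5L, persistence = 1, seed = 47L)
  pr <- simulate_proteome(cfg)
  mic <- simulate_microbiome(cfg, pr$truth)
  sp <- offset_alpha(cbind(mic$table_2h$values, mic$table_24h$values))
  varying <- union(mic$truth$discriminant_asvs, mic$truth$couplings$asv)
  out <- cross_timepoint_association(offset_log(mic$table_2h, sp),
                                     offset_log(mic$table_24h, sp))
  self <- out$edges[out$edges$x_feature == out$edges$y_feature, ]
  # every coupled taxon persists as a strong (q, q) self-correlation, and
  # all self-edges are substrate-varying taxa (ground truth)
  expect_true(all(mic$truth$couplings$asv %in% self$x_feature))
  expect_true(all(self$x_feature %in% varying))
  # pair count identity: substrates x (replicates at 2h x replicates at 24h
  expect_identical(out$results$n_pairs[1],
                   3L * cfg$replicates_per_substrate * cfg$replicates_per_substrate)
})
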