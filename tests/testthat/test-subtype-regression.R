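test_that("regulatory impact combines mark membership with calibrated scores", {
  ctx <- silens_contexts()
  ctrl <- (1:100) / 101
  curves <- lapply(ctx, function(cx) {
    list(enhancer = fit_fpr(ctrl), silencer = fit_fpr(ctrl))
  })
  names(curves) <- ctx
  peaks <- gr("chr1", c(1001, 3001, 5001), c(2000, 4000, 6000))
  ac <- gr("chr1", c(1001, 5001), c(2000, 6000))    # peaks 1 and 3
  me3 <- gr("chr1", c(3001, 5001), c(4000, 6000))   # peaks 2 and 3
  sc <- array(0.5, dim = c(3, 9, 3),
              dimnames = list(NULL, ctx, c("enhancer", "silencer", "control")))
  # peak 1: enhancer FPR 0.001-ish via the floor; set score above max
  sc[1, , "enhancer"] <- 1
  sc[2, , "silencer"] <- 1
  ri <- regulatory_impact(peaks, sc, curves, ac, me3)
  floor_ri <- -log10(1 / 101)
  expect_equal(unname(ri[1, "tissue"]), floor_ri)      # I_E only: positive
  expect_equal(unname(ri[2, "tissue"]), -floor_ri)     # I_S only: negative
  # peak 3: both marks with equal FPRs cancel exactly
  expect_equal(unname(ri[3, "tissue"]), 0)
  # no mark -> zero regardless of scores
  ri0 <- regulatory_impact(peaks[1], sc[1, , , drop = FALSE], curves,
                           GenomicRanges::GRanges(), GenomicRanges::GRanges())
  expect_equal(unname(ri0[1, ]), rep(0, 9))
  # literal orientation is the exact negation
  rl <- regulatory_impact(peaks, sc, curves, ac, me3, literal_sign = TRUE)
  expect_equal(rl, -ri)
})

test_that("gene domains are the TSS window plus introns, clipped at 1", {
  gm <- read_gene_models(tiny_gtf())
  # g1: [1001,2000], exons merged to [1001,1150] and [1901,2000];
  # one intron [1151,1900]; TSS 1001 with flank 100 gives a window
  # [901,1100] disjoint from the intron
  dom <- gene_domains(gm, "g1", flank = 100)
  expect_equal(GenomicRanges::start(dom), c(901, 1151))
  expect_equal(GenomicRanges::end(dom), c(1100, 1900))
  # a wider flank merges window and intron into one interval (their union)
  dom300 <- gene_domains(gm, "g1", flank = 300)
  expect_equal(GenomicRanges::start(dom300), 701)
  expect_equal(GenomicRanges::end(dom300), 1900)
  # near the chromosome start the window clips at 1
  dom2 <- gene_domains(gm, "g1", flank = 2000)
  expect_equal(min(GenomicRanges::start(dom2)), 1)
  # intronless gene: TSS window only
  f <- tempfile(fileext = ".gtf")
  a <- 'gene_id "gs";'
  writeLines(c(
    paste("chr9", "t", "gene", 10000, 11000, ".", "+", ".", a, sep = "\t"),
    paste("chr9", "t", "exon", 10000, 11000, ".", "+", ".", a, sep = "\t")
  ), f)
  gm2 <- read_gene_models(f)
  dom3 <- gene_domains(gm2, "gs", flank = 500)
  expect_length(dom3, 1)
  expect_equal(GenomicRanges::width(dom3), 1000)
})

test_that("gene RI aggregation sums domain peaks and normalises columns", {
  gm <- read_gene_models(tiny_gtf())
  ctx <- silens_contexts()
  # two peaks in g1's domain, one in g2's, one shared by neither
  peaks <- gr("chrT", c(500, 1200, 5500, 40000), c(600, 1300, 5600, 40100))
  ri <- matrix(0, 4, 9, dimnames = list(NULL, ctx))
  ri[1, ] <- 2; ri[2, ] <- -1; ri[3, ] <- 4; ri[4, ] <- 100
  raw <- aggregate_gene_ri(gm, peaks, ri, flank = 1000, normalize = FALSE)
  expect_equal(unname(raw["g1", "tissue"]), 1)   # 2 + (-1)
  expect_equal(unname(raw["g2", "tissue"]), 4)
  norm <- aggregate_gene_ri(gm, peaks, ri, flank = 1000)
  expect_equal(max(abs(norm[, "tissue"])), 1)
  # normalisation is idempotent and sign-preserving
  again <- normalize_columns(norm)
  expect_equal(again, norm, ignore_attr = TRUE)
  m <- matrix(c(-4, -2, 0, 1), 2, 2)
  nm <- normalize_columns(m)
  expect_equal(nm[, 1], c(-1, -0.5))
  # a peak inside two genes' domains contributes to both
  gmw <- gm
  both <- aggregate_gene_ri(gm, peaks[2], ri[2, , drop = FALSE],
                            flank = 10000, normalize = FALSE)
  expect_true(all(both[, "tissue"] == -1))
})

test_that("lasso recovery: planted weights, null response and constants", {
  set.seed(19)
  n <- 400
  X <- matrix(rnorm(n * 5), n, 5)
  w_true <- c(0.5, -0.3, 0.2, 0, 0.4)
  y <- as.numeric(X %*% w_true)
  y <- y / max(abs(y))
  w_scaled <- w_true / attr(normalize_columns(matrix(y)), "scale")
  fit <- fit_subtype_model(y, X, l1 = 1e-5, folds = 5, trials = 3, seed = 2)
  # noiseless response with a tiny penalty: near-exact recovery
  expect_lt(max(abs(fit$weights - w_true / max(abs(as.numeric(X %*% w_true))))),
            0.05 * max(abs(w_true)))
  expect_lt(fit$rmse, 0.01)
  # permuted response: RMSE close to sd(y)
  yp <- sample(y)
  null_fit <- fit_subtype_model(yp, X, l1 = 1e-4, folds = 5, trials = 3,
                                seed = 2)
  expect_lt(abs(null_fit$rmse - sd(yp)), 0.2 * sd(yp))
  # constant response: zero weights, intercept at the constant
  yc <- rep(0.7, n)
  cfit <- fit_subtype_model(yc, X, l1 = 1e-4, folds = 5, trials = 2, seed = 1)
  expect_equal(unname(cfit$weights), rep(0, 5))
  expect_equal(cfit$intercept, 0.7, tolerance = 1e-6)
  expect_error(fit_subtype_model(y[1:5], X[1:5, ], folds = 10), "folds")
})

test_that("lasso solution matches the closed-form soft threshold", {
  # orthonormal design: lasso weights are soft-thresholded OLS weights
  set.seed(4)
  n <- 500
  X <- qr.Q(qr(matrix(rnorm(n * 3), n, 3))) * sqrt(n)  # X'X = n I
  w <- c(0.4, -0.00005, 0.25)
  y <- as.numeric(X %*% w)
  l1 <- 1e-4
  fit <- silens:::lasso_fit(X, y, l1)
  soft <- sign(w) * pmax(abs(w) - l1, 0)
  expect_equal(fit$w, soft, tolerance = 1e-6)
})

test_that("model beats the shuffled baseline on signal, matches it on noise", {
  set.seed(99)
  X <- make_ri_features(400, 7, seed = 5)
  sim <- make_subtype_expression(X, c(0.8, -0.6, 0.5, -0.4, 0.3, -0.7, 0.2),
                                 noise_sd = 0.05, seed = 6)
  fit <- fit_subtype_model(sim$y, X, folds = 5, trials = 3, seed = 7)
  base <- shuffled_baseline(sim$y, X, folds = 5, trials = 3, seed = 7)
  expect_lt(fit$rmse, base$rmse)
  expect_gt(cor(fit$weights, sim$weights), 0.95)
  # deterministic under a fixed seed
  base2 <- shuffled_baseline(sim$y, X, folds = 5, trials = 3, seed = 7)
  expect_identical(base$rmse_trials, base2$rmse_trials)
  # pure noise: the two are statistically indistinguishable
  yn <- with(sim, sample(y))
  f0 <- fit_subtype_model(yn, X, folds = 5, trials = 3, seed = 8)
  b0 <- shuffled_baseline(yn, X, folds = 5, trials = 3, seed = 8)
  expect_lt(abs(f0$rmse - b0$rmse) / b0$rmse, 0.15)
})
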