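test_that("FPR curve matches direct counting, is monotone and floored", {
  ctrl <- seq(0.1, 1, by = 0.1)
  ctrl <- rep(ctrl, 10)  # 100 scores
  curve <- fit_fpr(ctrl)
  # direct count: fraction of controls >= 0.55 is 50/100
  expect_equal(fpr_at(curve, 0.55), 0.5)
  expect_equal(fpr_at(curve, -1), 1)               # below the minimum
  expect_equal(fpr_at(curve, 2), 1 / 101)          # above the maximum: floor
  # ties: fraction >= 0.5 includes the 0.5 scores themselves
  expect_equal(fpr_at(curve, 0.5), 0.6)
  expect_error(fit_fpr(runif(50)), ">= 100")

  set.seed(21)
  for (rep in 1:5) {
    sc <- rnorm(200)
    cv <- fit_fpr(sc)
    xs <- sort(runif(50, -3, 3))
    fx <- fpr_at(cv, xs)
    expect_true(all(diff(fx) <= 1e-12))            # non-increasing
    expect_true(all(fx >= cv$floor))
    # agreement with the literal definition
    expect_equal(fx, pmax(vapply(xs, function(s) mean(sc >= s), 0), cv$floor))
  }
})

test_that("threshold_at returns the smallest score reaching the target FPR", {
  set.seed(3)
  ctrl <- runif(100)
  curve <- fit_fpr(ctrl)
  thr <- threshold_at(curve, 0.05)
  expect_true(fpr_at(curve, thr) <= 0.05)
  # one step below the threshold the FPR exceeds the target
  below <- max(ctrl[ctrl < thr])
  expect_gt(fpr_at(curve, below), 0.05)
  # near the 95th percentile of the controls
  expect_lt(abs(thr - quantile(ctrl, 0.95)), 0.05)
  expect_equal(threshold_at(curve, 1), min(ctrl))  # target 1: minimum score
  expect_error(threshold_at(curve, 1e-6), "floor")
})

make_scores <- function(enh = 0.1, sil = 0.1) {
  m <- matrix(0, 9, 3, dimnames = list(silens_contexts(),
                                       c("enhancer", "silencer", "control")))
  m[, "enhancer"] <- enh
  m[, "silencer"] <- sil
  m[, "control"] <- 1 - enh - sil
  m
}

test_that("three-branch variant classification follows peak membership", {
  v <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, width = 1))
  thr <- list(c_e = rep(0.5, 9), c_s = rep(0.5, 9))
  me3 <- gr("chr1", 4800, 5200)
  ac <- gr("chr1", 4800, 5200)
  dnase <- gr("chr1", 4800, 5200)
  none <- GenomicRanges::GRanges()

  # branch 1: me3 membership + one context above c_s
  sc <- make_scores(sil = 0.1)
  sc["microglia", "silencer"] <- 0.9
  cl <- classify_variant(v, list(me3 = me3, ac = none, dnase = none), sc, thr)
  expect_equal(cl$call, "silencer_variant")
  expect_equal(cl$contexts, "microglia")
  expect_equal(cl$membership, "in_me3")

  # branch 2: ac membership + enhancer score above threshold
  sc <- make_scores(enh = 0.8)
  cl <- classify_variant(v, list(me3 = none, ac = ac, dnase = none), sc, thr)
  expect_equal(cl$call, "enhancer_variant")

  # branch 3: DNase only, silencer hit in one context requires enhancer
  # below threshold everywhere
  sc <- make_scores()
  sc["tissue", "silencer"] <- 0.9
  cl <- classify_variant(v, list(me3 = none, ac = none, dnase = dnase), sc, thr)
  expect_equal(cl$call, "silencer_variant")
  sc["astrocyte", "enhancer"] <- 0.9   # conflicting enhancer evidence
  cl <- classify_variant(v, list(me3 = none, ac = none, dnase = dnase), sc, thr)
  expect_equal(cl$call, "unclassified")

  # no membership: unclassified regardless of scores
  cl <- classify_variant(v, list(me3 = none, ac = none, dnase = none),
                         make_scores(enh = 0.99), thr)
  expect_equal(cl$call, "unclassified")
  expect_equal(cl$membership, "none")

  # exceeding is strict: scores exactly at the threshold do not trigger
  sc <- make_scores(sil = 0.5)
  cl <- classify_variant(v, list(me3 = me3, ac = none, dnase = none), sc, thr)
  expect_equal(cl$call, "unclassified")
})

fake_curves <- function(n = 200, seed = 9) {
  set.seed(seed)
  ctx <- silens_contexts()
  out <- lapply(ctx, function(cx) {
    list(enhancer = fit_fpr(runif(n)), silencer = fit_fpr(runif(n)))
  })
  names(out) <- ctx
  out
}

test_that("delta-activity identity, antisymmetry and orientation", {
  curves <- fake_curves()
  a <- make_scores(enh = 0.3, sil = 0.2)
  b <- make_scores(enh = 0.7, sil = 0.2)
  expect_equal(unname(delta_activity(a, a, curves)), rep(0, 9))
  d_ab <- delta_activity(a, b, curves)
  d_ba <- delta_activity(b, a, curves)
  expect_equal(d_ab, -d_ba)
  # alt with stronger enhancer score: positive delta
  expect_true(all(d_ab > 0))
  # alt with stronger silencer score: negative delta
  d_sil <- delta_activity(make_scores(sil = 0.2), make_scores(sil = 0.8),
                          curves)
  expect_true(all(d_sil < 0))
  # the literal-orientation flag negates exactly
  expect_equal(delta_activity(a, b, curves, literal_sign = TRUE), -d_ab)
  expect_true(all(is.finite(delta_activity(make_scores(enh = 1e-9),
                                           make_scores(enh = 1 - 1e-9),
                                           curves))))
})

test_that("delta-activity reproduces the closed form on a known curve", {
  # control scores on a uniform grid: FPR steps are exact fractions
  ctrl <- (1:100) / 101
  ctx <- silens_contexts()
  curves <- lapply(ctx, function(cx) {
    list(enhancer = fit_fpr(ctrl), silencer = fit_fpr(ctrl))
  })
  names(curves) <- ctx
  # ref enhancer score with FPR 0.5, alt with FPR 0.05; silencer unchanged
  ref <- make_scores(enh = ctrl[51], sil = 0.5)
  alt <- make_scores(enh = ctrl[96], sil = 0.5)
  d <- delta_activity(ref, alt, curves)
  expect_equal(unname(d["tissue"]), log10(0.5) - log10(0.05), tolerance = 1e-12)
})

test_that("significance calls match a quantile oracle", {
  set.seed(5)
  bg <- rnorm(10000)
  q05 <- quantile(bg, 0.05)
  q95 <- quantile(bg, 0.95)
  x <- c(3, -3, 0, max(bg), median(bg), q95 + 1e-9, q05 - 1e-9)
  got <- call_significance(x, bg)
  expect_equal(unname(got), c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE))
  expect_error(call_significance(1, rnorm(10)), ">= 100")
})

test_that("directional concordance counts sign agreement, excluding zeros", {
  expect_equal(directional_concordance(c(1, -2, 3), c(2, -1, 9))$dcr, 1)
  expect_equal(directional_concordance(c(1, -2, 3), -c(2, -1, 9))$dcr, 0)
  dc <- directional_concordance(c(1, 0, -1, 2), c(1, 5, 2, 0))
  expect_equal(dc$n_used, 2)
  expect_equal(dc$n_zero, 2)
  expect_equal(dc$dcr, 0.5)
  expect_error(directional_concordance(c(0, 0), c(1, 1)), "nonzero")
  # random signs concord at one half
  set.seed(8)
  a <- sample(c(-1, 1), 10000, TRUE)
  b <- sample(c(-1, 1), 10000, TRUE)
  expect_lt(abs(directional_concordance(a, b)$dcr - 0.5), 0.02)
})
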