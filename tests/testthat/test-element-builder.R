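# A hand-written peak scenario covering every element-construction branch;
# expected windows traced by hand from the overlap rules.
builder_fixture <- function() {
  list(
    # 1. enhancer: DNase [10001,10400] + ac inside, no me3
    # 2. both-marks: DNase with ac AND me3 in central 400 -> neither class
    # 3. dnase-silencer: DNase + me3 overlap, no ac in central 400
    # 4. DNase alone: no class
    # 5. enhancer with ac overlap at the peak edge but me3 far away
    # 6. near-promoter enhancer: window overlaps a promoter -> removed
    # 7. edge enhancer: 1-kb window crosses the chromosome start -> dropped
    dnase = gr("chrE", c(10001, 20001, 30001, 40001, 50001, 60001, 101),
               c(10400, 20400, 30400, 40400, 50800, 60400, 500)),
    ac = gr("chrE", c(10101, 20101, 50751, 60101, 181),
            c(10300, 20300, 51200, 60300, 520)),
    me3 = gr("chrE",
             c(20150, 30101, 70001, 80001),
             c(20250, 30300, 70400, 80400)),
    # me3 peak 3 (isolated): silencer; me3 peak 4 overlaps ac -> not isolated
    ac_extra = gr("chrE", 80101, 80200)
  )
}

test_that("call_candidates enumerates exactly the hand-traced element set", {
  fx <- builder_fixture()
  ac_all <- c(fx$ac, fx$ac_extra)
  seqlen <- c(chrE = 100000L)
  out <- call_candidates(fx$dnase, ac_all, fx$me3, genes = NULL,
                         sample_id = "s1", seqlengths = seqlen)
  df <- data.frame(start = GenomicRanges::start(out),
                   klass = S4Vectors::mcols(out)$klass)
  df <- df[order(df$start), ]
  # enhancer windows: DNase midpoints 10200, 50400(peak [50001,50800]),
  # 60200, and edge peak [101,500] midpoint 300 dropped at the edge;
  # silencers: dnase+me3 at 30200, isolated me3 at 70200
  expect_equal(df$start, c(10200, 30200, 50400, 60200, 70200) - 500 + 1)
  expect_equal(df$klass,
               c("enhancer", "silencer", "enhancer", "enhancer", "silencer"))
  expect_true(all(GenomicRanges::width(out) == 1000))
})

test_that("a DNase peak carrying both marks in its centre joins neither class", {
  fx <- builder_fixture()
  out <- call_candidates(fx$dnase[2], fx$ac, fx$me3[1], genes = NULL,
                         sample_id = "s1")
  expect_length(out, 0)
})

test_that("isolated H3K27me3 peaks become silencers; mark-overlapped ones do not", {
  fx <- builder_fixture()
  out <- call_candidates(GenomicRanges::GRanges(), c(fx$ac, fx$ac_extra),
                         fx$me3[3:4], genes = NULL, sample_id = "s1")
  expect_length(out, 1)
  expect_equal(S4Vectors::mcols(out)$klass, "silencer")
  expect_equal(GenomicRanges::start(out), 70200 - 499)
})

test_that("promoter and exon windows are excluded", {
  gm <- read_gene_models(tiny_gtf())
  # enhancer whose 1-kb window [1501,2500] overlaps g1's promoter/exons
  dnase <- gr("chrT", c(1801, 30001), c(2200, 30400))
  ac <- gr("chrT", c(1801, 30001), c(2200, 30400))
  out <- call_candidates(dnase, ac, GenomicRanges::GRanges(), genes = gm,
                         sample_id = "s1")
  expect_length(out, 1)
  expect_equal(GenomicRanges::start(out), 30200 - 499)
})

test_that("deduplication keeps exactly one element per >600 bp chain and is seeded", {
  # windows offset by 300 bp (overlap 700): one survives;
  # offset 400 (overlap exactly 600): both survive
  st <- c(1001, 1301, 5001, 5401)
  w <- gr("chr1", st, st + 999, klass = rep("enhancer", 4))
  kept <- deduplicate_elements(w, seed = 3)
  starts <- sort(GenomicRanges::start(kept))
  expect_length(kept, 3)
  expect_true(sum(starts %in% c(1001, 1301)) == 1)
  expect_true(all(c(5001, 5401) %in% starts))
  # determinism
  kept2 <- deduplicate_elements(w, seed = 3)
  expect_identical(GenomicRanges::start(kept), GenomicRanges::start(kept2))
  # chained group A~B~C: exactly one survivor
  cst <- c(1, 301, 601)
  chain <- gr("chr2", cst, cst + 999)
  for (s in 1:5) {
    k <- deduplicate_elements(chain, seed = s)
    ov <- overlap_pairs(k, k, min_bp = 601)
    expect_true(all(ov$query == ov$subject))  # no >600 bp pair remains
  }
})

test_that("context labels follow binary accessibility overlap", {
  est <- c(1001, 3001, 5001)
  el <- gr("chr1", est, est + 999,
           klass = c("enhancer", "silencer", "control"))
  cells <- silens_contexts()[-1]
  atac <- setNames(rep(list(GenomicRanges::GRanges()), 8), cells)
  atac$microglia <- gr("chr1", 1500, 1600)          # overlaps el 1 only
  atac$astrocyte <- gr("chr1", c(1, 3001, 5001), c(9000, 3100, 5100))
  out <- label_contexts(el, atac)
  m <- S4Vectors::mcols(out)
  expect_equal(m$label_tissue, c("enhancer", "silencer", "control"))
  expect_equal(m$label_microglia, c("enhancer", "control", "control"))
  expect_equal(m$label_astrocyte, c("enhancer", "silencer", "control"))
  # control elements are control in all contexts even when accessible
  expect_true(all(silens:::context_label_matrix(out)[3, ] == "control"))
  # a silencer with no accessibility peak: silencer in the tissue only
  lab2 <- silens:::context_label_matrix(out)[2, ]
  expect_equal(unname(lab2[c("tissue", "astrocyte")]),
               c("silencer", "silencer"))
  expect_true(all(lab2[setdiff(names(lab2), c("tissue", "astrocyte"))] ==
                    "control"))
})

test_that("control sampling excludes overlaps, errors on exhaustion, is seeded", {
  pst <- seq(1001, 99001, by = 2000)
  pool <- gr("chr1", pst, pst + 399)
  excl <- gr("chr1", 1, 50000)
  ctrl <- sample_controls(pool, list(excl), n_controls = 10, seed = 5)
  expect_length(ctrl, 10)
  expect_true(all(GenomicRanges::width(ctrl) == 1000))
  expect_equal(nrow(overlap_pairs(ctrl, excl)), 0)
  ctrl2 <- sample_controls(pool, list(excl), n_controls = 10, seed = 5)
  expect_identical(GenomicRanges::start(ctrl), GenomicRanges::start(ctrl2))
  expect_error(sample_controls(pool, list(gr("chr1", 1, 1e6)), 5, seed = 1),
               "exhausted")
})

test_that("holdout split partitions by chromosome", {
  el <- gr(c("chr1", "chr7", "chr8", "chr2"), rep(5001, 4), rep(6000, 4),
           klass = rep("enhancer", 4))
  sp <- split_holdout(el)
  expect_length(sp$train, 2)
  expect_length(sp$test, 2)
  expect_false(any(as.character(GenomicRanges::seqnames(sp$train)) %in%
                     c("chr7", "chr8")))
  expect_equal(length(sp$train) + length(sp$test), length(el))
  expect_warning(split_holdout(el[1]), "empty")
})
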