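test_that("peak calling finds the taller bump first and ignores flat tracks", {
  flat <- toy_track(rep(3, 200), resolution = 25)
  expect_equal(nrow(call_top_peaks(flat)), 0)

  v <- numeric(400)
  v[100:108] <- c(2, 4, 6, 8, 10, 8, 6, 4, 2)   # height 10
  v[300:308] <- c(1, 2, 3, 4, 5, 4, 3, 2, 1)    # height 5
  tr <- toy_track(v, resolution = 25)
  top1 <- call_top_peaks(tr, n = 1)
  expect_equal(nrow(top1), 1)
  # the peak interval covers the taller bump's apex at bin 104
  expect_true(top1$start <= 103 * 25 && top1$end >= 104 * 25)
  both <- call_top_peaks(tr, n = 10)
  expect_lte(nrow(both), 10)
  expect_true(all(diff(both$score) <= 0))
  expect_error(call_top_peaks(tr, n = 0), "positive")
})

test_that("peak ranking is invariant to positive rescaling of the track", {
  set.seed(9)
  v <- rpois(2000, 2) + runif(2000)   # continuous: no plateau ties
  v[500:520] <- v[500:520] + 40
  v[1500:1510] <- v[1500:1510] + 25
  tr <- toy_track(v, resolution = 25)
  p1 <- call_top_peaks(tr, n = 20)
  p2 <- call_top_peaks(toy_track(512 * v, resolution = 25), n = 20)
  expect_equal(p1[, c("rank", "chrom", "start", "end")],
               p2[, c("rank", "chrom", "start", "end")])
})

test_that("origin-overlap saturation counts percent per 100-peak block", {
  # 200 peaks alternating on/off origins by rank: both blocks 50%
  peaks <- data.frame(rank = 1:200, chrom = "chrA",
                      start = seq(0, by = 2000, length.out = 200))
  peaks$end <- peaks$start + 500
  class(peaks) <- c("peak_set", "data.frame")
  on <- seq(1, 200, by = 2)
  origins <- do.call(rbind, lapply(on, function(i)
    toy_locus(paste0("o", i), "chrA", peaks$start[i], peaks$end[i],
              orc = peaks$start[i] + 10)))
  sat <- peak_origin_saturation(peaks, origins, bin_peaks = 100)
  expect_equal(sat$percent_overlapping, c(50, 50))
  expect_equal(sat$n_peaks, c(100, 100))
})

test_that("set overlap percentage uses the smaller set as denominator", {
  a <- paste0("ars", 1:338)
  b <- paste0("ars", c(1:330, 400:409))
  st <- set_overlap_stats(a, b)
  expect_equal(st$n_common, 330)
  expect_equal(st$percent, 100 * 330 / 338)
  expect_equal(set_overlap_stats(a, a)$percent, 100)
  # random small sets vs brute-force membership count
  set.seed(10)
  x <- sample(letters, 12); y <- sample(letters, 15)
  expect_equal(set_overlap_stats(x, y)$n_common, sum(x %in% y))
  expect_error(set_overlap_stats(character(), a), "empty")
})

test_that("rescue fraction is counted against the proficient core", {
  wt <- paste0("a", 1:330); sir2 <- paste0("a", 1:330)
  rescued <- paste0("a", 1:272)
  rf <- rescue_fraction(rescued, wt, sir2)
  expect_equal(rf$core, 330)
  expect_equal(rf$percent, 100 * 272 / 330)
  expect_equal(rescue_fraction(character(), wt, sir2)$percent, 0)
  expect_error(rescue_fraction(rescued, "x", "y"), "core")
})

test_that("signal areas sum bins over reused windows", {
  zero <- toy_track(rep(0, 100), resolution = 25)
  expect_equal(origin_signal(zero, "chrA", 0, 500), 0)
  uni <- toy_track(rep(2, 100), resolution = 25)
  expect_equal(origin_signal(uni, "chrA", 1000, 1500), 2 * 20)
  set.seed(12)
  v <- rpois(100, 4)
  tr <- toy_track(as.numeric(v), resolution = 25)
  expect_equal(origin_signal(tr, "chrA", 250, 750), sum(v[11:30]))
  expect_error(origin_signal(tr, "chrA", 2000, 3000), "outside")
})

test_that("responsiveness quintiles are balanced, labelled, and order-invariant", {
  sig <- data.frame(id = sprintf("o%02d", 1:10), wt = 5, sir2d = 10,
                    cdc64 = 0.1, cdc64_sir2d = 1:10)
  rt <- responsiveness_table(sig)
  expect_equal(rt$ratio, seq(1, 0.1, by = -0.1))
  expect_equal(as.vector(table(rt$quintile)), rep(2, 5))
  expect_equal(rt$quintile[rt$rank <= 2], c(5, 5))
  expect_equal(rt$group[rt$rank <= 2], c("high", "high"))
  expect_equal(rt$group[rt$rank >= 9], c("low", "low"))
  # permuting the input does not change any origin's quintile
  perm <- responsiveness_table(sig[sample(10), ])
  expect_equal(perm[order(perm$id), ], rt[order(rt$id), ],
               ignore_attr = TRUE)
  # equal signals give ratio 1; zero numerator gives 0
  eq <- responsiveness_table(data.frame(id = c("a", "b"), wt = 1,
                                        sir2d = c(4, 4),
                                        cdc64 = 0, cdc64_sir2d = c(4, 0)))
  expect_equal(eq$ratio[eq$id == "a"], 1.0)
  expect_equal(eq$ratio[eq$id == "b"], 0)
  # non-positive denominators are excluded, all-zero errors
  part <- responsiveness_table(data.frame(id = c("a", "b"), wt = 1,
                                          sir2d = c(2, 0), cdc64 = 0,
                                          cdc64_sir2d = 1))
  expect_equal(attr(part, "excluded"), "b")
  expect_error(responsiveness_table(
    data.frame(id = "a", wt = 1, sir2d = 0, cdc64 = 0, cdc64_sir2d = 1)),
    "non-positive")
})

test_that("rescued-fraction estimate recovers the planted rescue probability", {
  cfg <- desk_sim_config(seed = 2)
  sim <- simulate_dataset(cfg, samples = c("mcm_wt", "mcm_sir2d",
                                           "mcm_cdc64", "mcm_cdc64_sir2d"))
  loci <- apply_heterochromatin_filter(sim$loci, sim$layout)
  origins <- loci[loci$locus_class == "origin", ]
  genos <- c("wt", "sir2d", "cdc64", "cdc64_sir2d")
  tracks <- lapply(genos, function(g)
    bin_track(sim_coverage(sim, paste0("mcm_", g)), 25))
  names(tracks) <- genos
  tracks <- lapply(tracks, function(t) scale_to_reference(t, tracks$cdc64))
  windows <- define_origin_windows(call_top_peaks(tracks$wt), origins,
                                   sim$layout)
  est <- estimate_rescued_fraction(tracks, windows)
  planted <- mean(sim$truth$rescued[sim$truth$id %in% origins$id])
  expect_lt(abs(est$fraction - planted),
            3 * sqrt(planted * (1 - planted) / est$n) + 0.02)
})
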