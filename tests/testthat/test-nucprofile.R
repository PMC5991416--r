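test_that("nucleosome slots fill nearest-first on each side of the ORC site", {
  layout <- toy_layout(c(chrA = 10000))
  frag <- orient_fragment(toy_locus(orc = 5000, start = 4000, end = 6000),
                          layout)
  dy <- 5000 + c(-420, -250, -90, 95, 260, 430)
  got <- assign_nucleosomes(frag, data.frame(chrom = "chrA", dyad = dy))
  expect_equal(unname(got[c("-1", "-2", "-3")]), 5000 + c(-90, -250, -420))
  expect_equal(unname(got[c("+1", "+2", "+3")]), 5000 + c(95, 260, 430))

  # one upstream dyad only: -1 filled, -2/-3 missing
  part <- assign_nucleosomes(frag, data.frame(chrom = "chrA",
                                              dyad = c(4900, 5100, 5300)))
  expect_equal(unname(part["-1"]), 4900)
  expect_true(all(is.na(part[c("-2", "-3")])))

  # minus strand flips sides
  fr_m <- orient_fragment(toy_locus(orc = 5000, start = 4000, end = 6000,
                                    strand = "-"), layout)
  got_m <- assign_nucleosomes(fr_m, data.frame(chrom = "chrA", dyad = dy))
  expect_equal(unname(got_m["+1"]), 5000 - 90)
  expect_equal(unname(got_m["-1"]), 5000 + 95)

  # 20 random dyads vs sort-by-|offset| per side
  set.seed(13)
  rdy <- sample(4400:5600, 20)
  got_r <- assign_nucleosomes(frag, data.frame(chrom = "chrA", dyad = rdy))
  off <- rdy - 5000
  neg <- sort(off[off < 0], decreasing = TRUE)
  pos <- sort(off[off > 0])
  expect_equal(unname(got_r[c("-1", "-2", "-3")]), 5000 + neg[1:3])
  expect_equal(unname(got_r[c("+1", "+2", "+3")]), 5000 + pos[1:3])
})

test_that("mark ratios divide window sums and tolerate empty denominators", {
  same <- toy_track(rep(4, 1000))
  expect_equal(nucleosome_mark_ratio(same, same, "chrA", 500), 1.0)
  expect_equal(nucleosome_mark_ratio(toy_track(rep(3, 1000)),
                                     toy_track(rep(6, 1000)), "chrA", 500),
               0.5)
  set.seed(14)
  m <- toy_track(as.numeric(rpois(1000, 5)))
  d <- toy_track(as.numeric(rpois(1000, 5)))
  expect_equal(nucleosome_mark_ratio(m, d, "chrA", 321),
               sum(m$values$chrA[(321 - 73 + 1):(321 + 74)]) /
                 sum(d$values$chrA[(321 - 73 + 1):(321 + 74)]))
  zero <- toy_track(rep(0, 1000))
  expect_true(is.na(nucleosome_mark_ratio(m, zero, "chrA", 500)))
  # window leaving the chromosome is missing, not an error
  expect_true(is.na(nucleosome_mark_ratio(m, d, "chrA", 30)))
})

test_that("control baseline is the mean of per-locus nucleosome means", {
  layout <- toy_layout(c(chrA = 5000))
  controls <- rbind(toy_locus("c1", start = 500, end = 1701,
                              class = "intergenic_control"),
                    toy_locus("c2", start = 3000, end = 4201,
                              class = "intergenic_control"))
  dyads <- data.frame(chrom = "chrA",
                      dyad = c(seq(650, 1500, by = 165),
                               seq(3150, 4000, by = 165)))
  # mark/denom ratio is 1 inside c1 and 3 inside c2
  mv <- rep(2, 5000); mv[3001:4201] <- 6
  mark <- toy_track(mv); denom <- toy_track(rep(2, 5000))
  b <- control_baseline(controls, dyads, mark, denom)
  expect_equal(as.numeric(b), mean(c(1, 3)))
  pool <- attr(b, "pool")
  expect_equal(sort(unique(pool)), c(1, 3))
  expect_lte(length(pool), 12)
  expect_error(control_baseline(controls, dyads, mark, toy_track(rep(0, 5000))),
               "control")
})

test_that("profiles log2-normalise to the baseline and drop non-positive entries", {
  m <- matrix(c(2, 1, 0, NA), 2, 2,
              dimnames = list(c("a", "b"), c("-1", "+1")))
  norm <- normalize_profile(m, baseline = 2)
  expect_equal(norm["a", "-1"], 0)
  expect_equal(norm["b", "-1"], -1)
  expect_true(is.na(norm["a", "+1"]))
  expect_true(is.na(norm["b", "+1"]))
  expect_error(normalize_profile(m, 0), "positive")
})

test_that("group t-statistics match the pooled-variance closed form", {
  mat <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(letters[1:4], "+1"))
  gp <- group_profile(mat, letters[1:4], control_pool = c(3, 4, 5, 6))
  expect_equal(gp$t, -2.1909, tolerance = 1e-4)
  expect_equal(gp$df, 6)
  expect_equal(gp$p, 2 * pt(-2.190890, 6), tolerance = 1e-6)
  expect_equal(gp$se, sd(1:4) / 2)

  # identical group and control values: t = 0, p = 1
  same <- group_profile(mat, letters[1:4], control_pool = c(1, 2, 3, 4))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # degenerate zero-variance cases
  const <- matrix(rep(2, 3), 3, 1, dimnames = list(letters[1:3], "+1"))
  eqm <- group_profile(const, letters[1:3], control_pool = rep(2, 5))
  expect_equal(eqm$p, 1)
  neqm <- group_profile(const, letters[1:3], control_pool = rep(7, 5))
  expect_equal(neqm$p, 0)
  expect_true(neqm$degenerate)
})

test_that("group p-values fall monotonically with planted effect size", {
  set.seed(15)
  control <- rnorm(60, 0, 0.3)
  noise <- rnorm(30, 0, 0.3)
  ps <- vapply(c(0.1, 0.25, 0.5), function(effect) {
    mat <- matrix(noise - effect, 30, 1,
                  dimnames = list(paste0("l", 1:30), "+1"))
    group_profile(mat, paste0("l", 1:30), control)$p
  }, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("box-whisker summaries use type-7 quartiles and 1.5 IQR whiskers", {
  m <- matrix(1:9, 9, 1, dimnames = list(paste0("l", 1:9), "+1"))
  groups <- setNames(rep("g", 9), paste0("l", 1:9))
  bx <- boxplot_summary(m, groups)
  expect_equal(bx$median, 5)
  expect_equal(bx$q1, 3)
  expect_equal(bx$q3, 7)
  expect_equal(bx$whisker_lo, 1)
  expect_equal(bx$whisker_hi, 9)
  cm <- matrix(rep(2.5, 4), 4, 1, dimnames = list(paste0("l", 1:4), "+1"))
  cb <- boxplot_summary(cm, setNames(rep("g", 4), paste0("l", 1:4)))
  expect_equal(cb$median, 2.5)
  expect_equal(cb$q3 - cb$q1, 0)
})

test_that("mark identical to denominator gives all-zero profiles and null tests", {
  layout <- toy_layout(c(chrA = 60000))
  loci <- rbind(
    do.call(rbind, lapply(1:12, function(i)
      toy_locus(paste0("o", i), start = i * 4000, end = i * 4000 + 1201,
                orc = i * 4000 + 600))),
    do.call(rbind, lapply(1:12, function(i)
      toy_locus(paste0("c", i), start = i * 4000 + 2000,
                end = i * 4000 + 3201, class = "intergenic_control"))))
  dyads <- data.frame(chrom = "chrA", dyad = seq(100, 59900, by = 165))
  tr <- toy_track(rep(4, 60000))
  prof <- build_nuc_profile(loci, dyads, tr, tr, layout)
  expect_true(all(prof$normalized[!is.na(prof$normalized)] == 0))
  gp <- group_profile(prof$normalized, paste0("o", 1:12), prof$control_pool)
  expect_true(all(gp$p[!is.na(gp$p)] >= 0.99))
})
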