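test_that("loci files round-trip through BED6+3 with all fields preserved", {
  layout <- toy_layout(c(chrII = 20000))
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrII\t9950\t11150\tARS_toy\t0\t+\torigin\t10500\t+", path)
  loci <- load_loci(path, layout)
  expect_equal(loci$orc_start, 10500)
  expect_equal(loci$locus_class, "origin")
  expect_equal(loci$t_rich_strand, "+")

  three <- rbind(
    toy_locus("a", "chrII", 100, 1400, "origin", 700, "+"),
    toy_locus("b", "chrII", 2000, 3300, "nonorigin_orc", 2600, "-"),
    toy_locus("c", "chrII", 5000, 6300, "intergenic_control"))
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_loci(three, p2)
  back <- load_loci(p2, layout)
  expect_equal(back, three)
})

test_that("malformed locus rows are rejected with their row number", {
  layout <- toy_layout(c(chrA = 1000))
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrA\t10\t500\tok\t0\t+\torigin\t100\t+",
               "chrA\t600\t600\tbad\t0\t+\torigin\t600\t+"), path)
  expect_error(load_loci(path, layout), "row 2")
  writeLines("chrZ\t10\t500\tx\t0\t+\torigin\t100\t+", path)
  expect_error(load_loci(path, layout), "unknown chromosome")
  writeLines("chrA\t10\t500\tx\t0\t+\tweird_class\t100\t+", path)
  expect_error(load_loci(path, layout), "unknown locus class")
  # control loci must not carry ORC fields and vice versa
  writeLines("chrA\t10\t500\tx\t0\t+\tintergenic_control\t100\t+", path)
  expect_error(load_loci(path, layout), "row 1")
  writeLines("chrA\t10\t500\tx\t0\t.\torigin\t.\t.", path)
  expect_error(load_loci(path, layout), "row 1")
})

test_that("heterochromatin/telomere filter matches a brute-force check and is idempotent", {
  layout <- toy_layout(c(chrA = 300000),
                       het = data.frame(chrom = "chrA",
                                        start = c(100000, 200000),
                                        end = c(110000, 201000)))
  # locus within 15 kb of a chromosome end is telomeric
  telo <- toy_locus("t", "chrA", 5000, 6200, orc = 5600)
  out <- apply_heterochromatin_filter(telo, layout)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "removed")$reason, "telomeric")

  # vacuous filter: no masks, no telomere exclusion
  free <- toy_locus("f", "chrA", 5000, 6200, orc = 5600)
  nolayout <- toy_layout(c(chrA = 300000))
  kept <- apply_heterochromatin_filter(free, nolayout, telomere_bp = 0)
  expect_equal(kept$id, "f")

  # 10 loci vs 2 masks: survivors equal exhaustive per-locus overlap check
  set.seed(11)
  starts <- sort(sample(seq(16000, 280000, by = 2000), 10))
  loci <- do.call(rbind, lapply(seq_along(starts), function(i)
    toy_locus(paste0("L", i), "chrA", starts[i], starts[i] + 1201,
              orc = starts[i] + 600)))
  out <- apply_heterochromatin_filter(loci, layout)
  overlaps <- function(s, e, ms, me) s < me && e > ms
  keep_bf <- vapply(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    het_hit <- any(vapply(seq_len(nrow(layout$het_intervals)), function(j)
      overlaps(l$start, l$end, layout$het_intervals$start[j],
               layout$het_intervals$end[j]), TRUE))
    telo <- l$start < 15000 || l$end > 300000 - 15000
    !het_hit && !telo
  }, TRUE)
  expect_equal(out$id, loci$id[keep_bf])

  # idempotence
  twice <- apply_heterochromatin_filter(out, layout)
  expect_equal(twice$id, out$id)
})

test_that("oriented fragments anchor at the ORC site and mirror across strands", {
  layout <- toy_layout(c(chrA = 10000))
  plus <- orient_fragment(toy_locus(orc = 5000, start = 4000, end = 6000,
                                    chrom = "chrA"), layout)
  expect_length(plus$pos, 1201)
  expect_equal(plus$pos[plus$offsets == 0], 5000)
  expect_equal(plus$pos[plus$offsets == 10], 5010)

  minus <- orient_fragment(toy_locus(orc = 5000, start = 4000, end = 6000,
                                     strand = "-"), layout)
  expect_equal(minus$pos[minus$offsets == 10], 4990)
  expect_equal(minus$pos[minus$offsets == -10], 5010)
  # mirror identity: plus(x) + minus(x) = 2 * orc_start at every offset
  expect_equal(plus$pos + minus$pos, rep(2 * 5000, 1201))
})

test_that("fragments crossing a chromosome end error, pad, or drop as requested", {
  layout <- toy_layout(c(chrA = 1000))
  near_end <- toy_locus(orc = 900, start = 850, end = 950)
  expect_error(orient_fragment(near_end, layout), "boundary")
  padded <- orient_fragment(near_end, layout, pad_missing = TRUE)
  expect_true(any(is.na(padded$pos)))
  expect_equal(padded$pos[padded$offsets == 0], 900)

  big <- toy_layout(c(chrA = 10000))
  both <- rbind(toy_locus("edge", orc = 9800, start = 9700, end = 9900),
                toy_locus("ok", orc = 5000, start = 4900, end = 5100))
  frags <- orient_fragments(both, big)
  expect_named(frags, "ok")
  expect_equal(attr(frags, "removed"), "edge")
})

test_that("strand flip oracle: minus-strand mapping equals plus mapping on mirrored coordinates", {
  layout <- toy_layout(c(chrA = 10000))
  orc <- 4321
  minus <- orient_fragment(toy_locus(orc = orc, start = 3000, end = 6000,
                                     strand = "-"), layout)
  # mirror the chromosome around the ORC start and apply the plus rule
  mirrored_plus <- orc - (orc + minus$offsets - orc)
  expect_equal(minus$pos, orc - minus$offsets)
  expect_equal(minus$pos, mirrored_plus)
})
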