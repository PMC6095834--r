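write_bed <- function(lines) {
  f <- tempfile(fileext = ".bed")
  writeLines(lines, f)
  f
}

test_that("BED TSS extraction follows 0-based half-open strand conventions", {
  f <- write_bed(c("chr1\t100\t200\tg1\t0\t+",
                   "chr1\t100\t200\tg2\t0\t-"))
  r <- read_bed_tss(f)
  expect_equal(r$tss, c(100L, 199L))
  expect_equal(r$strand, c("+", "-"))

  # roundtrip through the writer preserves chrom/tss/strand/name
  f2 <- tempfile(fileext = ".bed")
  write_bed_tss(r, f2)
  r2 <- read_bed_tss(f2)
  expect_equal(r2[c("chrom", "tss", "strand", "name")],
               r[c("chrom", "tss", "strand", "name")])
})

test_that("malformed BED lines are rejected with their line number", {
  expect_error(read_bed_tss(write_bed("chr1\t100\t200")), "line 1")
  expect_error(read_bed_tss(write_bed(c("chr1\t100\t200\tg\t0\t+",
                                        "chr1\tx\t200\tg\t0\t+"))),
               "line 2")
  expect_error(read_bed_tss(write_bed("chr1\t100\t200\tg\t0\t*")),
               "strand")
})

test_that("bedGraph tracks read as base-level coverage with implicit zeros", {
  f <- tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t10\t2.5", "chr1\t20\t30\t1.0"), f)
  tr <- read_bedgraph(f)
  expect_s3_class(tr, "signal_track")
  regs <- data.frame(chrom = "chr1", tss = 10L, strand = "+", name = "r1")
  m <- tss_matrix(tr, regs, flank = 10, bin_size = 10)
  # window [0, 20): first bin covers the 2.5 block, second the zero gap
  expect_equal(unname(m[1, ]), c(2.5, 0))
})

test_that("constant tracks give flat profiles with zero standard error", {
  tr <- signal_track("chr1", 0L, 100000L, 3)
  regs <- data.frame(chrom = "chr1",
                     tss = c(20000L, 40000L, 60000L),
                     strand = c("+", "-", "+"),
                     name = paste0("r", 1:3))
  m <- tss_matrix(tr, regs, flank = 3000, bin_size = 50)
  expect_equal(dim(m), c(3L, 120L))
  expect_true(all(m == 3))
  pr <- average_profile(m)
  expect_true(all(pr$mean == 3))
  expect_true(all(pr$stderr == 0))
  # mass conservation: bin means times bin width recover the window total
  expect_equal(sum(m[1, ]) * 50, 3 * 6000)
})

test_that("a one-bin delta lands in the first downstream bin and mirrors on minus strand", {
  tss <- 5000L
  tr <- signal_track("chr1", tss, tss + 50L, 7)   # exactly [tss, tss + bin)
  plus <- data.frame(chrom = "chr1", tss = tss, strand = "+", name = "p")
  minus <- data.frame(chrom = "chr1", tss = tss, strand = "-", name = "m")
  mp <- tss_matrix(tr, plus, flank = 500, bin_size = 50)
  mm <- tss_matrix(tr, minus, flank = 500, bin_size = 50)
  # + strand: bin 11 of 20 covers [tss, tss+50)
  expect_equal(unname(which(mp[1, ] > 0)), 11L)
  expect_equal(unname(mp[1, 11]), 7)
  # - strand: the signal appears in the mirrored bin
  expect_equal(unname(which(mm[1, ] > 0)), 10L)
  expect_equal(unname(mm[1, 10]), 7)
})

test_that("strand mirroring the regions and track leaves the profile unchanged", {
  set.seed(9)
  # random blocky track on a 20 kb chromosome
  starts <- seq(0L, 19950L, by = 50L)
  vals <- round(runif(length(starts), 0, 5), 2)
  tr <- signal_track("chr1", starts, starts + 50L, vals)
  regs <- data.frame(chrom = "chr1",
                     tss = sample(5000:15000, 8),
                     strand = sample(c("+", "-"), 8, replace = TRUE),
                     name = paste0("r", 1:8))
  m1 <- tss_matrix(tr, regs, flank = 1000, bin_size = 50)
  # mirror each region: flip its strand and reflect the track around its
  # TSS; the binned window must be unchanged
  L <- 20000L
  for (i in seq_len(nrow(regs))) {
    # reflect track values around this TSS (position x -> 2*tss - x)
    tssb <- regs$tss[i]
    w <- 1000L
    v <- vapply(0:(2 * w - 1), function(off) {
      pos <- tssb - w + off              # 0-based position in the window
      mirr <- 2L * tssb - pos - 1L       # reflected position
      idx <- mirr %/% 50L + 1L
      if (mirr < 0 || mirr >= L) 0 else vals[idx]
    }, numeric(1))
    flip <- regs[i, , drop = FALSE]
    flip$strand <- ifelse(flip$strand == "+", "-", "+")
    tr_m <- signal_track("chr1", 0:(2 * w - 1) + (tssb - w),
                         1:(2 * w) + (tssb - w), v)
    m2 <- tss_matrix(tr_m, flip, flank = 1000, bin_size = 50)
    expect_equal(unname(m2[1, ]), unname(m1[i, ]))
  }
})

test_that("profiles average per bin with standard errors and recover peaks", {
  # two regions with bin values 0 and 2 -> mean 1, SE 1
  tr <- signal_track("chr1", 1000L, 1100L, 2)
  regs <- data.frame(chrom = "chr1", tss = c(1000L, 5000L),
                     strand = "+", name = c("a", "b"))
  m <- tss_matrix(tr, regs, flank = 100, bin_size = 100)
  pr <- average_profile(m)
  peak <- which(pr$mean > 0)
  expect_equal(pr$mean[peak], 1)
  expect_equal(pr$stderr[peak], 1)
  expect_equal(pr$n_regions, 2L)

  # identical rows have zero SE everywhere
  pr2 <- average_profile(m[c(1, 1), ])
  expect_true(all(pr2$stderr == 0))

  # Gaussian peak + noise at many TSSs: recovered peak within one bin of 0
  set.seed(123)
  n <- 200; flank <- 1000L; bs <- 50L
  spacing <- 4000L
  tsss <- spacing * seq_len(n)
  base <- unlist(lapply(tsss, function(t0) {
    offs <- seq(-flank, flank - bs, by = bs)
    round(50 * exp(-(offs + bs / 2)^2 / (2 * 200^2)) +
            rnbinom(length(offs), mu = 5, size = 2))
  }))
  starts <- unlist(lapply(tsss, function(t0)
    seq(t0 - flank, t0 + flank - bs, by = bs)))
  tr3 <- signal_track("chr1", starts, starts + bs, base)
  regs3 <- data.frame(chrom = "chr1", tss = tsss,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      name = paste0("g", seq_len(n)))
  pr3 <- average_profile(tss_matrix(tr3, regs3, flank = flank, bin_size = bs))
  expect_lte(abs(pr3$offset[which.max(pr3$mean)] + bs / 2), bs)
})

test_that("regions on chromosomes missing from the track are zero with a tally", {
  tr <- signal_track("chr1", 0L, 1000L, 1)
  regs <- data.frame(chrom = c("chr1", "chrUn"), tss = c(500L, 500L),
                     strand = "+", name = c("a", "b"))
  expect_warning(m <- tss_matrix(tr, regs, flank = 100, bin_size = 50),
                 "absent")
  expect_true(all(m[2, ] == 0))
  expect_equal(attr(m, "missing_chrom"), 1L)
  expect_error(tss_matrix(tr, regs, flank = 100, bin_size = 30), "multiple")
})

test_that("profile TSV writer emits offset, mean, stderr and n", {
  tr <- signal_track("chr1", 0L, 10000L, 2)
  regs <- data.frame(chrom = "chr1", tss = 5000L, strand = "+", name = "r")
  pr <- average_profile(tss_matrix(tr, regs, flank = 500, bin_size = 50))
  f <- tempfile(fileext = ".tsv")
  write_profile(pr, f)
  back <- read.delim(f)
  expect_equal(names(back), c("offset", "mean", "stderr", "n"))
  expect_equal(back$mean, pr$mean)
  expect_equal(back$offset, pr$offset)
})
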