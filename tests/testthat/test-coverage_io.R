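test_that("read_coverage_bed parses 4-column BED and validates lines", {
  f <- withr::local_tempfile()
  writeLines("chr1\t0\t10\t5", f)
  tr <- read_coverage_bed(f)
  expect_s3_class(tr, "coverage_track")
  expect_equal(as.data.frame(tr),
               data.frame(chrom = "chr1", start = 0L, end = 10L, value = 5),
               ignore_attr = TRUE)

  writeLines(c("# a comment", "track name=x", "browser position chr1",
               "chr1\t0\t10\t1", "chr1\t10\t20\t2", "chr1\t20\t30\t3"), f)
  tr <- read_coverage_bed(f)
  expect_equal(bin_size(tr), 10L)
  expect_equal(tr$value, c(1, 2, 3))

  writeLines(character(), f)
  expect_equal(nrow(read_coverage_bed(f)), 0L)

  expect_error(read_coverage_bed(file.path(tempdir(), "no-such.bed")),
               "not found")
})

test_that("malformed lines are rejected with their line number", {
  f <- withr::local_tempfile()
  cases <- list(
    c("chr1\t0\t10\t1", "chr1\t10\t20"),          # too few fields
    c("chr1\t0\t10\t1", "chr1\t-5\t20\t1"),       # negative coordinate
    c("chr1\t0\t10\t1", "chr1\t20\t20\t1"),       # end <= start
    c("chr1\t0\t10\t1", "chr1\t10\t20\tabc"),     # non-numeric value
    c("chr1\t0\t10\t1", "chr1\t10\t20\t-3"))      # negative value
  for (lines in cases) {
    writeLines(lines, f)
    expect_error(read_coverage_bed(f), "line 2")
  }
  # overlap is a validation error
  writeLines(c("chr1\t0\t10\t1", "chr1\t5\t15\t1"), f)
  expect_error(read_coverage_bed(f), "overlap")
})

test_that("unsorted input is sorted per chromosome with a notice", {
  f <- withr::local_tempfile()
  writeLines(c("chr2\t10\t20\t2", "chr2\t0\t10\t1", "chr1\t0\t10\t3"), f)
  expect_message(tr <- read_coverage_bed(f), "sort")
  expect_equal(tr$start, c(0L, 10L, 0L))
  # chromosome order of first appearance is preserved, not karyotype-sorted
  expect_equal(chrom_order(tr), c("chr2", "chr1"))
})

test_that("write_bed formats values and round-trips through the reader", {
  f <- withr::local_tempfile()
  tr <- probability_track("chr1", 0L, 10L, 0.39347)
  write_bed(tr, f, precision = 4)
  expect_equal(readLines(f), "chr1\t0\t10\t0.3935")

  write_bed(coverage_track(character(), integer(), integer(), numeric()), f)
  expect_equal(length(readLines(f)), 0L)

  withr::local_seed(11)
  for (i in 1:10) {
    tr <- random_track(sample.int(200, 1L))
    prec <- sample(2:8, 1L)
    write_bed(tr, f, precision = prec)
    back <- read_coverage_bed(f)
    expect_equal(back$value, tr$value, tolerance = 10^(-prec) * 2)
    expect_equal(back[c("chrom", "start", "end")],
                 tr[c("chrom", "start", "end")], ignore_attr = TRUE)
  }
})

test_that("written BED agrees with an independent bedGraph importer", {
  skip_if_not_installed("rtracklayer")
  f <- withr::local_tempfile(fileext = ".bedGraph")
  withr::local_seed(7)
  tr <- random_track(100)
  write_bed(tr, f, precision = 3)
  gr <- rtracklayer::import(f, format = "bedGraph")
  expect_equal(GenomicRanges::start(gr) - 1L, tr$start)
  expect_equal(GenomicRanges::end(gr), tr$end)
  expect_equal(gr$score, round(tr$value, 3))
})

test_that("write_bedgraph emits a header and honours run-length merging", {
  f <- withr::local_tempfile()
  tr <- probability_track(rep("chr1", 4), seq(0L, 30L, 10L), seq(10L, 40L, 10L),
                          c(0.5, 0.5, 0.2, 0.2))
  write_bedgraph(tr, f, track_name = "demo", merge = TRUE)
  lines <- readLines(f)
  expect_equal(lines[1L], "track type=bedGraph name=demo")
  expect_equal(length(lines), 3L)                 # two merged runs
  expect_match(lines[2L], "^chr1\t0\t20\t0.5")

  write_bedgraph(tr, f, merge = FALSE)
  expect_equal(length(readLines(f)), nrow(tr) + 1L)

  # merge never joins across chromosomes or across coordinate gaps
  tr2 <- probability_track(c("chr1", "chr2"), c(0L, 0L), c(10L, 10L),
                           c(0.5, 0.5))
  write_bedgraph(tr2, f, merge = TRUE)
  expect_equal(length(readLines(f)), 3L)
})

test_that("bedGraph run-length merge preserves the bin-expanded values", {
  f <- withr::local_tempfile()
  withr::local_seed(3)
  vals <- sample(c(0, 0.25, 0.5), 60, replace = TRUE)
  tr <- make_track(vals, probability = TRUE)
  write_bedgraph(tr, f, merge = TRUE, precision = 6)
  rec <- read.table(f, skip = 1, sep = "\t",
                    col.names = c("chrom", "start", "end", "value"))
  expanded <- rep(rec$value, (rec$end - rec$start) / bin_size(tr))
  expect_equal(expanded, vals)
})

test_that("rebin averages covered bins and preserves the weighted mean", {
  tr <- make_track(c(2, 4, 6, 8), bin_size = 10L)
  out <- rebin(tr, 20L)
  expect_equal(out$value, c(3, 7))
  expect_equal(out$end, c(20L, 40L))
  expect_identical(rebin(tr, 10L), tr)
  expect_error(rebin(tr, 15L), "multiple")

  withr::local_seed(5)
  vals <- rpois(120, 6)
  tr <- make_track(vals, bin_size = 10L, chrom = rep(c("chrA", "chrB"), 60))
  out <- rebin(tr, 40L)
  expect_equal(sum(out$value * (out$end - out$start)),
               sum(tr$value * (tr$end - tr$start)))
  expect_true(all(out$end - out$start == 40L))
})

test_that("track constructors enforce sortedness, overlap and value range", {
  expect_error(coverage_track("chr1", c(0L, 5L), c(10L, 15L), c(1, 1)),
               "overlap")
  expect_error(coverage_track("chr1", c(10L, 0L), c(20L, 10L), c(1, 1)),
               "sorted")
  expect_error(coverage_track("chr1", 0L, 10L, -1), "negative")
  expect_error(probability_track("chr1", 0L, 10L, 1.5), "> 1")
  expect_error(coverage_track(c("chr1", "chr2", "chr1"),
                              c(0L, 0L, 10L), c(10L, 10L, 20L), c(1, 1, 1)),
               "interleaved")
})
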