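test_that("generated paired FASTQ matches the requested shape and is deterministic", {
  dir <- withr::local_tempdir()
  out <- generate_fastq(100, read_len = 152, paired = TRUE, seed = 1,
                        out_dir = dir, prefix = "s1")
  expect_equal(nrow(out), 2)
  for (p in out$path) {
    lines <- readLines(p)
    expect_length(lines, 400)
    expect_true(all(nchar(lines[seq(2, 400, 4)]) == 152))
    expect_true(all(nchar(lines[seq(4, 400, 4)]) == 152))
    expect_equal(count_fastq_records(p), 100L)
  }
  # mate-consistent identifiers
  id1 <- readLines(out$path[1])[seq(1, 400, 4)]
  id2 <- readLines(out$path[2])[seq(1, 400, 4)]
  expect_equal(sub("/1$", "", id1), sub("/2$", "", id2))
  expect_true(all(grepl("/1$", id1)) && all(grepl("/2$", id2)))

  # same seed -> byte-identical; different seed -> different
  dir2 <- withr::local_tempdir()
  out2 <- generate_fastq(100, 152, TRUE, seed = 1, out_dir = dir2, prefix = "s1")
  expect_identical(readBin(out$path[1], "raw", 1e6),
                   readBin(out2$path[1], "raw", 1e6))
  out3 <- generate_fastq(100, 152, TRUE, seed = 2, out_dir = dir2, prefix = "s3")
  expect_false(identical(readLines(out$path[1])[2], readLines(out3$path[1])[2]))

  empty <- generate_fastq(0, paired = FALSE, out_dir = dir2, prefix = "e")
  expect_equal(count_fastq_records(empty$path), 0L)
})

test_that("chunk plans are balanced with remainders at the front", {
  plan <- chunk_plan(10, 3)
  expect_equal(plan$n_records, c(4L, 3L, 3L))
  expect_equal(plan$last_record, c(4L, 7L, 10L))
  expect_equal(sum(chunk_plan(1000, 7)$n_records), 1000)
  p <- chunk_plan(1000, 7)$n_records
  expect_lte(max(p) - min(p), 1)
  expect_false(is.unsorted(rev(p)))   # earlier chunks never smaller
  expect_error(chunk_plan(2, 3), class = "fastq_split_error")
})

test_that("split chunks concatenate back to the input byte-for-byte", {
  dir <- withr::local_tempdir()
  fq <- generate_fastq(10, 20, paired = FALSE, seed = 5, out_dir = dir,
                       prefix = "ten")$path
  chunks <- split_fastq(fq, 3, file.path(dir, "chunks"))
  expect_equal(chunks$n_records, c(4L, 3L, 3L))
  expect_equal(basename(chunks$path),
               c("ten.chunk1.fastq", "ten.chunk2.fastq", "ten.chunk3.fastq"))
  cat_bytes <- do.call(c, lapply(chunks$path, readBin, "raw", 1e6))
  expect_identical(cat_bytes, readBin(fq, "raw", 1e6))

  single <- split_fastq(fq, 1, file.path(dir, "one"))
  expect_identical(readBin(single$path, "raw", 1e6), readBin(fq, "raw", 1e6))

  # property: random sizes and chunk counts round-trip
  set.seed(8)
  for (i in 1:15) {
    n <- sample(1:50, 1)
    k <- sample(1:n, 1)
    f <- generate_fastq(n, sample(10:40, 1), paired = FALSE, seed = i,
                        out_dir = withr::local_tempdir(), prefix = "p")$path
    ch <- split_fastq(f, k, file.path(dirname(f), "c"))
    expect_identical(do.call(c, lapply(ch$path, readBin, "raw", 1e7)),
                     readBin(f, "raw", 1e7))
    expect_lte(max(ch$n_records) - min(ch$n_records), 1)
  }
})

test_that("paired mates split into identically-sized, range-aligned chunks", {
  dir <- withr::local_tempdir()
  out <- generate_fastq(23, 30, paired = TRUE, seed = 2, out_dir = dir,
                        prefix = "pe")
  c1 <- split_fastq(out$path[1], 4, file.path(dir, "m1"))
  c2 <- split_fastq(out$path[2], 4, file.path(dir, "m2"))
  expect_equal(c1$n_records, c2$n_records)
  # chunk k of each mate holds the same ordinal records
  for (k in 1:4) {
    ids1 <- readLines(c1$path[k])
    ids1 <- sub("/1$", "", ids1[seq(1, length(ids1), 4)])
    ids2 <- readLines(c2$path[k])
    ids2 <- sub("/2$", "", ids2[seq(1, length(ids2), 4)])
    expect_equal(ids1, ids2)
  }
})

test_that("malformed FASTQ is rejected with the offending line number", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "trunc.fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), f1)
  expect_error(split_fastq(f1, 1), class = "fastq_parse_error")

  f2 <- file.path(dir, "badsep.fastq")
  writeLines(c("@r1", "ACGT", "x", "IIII"), f2)
  expect_error(split_fastq(f2, 1), regexp = "line 3",
               class = "fastq_parse_error")

  f3 <- file.path(dir, "badlen.fastq")
  writeLines(c("@r1", "ACGT", "+", "III"), f3)
  expect_error(split_fastq(f3, 1), regexp = "line 4",
               class = "fastq_parse_error")

  f4 <- file.path(dir, "badid.fastq")
  writeLines(c("r1", "ACGT", "+", "IIII"), f4)
  expect_error(split_fastq(f4, 1), regexp = "line 1",
               class = "fastq_parse_error")

  # more chunks than records is refused, not silently padded
  f5 <- generate_fastq(2, 10, paired = FALSE, seed = 1, out_dir = dir,
                       prefix = "tiny")$path
  expect_error(split_fastq(f5, 3), class = "fastq_split_error")
})

test_that("the generator restores the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  generate_fastq(5, 10, paired = FALSE, seed = 9,
                 out_dir = withr::local_tempdir())
  expect_identical(.Random.seed, before)
})
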