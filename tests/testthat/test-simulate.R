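test_that("ideal makespan follows the round structure", {
  expect_equal(ideal_makespan(100000, 1999, 120), 6120)
  expect_equal(ideal_makespan(10000, 1999, 120), 720)
  expect_equal(ideal_makespan(5, 5, 3.5), 3.5)      # one round
  expect_equal(ideal_makespan(0, 4, 10), 0)
  expect_error(ideal_makespan(10, 0, 1), class = "sim_error")
})

test_that("jobs-per-worker bounds are floor/ceiling of n/W", {
  expect_equal(unname(rounds_bounds(10000, 1999)), c(5L, 6L))
  expect_equal(unname(rounds_bounds(6, 3)), c(2L, 2L))
  expect_equal(unname(rounds_bounds(7, 3)), c(2L, 3L))
  # realized counts from greedy dispatch hit exactly those bounds
  set.seed(3)
  for (i in 1:20) {
    n <- sample(1:60, 1); W <- sample(1:8, 1)
    tl <- simulate_schedule(sim_request(n, 1), W)
    counts <- worker_counts(tl)$n_units
    b <- rounds_bounds(n, W)
    expect_equal(min(counts), unname(b["min"]))
    expect_equal(max(counts), unname(b["max"]))
  }
})

test_that("simulated uniform workloads reach the ideal makespan exactly", {
  tl <- simulate_schedule(sim_request(4, 1), n_workers = 2)
  expect_equal(timeline_makespan(tl), 2)
  set.seed(17)
  for (i in 1:200) {
    n <- sample(1:200, 1); W <- sample(1:16, 1)
    d <- sample(c(0.5, 1, 2, 7, 120), 1)
    tl <- simulate_schedule(sim_request(n, d), W, overhead = 0)
    expect_equal(timeline_makespan(tl), ideal_makespan(n, W, d))
  }
})

test_that("dependent requests wait for full predecessor completion", {
  reqs <- list(
    sim_request(2, 5, label = "fastq_splitter"),
    sim_request(12, 3, depends_on = 1, label = "bwa_align")
  )
  tl <- simulate_schedule(reqs, n_workers = 4)
  split_end <- max(tl$t_end[tl$submission == 1])
  expect_true(all(tl$t_start[tl$submission == 2] >= split_end))

  # 14 two-stage pipelines: no align unit starts before its own splitter ends
  reqs14 <- list()
  for (s in 1:14) {
    reqs14[[2 * s - 1]] <- sim_request(2, 4)
    reqs14[[2 * s]] <- sim_request(10, sample(2:6, 1), depends_on = 2 * s - 1)
  }
  tl14 <- simulate_schedule(reqs14, n_workers = 10)
  for (s in 1:14) {
    se <- max(tl14$t_end[tl14$submission == 2 * s - 1])
    expect_true(all(tl14$t_start[tl14$submission == 2 * s] >= se))
  }
  expect_error(
    simulate_schedule(list(sim_request(1, 1, depends_on = 2),
                           sim_request(1, 1, depends_on = 1)), 2),
    class = "sim_error")
})

test_that("the event simulator matches the brute-force oracle on small instances", {
  set.seed(23)
  for (i in 1:60) {
    wl <- random_sim_workload(max_requests = 3, max_units = 12, max_workers = 8)
    tl <- simulate_schedule(wl$requests, wl$n_workers)
    or <- oracle_schedule(wl$requests, wl$n_workers)
    tl_df <- as.data.frame(tl)[order(tl$submission, tl$task_index), ]
    or <- or[order(or$submission, or$task_index), ]
    expect_equal(tl_df$t_start, or$t_start, tolerance = 1e-9)
    expect_equal(tl_df$t_end, or$t_end, tolerance = 1e-9)
    expect_equal(tl_df$worker_id, or$worker_id)
  }
})

test_that("makespan is monotone in workers and overhead", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:80, 1); d <- stats::runif(1, 0.5, 5)
    W <- sample(1:10, 1)
    m1 <- timeline_makespan(simulate_schedule(sim_request(n, d), W))
    m2 <- timeline_makespan(simulate_schedule(sim_request(n, d), W + 2))
    expect_gte(m1, m2)
    o1 <- timeline_makespan(simulate_schedule(sim_request(n, d), W, overhead = 0.1))
    o2 <- timeline_makespan(simulate_schedule(sim_request(n, d), W, overhead = 0.5))
    expect_gte(o2, o1)
    expect_gte(o1, m1)
  }
})

test_that("per-assignment overhead serializes on the master", {
  # 1 worker, 3 jobs of 1 s, 0.5 s overhead: starts at 0.5, 2.0, 3.5
  tl <- simulate_schedule(sim_request(3, 1), 1, overhead = 0.5)
  expect_equal(tl$t_start, c(0.5, 2.0, 3.5))
  # many workers, zero-length jobs: the master itself is the bottleneck
  tl2 <- simulate_schedule(sim_request(10, 0), 100, overhead = 0.25)
  expect_equal(timeline_makespan(tl2), 9 * 0.25)
})

test_that("timeline export round-trips and keeps per-worker counts", {
  tl <- simulate_schedule(sim_request(3, 2), 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  timeline_export(tl, path)
  lines <- readLines(path)
  expect_length(lines, 4)  # header + 3 rows
  back <- timeline_read(path, n_workers = 2)
  expect_equal(timeline_makespan(back), timeline_makespan(tl))
  expect_equal(worker_counts(back), worker_counts(tl))

  # scaled staircase export: per-worker rows within floor/ceil bounds
  big <- simulate_schedule(sim_request(100, 120), 19)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  timeline_export(big, p2)
  rows <- utils::read.delim(p2)
  counts <- table(rows$worker_id)
  b <- rounds_bounds(100, 19)
  expect_true(all(counts >= b["min"] & counts <= b["max"]))
  expect_false(is.unsorted(rows$t_start))
})

test_that("the MDS advisor flags rates strictly above the limit", {
  r <- mds_load_check(20000, 1.0)
  expect_equal(r$rate, 20000)
  expect_true(r$exceeds)          # the launch-storm regime
  expect_false(mds_load_check(0, 1.0)$exceeds)
  expect_false(mds_load_check(1300, 1.0)$exceeds)   # boundary: strict >
  expect_true(mds_load_check(1301, 1.0)$exceeds)
  expect_equal(mds_load_check(650, 0.5)$rate, 1300)
  expect_error(mds_load_check(10, 0), class = "sim_error")
})

test_that("timeline tidiers and plots work", {
  tl <- simulate_schedule(list(sim_request(4, 1), sim_request(2, 2)), 2)
  td <- tidy(tl)
  expect_true(all(c("duration", "worker_id") %in% names(td)))
  g <- glance(tl)
  expect_equal(g$n_units, 6)
  expect_equal(g$n_workers, 2)
  p1 <- autoplot(tl, ideal = ideal_makespan(6, 2, 1))
  p2 <- plot_worker_filling(tl)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})
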