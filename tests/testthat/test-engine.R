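test_that("handle_submit expands into MAIN and stamps registration", {
  eng <- make_engine(worker_count = 0)
  sid <- handle_submit(eng, task_request("exit 0", 4, "stage1"))
  expect_equal(sid, 1L)
  expect_equal(pool_size(eng$main), 4)
  u <- vge_units(eng)
  expect_true(all(u$state == "PENDING"))
  expect_true(all(!is.na(u$t_submit)))

  s <- query_status(eng, sid)
  expect_equal(s$n_pending, 4)
  expect_false(s$all_done)
})

test_that("14 pipelines x 2 splitter jobs queue 28 units before any scheduling", {
  eng <- make_engine(worker_count = 0)
  for (p in 1:14)
    handle_submit(eng, task_request("split input", 2,
                                    sprintf("sample%02d_fastq_splitter", p)))
  expect_equal(pool_size(eng$main), 28)
  expect_equal(sum(vge_units(eng)$state == "PENDING"), 28)
})

test_that("submissions after shutdown are rejected without pool changes", {
  eng <- make_engine(worker_count = 1)
  engine_shutdown(eng)
  expect_error(handle_submit(eng, task_request("exit 0", 2, "late")),
               class = "vge_submit_rejected")
  expect_equal(pool_size(eng$main), 0)
})

test_that("refill follows the two-step policy and never tops up FIRST", {
  eng <- make_engine(worker_count = 8)
  handle_submit(eng, task_request("exit 0", 100, "bulk"))
  moved <- refill(eng)
  expect_equal(unname(moved), c(100L, 8L))
  expect_equal(pool_size(eng$main), 0)
  expect_equal(pool_size(eng$second), 92)
  expect_equal(pool_size(eng$first), 8)

  # FIRST non-empty: no movement, and MAIN is left alone while SECOND holds units
  handle_submit(eng, task_request("exit 0", 5, "later"))
  expect_equal(unname(refill(eng)), c(0L, 0L))
  expect_equal(pool_size(eng$main), 5)

  empty <- make_engine(worker_count = 4)
  expect_equal(unname(refill(empty)), c(0L, 0L))
})

test_that("schedule_step pairs FIFO units with idle workers", {
  eng <- make_engine(worker_count = 2)
  handle_submit(eng, task_request("exit 0", 3, "three"))
  a <- schedule_step(eng)
  expect_equal(nrow(a), 2)                    # min(idle, available)
  expect_equal(a$task_index, 1:2)             # FIFO
  expect_equal(a$worker_id, 1:2)              # ascending worker ids
  expect_true(all(vge_workers(eng)$status[1:2] == "BUSY"))

  a2 <- schedule_step(eng)                    # no idle workers -> no-op
  expect_equal(nrow(a2), 0)
})

test_that("handle_complete finishes units, frees workers, and is exactly-once", {
  eng <- make_engine(worker_count = 2)
  sid <- handle_submit(eng, task_request("exit 0", 2, "pair"))
  schedule_step(eng)
  s <- handle_complete(eng, 1L, sid, 1L, 0L)
  expect_equal(s$n_done, 1)
  expect_equal(vge_workers(eng)$status[1], "IDLE")
  expect_equal(vge_workers(eng)$completed_count[1], 1)

  s2 <- handle_complete(eng, 2L, sid, 2L, 7L)
  expect_equal(s2$n_failed, 1)
  expect_true(s2$all_done)   # FAILED counts as finished

  # duplicate COMPLETE: warned, ignored, counts unchanged
  expect_warning(handle_complete(eng, 2L, sid, 2L, 0L),
                 class = "vge_protocol_warning")
  s3 <- query_status(eng, sid)
  expect_equal(s3$n_failed, 1)
  expect_equal(s3$n_done, 1)
  expect_equal(vge_workers(eng)$completed_count, c(1L, 1L))

  # completion from the wrong worker or for an unknown unit: same treatment
  expect_warning(handle_complete(eng, 1L, sid, 2L, 0L),
                 class = "vge_protocol_warning")
  expect_warning(handle_complete(eng, 1L, 99L, 1L, 0L),
                 class = "vge_protocol_warning")
  u <- vge_units(eng)
  expect_equal(u$exit_code, c(0L, 7L))
})

test_that("query_status errors on unknown ids and counts always sum to max_task", {
  eng <- make_engine(worker_count = 2)
  expect_error(query_status(eng, 5L), class = "vge_not_found")
  sid <- handle_submit(eng, task_request("exit 0", 5, "five"))
  s <- query_status(eng, sid)
  expect_equal(s$n_pending, 5)
  expect_false(s$all_done)
  engine_run(eng, sid)
  s2 <- query_status(eng, sid)
  expect_true(s2$all_done)
  expect_equal(s2$n_done, 5)
})

test_that("exactly-once assignment and conservation hold under random workloads", {
  set.seed(99)
  for (rep in 1:5) {
    W <- sample(1:6, 1)
    eng <- make_engine(worker_count = W)
    total <- 0L
    sids <- integer()
    for (r in seq_len(sample(1:5, 1))) {
      mt <- sample(1:12, 1)
      total <- total + mt
      sids <- c(sids, handle_submit(eng, task_request("exit 0", mt,
                                                      paste0("r", r))))
    }
    log <- run_engine_logged(eng)
    # every unit assigned exactly once
    expect_equal(nrow(log), total)
    expect_equal(anyDuplicated(log$unit_id), 0L)
    u <- vge_units(eng)
    expect_equal(nrow(u), total)
    expect_true(all(u$state == "DONE"))
    # counts sum to the whole workload, per submission and per worker
    expect_equal(sum(vge_workers(eng)$completed_count), total)
    for (sid in sids) {
      s <- query_status(eng, sid)
      expect_equal(s$n_done + s$n_failed + s$n_pending +
                     s$n_assigned + s$n_running, s$max_task)
    }
    # timestamps honor the lifecycle order
    expect_true(all(u$t_submit <= u$t_assign & u$t_assign <= u$t_start &
                      u$t_start <= u$t_end))
    # global FIFO: units left the queue in registration order
    expect_equal(log$unit_id, sort(log$unit_id))
  }
})

test_that("a worker is never booked onto two units at once", {
  eng <- make_engine(worker_count = 3, executor = "shell")
  handle_submit(eng, task_request("sleep 0.2", 6, "naps"))
  for (i in 1:200) {
    schedule_step(eng)
    busy <- vge_workers(eng)
    expect_true(all(table(busy$current_unit[!is.na(busy$current_unit)]) == 1))
    expect_true(all(is.na(busy$current_unit) | busy$status == "BUSY"))
    taskfarm:::pump_workers(eng)
    taskfarm:::collect_messages(eng)
    st <- eng$units
    if (!any(st$state[seq_len(st$n)] != "DONE")) break
    Sys.sleep(0.01)
  }
  expect_true(all(vge_units(eng)$state == "DONE"))
})

test_that("one cycle assigns work whenever a unit and an idle worker exist", {
  eng <- make_engine(worker_count = 1)
  handle_submit(eng, task_request("exit 0", 1, "single"))
  a <- schedule_step(eng)   # liveness: first cycle must issue >= 1 assignment
  expect_gte(nrow(a), 1)
})

test_that("a lost worker fails its unit with exit 255 and leaves scheduling", {
  eng <- make_engine(worker_count = 2)
  sid <- handle_submit(eng, task_request("exit 0", 4, "lossy"))
  transport_close(eng$ep_workers[[1]])
  engine_run(eng, sid)
  u <- vge_units(eng)
  lost <- u[u$worker_id == 1 & u$state == "FAILED", ]
  expect_equal(nrow(lost), 1)
  expect_equal(lost$exit_code, 255L)
  expect_equal(vge_workers(eng)$status[1], "STOPPED")
  # the rest completed on the surviving worker
  expect_equal(sum(u$state == "DONE"), 3)
  expect_true(all(u$worker_id[u$state == "DONE"] == 2))
})

test_that("fail_fast aborts a submission's queued units with exit 125", {
  eng <- make_engine(worker_count = 1, executor = "shell", fail_fast = TRUE)
  sid <- handle_submit(eng, task_request("exit 3", 5, "doomed"))
  engine_run(eng, sid, timeout = 60)
  u <- vge_units(eng)
  expect_true(all(u$state == "FAILED"))
  expect_equal(sum(u$exit_code == 3L), 1)
  expect_equal(sum(u$exit_code == 125L), 4)
  expect_true(query_status(eng, sid)$all_done)
})

test_that("shutdown reports acks, never-assigned units and per-worker counts", {
  eng <- make_engine(worker_count = 2)
  s0 <- engine_shutdown(make_engine(worker_count = 2))
  expect_equal(s0$n_units, 0)
  expect_length(s0$unresponsive, 0)

  handle_submit(eng, task_request("exit 0", 6, "todo"))
  engine_run(eng)
  handle_submit(eng, task_request("exit 0", 3, "leftover"))
  summ <- engine_shutdown(eng)
  expect_equal(summ$never_assigned, 3)
  expect_equal(summ$n_done, 6)
  expect_equal(sum(summ$workers$completed_count), 6)
  expect_true(file.exists(file.path(eng$cfg$log_dir, "summary.tsv")))
  g <- glance(summ)
  expect_equal(g$n_done, 6)
})
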