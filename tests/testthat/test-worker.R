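make_assignment <- function(script, dir, task_index = 1L, worker_id = 1L,
                            basename = "job", submission_id = 1L) {
  path <- file.path(dir, paste0(basename, ".sh"))
  writeLines(script, path)
  list(submission_id = submission_id, task_index = task_index,
       basename = basename, script_path = path, worker_id = worker_id)
}

test_that("run_unit propagates shell exit codes unaltered", {
  dir <- withr::local_tempdir()
  log <- file.path(dir, "worker_1.log"); file.create(log)
  rec0 <- run_unit(make_assignment("exit 0", dir, basename = "ok"), log)
  expect_equal(rec0$exit_code, 0L)
  rec7 <- run_unit(make_assignment("exit 7", dir, basename = "bad"), log)
  expect_equal(rec7$exit_code, 7L)
  expect_true(rec7$t_end >= rec7$t_start)
  # one log line per executed unit, tab-separated
  lines <- readLines(log)
  expect_length(lines, 2)
  expect_equal(as.integer(vapply(strsplit(lines, "\t"), `[[`, "", 6)),
               c(0L, 7L))
})

test_that("the array-task context variables reach the command", {
  # oracle: run the same script directly in sh with the variable set by hand
  dir <- withr::local_tempdir()
  log <- file.path(dir, "worker_3.log"); file.create(log)
  out_pkg <- file.path(dir, "out_pkg.txt")
  out_sh <- file.path(dir, "out_sh.txt")
  script <- sprintf('printf "%%s" "$VGE_TASK_ID" > %s', shQuote(out_pkg))
  a <- make_assignment(script, dir, task_index = 2L, worker_id = 3L,
                       basename = "echoid", submission_id = 9L)
  run_unit(a, log)
  system2("sh", c("-c", shQuote(sub(out_pkg, out_sh, script, fixed = TRUE))),
          env = "VGE_TASK_ID=2")
  expect_identical(readLines(out_pkg, warn = FALSE),
                   readLines(out_sh, warn = FALSE))
  expect_identical(readLines(out_pkg, warn = FALSE), "2")

  env_dump <- file.path(dir, "env.txt")
  a2 <- make_assignment(
    sprintf('printf "%%s %%s %%s" "$VGE_BASENAME" "$VGE_SUBMISSION_ID" "$VGE_WORKER_ID" > %s',
            shQuote(env_dump)), dir, task_index = 1L, worker_id = 4L,
    basename = "ctx", submission_id = 5L)
  run_unit(a2, log)
  expect_identical(readLines(env_dump, warn = FALSE), "ctx 5 4")
})

test_that("a missing command script completes with sentinel exit 254", {
  dir <- withr::local_tempdir()
  log <- file.path(dir, "worker_1.log"); file.create(log)
  rec <- run_unit(list(submission_id = 1L, task_index = 1L, basename = "gone",
                       script_path = file.path(dir, "nope.sh"),
                       worker_id = 1L), log)
  expect_equal(rec$exit_code, 254L)
})

test_that("precreate_logs creates exactly worker_count files, idempotently", {
  dir <- withr::local_tempdir()
  res <- precreate_logs(8, dir)
  expect_equal(nrow(res), 8)
  expect_true(all(file.exists(res$path)))
  expect_true(all(res$created))
  expect_equal(basename(res$path), sprintf("worker_%d.log", 1:8))

  res0 <- precreate_logs(0, file.path(dir, "empty"))
  expect_equal(nrow(res0), 0)

  # idempotent: appended content survives re-invocation
  cat("marker\n", file = res$path[3], append = TRUE)
  res2 <- precreate_logs(8, dir)
  expect_true(all(!res2$created))
  expect_equal(readLines(res$path[3]), "marker")

  # a log_dir path blocked by an existing regular file cannot be created
  blocked <- file.path(dir, "blocked"); file.create(blocked)
  expect_error(precreate_logs(2, blocked), class = "worker_startup_error")
})

test_that("file creations are W logs before launch plus one script per submission", {
  eng <- make_engine(worker_count = 3, executor = "shell")
  handle_submit(eng, task_request("exit 0", 5, "alpha"))
  handle_submit(eng, task_request("exit 0", 4, "beta"))
  engine_run(eng)
  ev <- dplyr::bind_rows(lapply(eng$io_events, tibble::as_tibble))
  logs <- ev[ev$event == "create_log" & grepl("worker_", ev$path), ]
  scripts <- ev[ev$event == "create_script", ]
  expect_equal(nrow(logs), 3)                 # one per worker, not per job
  expect_equal(nrow(scripts), 2)              # one per submission, not per unit
  # every log creation precedes every execution start
  first_start <- min(vge_units(eng)$t_start)
  expect_true(all(logs$time < first_start))
  expect_true(all(ev$actor == "master"))      # single creating actor
})

test_that("exit codes flow unaltered from the shell into submission status", {
  eng <- make_engine(worker_count = 2, executor = "shell")
  res <- vge_task("exit $VGE_TASK_ID", max_task = 3, basename = "codes",
                  endpoint = eng)
  expect_equal(res$exit_code, 1:3)
  expect_equal(res$state, rep("FAILED", 3))
})
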