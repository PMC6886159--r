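#' Create a task-farm engine
#'
#' The engine is the master of a master-worker farm. It owns the unit table
#' (the one home of every unit's state), the three FIFO pools (MAIN /
#' SECOND / FIRST), the worker records and the executor. Workers are
#' in-process endpoints on the in-memory transport; the master talks to them
#' with the same encoded frames it would send over any other carrier.
#'
#' Worker log files are created here, by this single actor, before any
#' worker can run — one file creation per worker, never one per job, so the
#' farm's start-up metadata load stays proportional to the worker count.
#'
#' @param config A [farm_config()].
#' @return An environment of class `"vge_engine"`.
#' @export
#' @examples
#' eng <- vge_engine(farm_config(worker_count = 2, executor = "instant"))
#' handle_submit(eng, task_request("exit 0", 4, "demo"))
#' engine_run(eng)
#' vge_workers(eng)
vge_engine <- function(config = farm_config()) {
  stopifnot(inherits(config, "farm_config"))
  eng <- new.env(parent = emptyenv())
  eng$cfg <- config
  eng$units <- units_store()
  eng$submissions <- list()
  eng$next_submission_id <- 1L
  eng$main <- new_job_pool("MAIN")
  eng$second <- new_job_pool("SECOND")
  eng$first <- new_job_pool("FIRST")
  W <- config$worker_count
  eng$w_status <- rep("IDLE", W)
  eng$w_current <- rep(NA_integer_, W)
  eng$w_completed <- integer(W)
  eng$accepting <- TRUE
  eng$started_at <- now_s()
  eng$io_events <- list()
  eng$acks <- integer()

  # single-actor log pre-creation, before any worker exists
  logs <- precreate_logs(W, config$log_dir)
  for (i in seq_len(nrow(logs))) {
    if (logs$created[i]) record_io(eng, "master", "create_log", logs$path[i])
  }
  eng$log_paths <- logs$path
  eng$master_log <- file.path(config$log_dir, "master.log")
  if (!file.exists(eng$master_log)) {
    file.create(eng$master_log)
    record_io(eng, "master", "create_log", eng$master_log)
  }

  eng$broker <- mem_transport()
  eng$ep_master <- transport_endpoint(eng$broker, "master", "MASTER")
  eng$ep_workers <- lapply(seq_len(W), function(w)
    transport_endpoint(eng$broker, worker_name(w), "WORKER"))
  eng$executor <- new_executor(config$executor)
  class(eng) <- "vge_engine"
  eng
}

worker_name <- function(w) sprintf("worker_%d", w)

record_io <- function(eng, actor, event, path) {
  eng$io_events[[length(eng$io_events) + 1L]] <-
    list(time = now_s(), actor = actor, event = event, path = path)
  invisible(eng)
}

master_log <- function(eng, ...) {
  line <- sprintf("%.6f\t%s", now_s(), sprintf(...))
  try(cat(line, "\n", sep = "", file = eng$master_log, append = TRUE),
      silent = TRUE)
  invisible(eng)
}

#' @export
print.vge_engine <- function(x, ...) {
  cat(sprintf(
    "<vge_engine: %d worker(s), pools MAIN=%d SECOND=%d FIRST=%d, %d unit(s)>\n",
    length(x$w_status), pool_size(x$main), pool_size(x$second),
    pool_size(x$first), x$units$n))
  invisible(x)
}

# --- unit table: growable parallel vectors ----------------------------------

units_store <- function(capacity = 256L) {
  st <- new.env(parent = emptyenv())
  st$n <- 0L
  st$submission_id <- integer(capacity)
  st$task_index <- integer(capacity)
  st$state <- character(capacity)
  st$worker_id <- integer(capacity)
  st$exit_code <- integer(capacity)
  st$t_submit <- numeric(capacity)
  st$t_assign <- numeric(capacity)
  st$t_start <- numeric(capacity)
  st$t_end <- numeric(capacity)
  st
}

units_add <- function(st, submission_id, n, t_submit) {
  need <- st$n + n
  if (need > length(st$state)) {
    grow <- max(need, 2L * length(st$state))
    for (f in c("submission_id", "task_index", "worker_id", "exit_code"))
      st[[f]] <- c(st[[f]], integer(grow - length(st[[f]])))
    st$state <- c(st$state, character(grow - length(st$state)))
    for (f in c("t_submit", "t_assign", "t_start", "t_end"))
      st[[f]] <- c(st[[f]], numeric(grow - length(st[[f]])))
  }
  ids <- seq.int(st$n + 1L, length.out = n)
  st$submission_id[ids] <- submission_id
  st$task_index[ids] <- seq_len(n)
  st$state[ids] <- "PENDING"
  st$worker_id[ids] <- NA_integer_
  st$exit_code[ids] <- NA_integer_
  st$t_submit[ids] <- t_submit
  st$t_assign[ids] <- NA_real_
  st$t_start[ids] <- NA_real_
  st$t_end[ids] <- NA_real_
  st$n <- need
  ids
}

unit_set_state <- function(st, id, to) {
  check_transition(st$state[id], to)
  st$state[id] <- to
  invisible(st)
}

#' Inspect engine state as tibbles
#'
#' @param engine A [vge_engine()].
#' @return `vge_units()`: one row per expanded unit with its lifecycle state,
#'   worker binding, exit code and timestamps. `vge_workers()`: one row per
#'   worker with status (`IDLE`/`BUSY`/`STOPPED`), current unit and
#'   completion count.
#' @export
vge_units <- function(engine) {
  st <- engine$units
  idx <- seq_len(st$n)
  tibble(
    unit_id = idx,
    submission_id = st$submission_id[idx],
    task_index = st$task_index[idx],
    state = st$state[idx],
    worker_id = st$worker_id[idx],
    exit_code = st$exit_code[idx],
    t_submit = st$t_submit[idx],
    t_assign = st$t_assign[idx],
    t_start = st$t_start[idx],
    t_end = st$t_end[idx]
  )
}

#' @rdname vge_units
#' @export
vge_workers <- function(engine) {
  tibble(
    worker_id = seq_along(engine$w_status),
    status = engine$w_status,
    current_unit = engine$w_current,
    completed_count = engine$w_completed
  )
}

# --- submission -------------------------------------------------------------

#' Register a submission in the MAIN pool
#'
#' Expands the request into `max_task` PENDING units, appends them to the
#' MAIN pool in task-index order, and materializes the command script once
#' per submission (units share it, parameterized by `VGE_TASK_ID`), so a
#' submission costs one file creation regardless of its array size.
#' `basename` collisions are resolved by suffixing the submission id.
#'
#' @param engine A [vge_engine()].
#' @param req A [task_request()].
#' @return The engine-assigned integer `submission_id`.
#' @export
handle_submit <- function(engine, req) {
  if (!engine$accepting)
    abort("engine is shutting down; submission rejected",
          class = "vge_submit_rejected")
  if (!inherits(req, "task_request"))
    abort("`req` must be a task_request", class = "task_request_error")
  sid <- engine$next_submission_id
  engine$next_submission_id <- sid + 1L
  t <- now_s()
  base <- req$basename
  if (any(vapply(engine$submissions, function(s) identical(s$basename, base),
                 logical(1))))
    base <- sprintf("%s_%d", base, sid)

  script_path <- materialize_script(engine, req$command_text, base)
  ids <- units_add(engine$units, sid, req$max_task, t)
  pool_append(engine$main, ids)
  engine$submissions[[sid]] <- list(
    submission_id = sid, basename = base, pipeline_id = req$pipeline_id,
    command_text = req$command_text, max_task = req$max_task,
    t_submit = t, unit_ids = ids, script_path = script_path
  )
  master_log(engine, "SUBMIT\t%d\t%s\tmax_task=%d", sid, base, req$max_task)
  sid
}

# a command is either the path of an existing executable script (used as-is)
# or literal sh text (written once per submission)
materialize_script <- function(engine, command_text, base) {
  if (file.exists(command_text) && !dir.exists(command_text))
    return(normalizePath(command_text))
  path <- file.path(engine$cfg$log_dir, paste0(base, ".sh"))
  writeLines(command_text, path)
  record_io(engine, "master", "create_script", path)
  path
}

# --- pool maintenance -------------------------------------------------------

#' Refill the local pools
#'
#' The two-step policy that keeps MAIN-pool accesses rare: when FIRST has
#' drained, it is refilled with up to `worker_count` units from SECOND; only
#' when SECOND is also empty is MAIN touched, and then everything it holds
#' is moved at once. MAIN is never read while SECOND still has units.
#'
#' @param engine A [vge_engine()].
#' @return Named integer vector `c(second_filled=, first_filled=)`.
#' @export
refill <- function(engine) {
  second_filled <- 0L
  first_filled <- 0L
  if (pool_size(engine$first) == 0L) {
    if (pool_size(engine$second) == 0L)
      second_filled <- transfer_all(engine$main, engine$second)
    if (pool_size(engine$second) > 0L)
      first_filled <- extract_batch(engine$second, engine$first,
                                    length(engine$w_status))
  }
  c(second_filled = second_filled, first_filled = first_filled)
}

# --- scheduling -------------------------------------------------------------

#' Assign queued units to idle workers
#'
#' Pairs the oldest FIRST-pool units with idle workers (lowest worker id
#' first) until either runs out, sending each worker an `ASSIGN` frame.
#' Refills the pools first whenever FIRST is empty. A worker whose endpoint
#' cannot be reached is marked `STOPPED` and its unit finishes as FAILED
#' with exit code 255.
#'
#' @param engine A [vge_engine()].
#' @param now Timestamp recorded as `t_assign`.
#' @return Tibble of issued assignments (`unit_id`, `submission_id`,
#'   `task_index`, `worker_id`).
#' @export
schedule_step <- function(engine, now = now_s()) {
  st <- engine$units
  out_unit <- integer(); out_worker <- integer()
  idle <- which(engine$w_status == "IDLE")
  i <- 1L
  while (i <= length(idle)) {
    if (pool_size(engine$first) == 0L) {
      refill(engine)
      if (pool_size(engine$first) == 0L) break
    }
    uid <- dequeue_next(engine$first)
    if (st$state[uid] != "PENDING") next  # aborted while queued (fail_fast)
    w <- idle[i]
    sub <- engine$submissions[[st$submission_id[uid]]]
    payload <- list(unit_id = uid, submission_id = st$submission_id[uid],
                    task_index = st$task_index[uid], basename = sub$basename,
                    script_path = sub$script_path, worker_id = w)
    unit_set_state(st, uid, "ASSIGNED")
    st$worker_id[uid] <- w
    st$t_assign[uid] <- now
    sent <- tryCatch({
      transport_send(engine$ep_master, vge_encode(vge_message("ASSIGN", payload)),
                     worker_name(w))
      TRUE
    }, error = function(e) FALSE)
    if (!sent) {
      engine$w_status[w] <- "STOPPED"
      unit_set_state(st, uid, "RUNNING")
      unit_set_state(st, uid, "FAILED")
      st$exit_code[uid] <- 255L  # worker lost before execution
      st$t_start[uid] <- now; st$t_end[uid] <- now
      master_log(engine, "WORKER_LOST\t%d\tunit=%d", w, uid)
      check_fail_fast(engine, st$submission_id[uid])
    } else {
      engine$w_status[w] <- "BUSY"
      engine$w_current[w] <- uid
      out_unit <- c(out_unit, uid); out_worker <- c(out_worker, w)
    }
    i <- i + 1L
  }
  tibble::new_tibble(list(
    unit_id = out_unit,
    submission_id = st$submission_id[out_unit],
    task_index = st$task_index[out_unit],
    worker_id = out_worker
  ), nrow = length(out_unit))
}

# --- completion -------------------------------------------------------------

#' Record a unit's completion
#'
#' Moves the unit to `DONE` (exit 0) or `FAILED` (anything else), frees the
#' worker and bumps its completion count. A completion for an unknown unit,
#' a unit not currently on that worker, or a unit already terminal is a
#' protocol error: it is logged, a warning of class
#' `"vge_protocol_warning"` is raised, and no state changes.
#'
#' @param engine A [vge_engine()].
#' @param worker_id Reporting worker.
#' @param submission_id,task_index Unit key.
#' @param exit_code Shell exit code, propagated unaltered.
#' @param t_start,t_end Execution timestamps from the worker.
#' @return The submission's updated status tibble (see [query_status()]),
#'   invisibly on error paths.
#' @export
handle_complete <- function(engine, worker_id, submission_id, task_index,
                            exit_code, t_start = now_s(), t_end = now_s()) {
  st <- engine$units
  sub <- if (submission_id >= 1L && submission_id < engine$next_submission_id)
    engine$submissions[[submission_id]] else NULL
  uid <- if (!is.null(sub) && task_index >= 1L && task_index <= sub$max_task)
    sub$unit_ids[task_index] else NA_integer_
  bad <- is.na(uid) ||
    !(st$state[uid] %in% c("ASSIGNED", "RUNNING")) ||
    !identical(st$worker_id[uid], as.integer(worker_id))
  if (bad) {
    master_log(engine, "BAD_COMPLETE\tworker=%s\tsub=%s\ttask=%s",
               format(worker_id), format(submission_id), format(task_index))
    rlang::warn("completion for unknown or non-running unit ignored",
                class = "vge_protocol_warning")
    return(invisible(if (!is.null(sub)) query_status(engine, submission_id)))
  }
  if (st$state[uid] == "ASSIGNED") unit_set_state(st, uid, "RUNNING")
  st$t_start[uid] <- t_start
  unit_set_state(st, uid, if (exit_code == 0L) "DONE" else "FAILED")
  st$exit_code[uid] <- as.integer(exit_code)
  st$t_end[uid] <- t_end
  w <- as.integer(worker_id)
  if (engine$w_status[w] == "BUSY") {
    engine$w_status[w] <- "IDLE"
    engine$w_current[w] <- NA_integer_
  }
  engine$w_completed[w] <- engine$w_completed[w] + 1L
  if (exit_code != 0L) check_fail_fast(engine, submission_id)
  query_status(engine, submission_id)
}

# fail_fast: abort this submission's still-queued units (legal lifecycle,
# zero-duration, sentinel exit 125) and drop them from every pool
check_fail_fast <- function(engine, submission_id) {
  if (!engine$cfg$fail_fast) return(invisible())
  st <- engine$units
  ids <- engine$submissions[[submission_id]]$unit_ids
  pending <- ids[st$state[ids] == "PENDING"]
  if (length(pending) == 0L) return(invisible())
  for (p in list(engine$main, engine$second, engine$first))
    pool_remove(p, pending)
  t <- now_s()
  for (uid in pending) {
    unit_set_state(st, uid, "ASSIGNED")
    unit_set_state(st, uid, "RUNNING")
    unit_set_state(st, uid, "FAILED")
    st$exit_code[uid] <- 125L
    st$t_assign[uid] <- t; st$t_start[uid] <- t; st$t_end[uid] <- t
  }
  master_log(engine, "FAIL_FAST\tsub=%d\taborted=%d", submission_id,
             length(pending))
  invisible()
}

#' Submission status snapshot
#'
#' @param engine A [vge_engine()].
#' @param submission_id A known submission id.
#' @return One-row tibble: per-state counts (always summing to `max_task`),
#'   `all_done` (no unit still PENDING/ASSIGNED/RUNNING), and the submission
#'   label.
#' @export
query_status <- function(engine, submission_id) {
  sub <- if (is_count(submission_id, 1L) &&
             submission_id < engine$next_submission_id)
    engine$submissions[[submission_id]] else NULL
  if (is.null(sub))
    abort(sprintf("unknown submission_id %s", format(submission_id)),
          class = "vge_not_found")
  states <- engine$units$state[sub$unit_ids]
  n_pending <- sum(states == "PENDING")
  n_assigned <- sum(states == "ASSIGNED")
  n_running <- sum(states == "RUNNING")
  # new_tibble: this runs once per completion, so skip tibble()'s tidy-eval
  tibble::new_tibble(list(
    submission_id = sub$submission_id, basename = sub$basename,
    max_task = sub$max_task,
    n_pending = n_pending, n_assigned = n_assigned, n_running = n_running,
    n_done = sum(states == "DONE"), n_failed = sum(states == "FAILED"),
    all_done = (n_pending + n_assigned + n_running) == 0L
  ), nrow = 1L)
}

# exit codes of a finished submission, in task-index order
submission_exit_codes <- function(engine, submission_id) {
  sub <- engine$submissions[[submission_id]]
  engine$units$exit_code[sub$unit_ids]
}

# --- the scheduling cycle ---------------------------------------------------

# workers: drain ASSIGN/SHUTDOWN frames, start executions, emit COMPLETEs
pump_workers <- function(engine) {
  for (w in seq_along(engine$ep_workers)) {
    if (engine$w_status[w] == "STOPPED") next
    ep <- engine$ep_workers[[w]]
    repeat {
      m <- tryCatch(transport_recv(ep, timeout = 0), error = function(e) NULL)
      if (is.null(m)) break
      msg <- vge_decode(m$frame)
      if (msg$kind == "ASSIGN") {
        executor_start(engine$executor, msg$payload, engine$log_paths[w])
      } else if (msg$kind == "SHUTDOWN") {
        transport_send(ep, vge_encode(vge_message("SHUTDOWN_ACK",
                                                  list(worker_id = w),
                                                  msg$correlation_id)),
                       "master")
      }
    }
  }
  for (rec in executor_poll(engine$executor)) {
    w <- rec$worker_id
    transport_send(engine$ep_workers[[w]],
                   vge_encode(vge_message("COMPLETE", rec)), "master")
  }
  invisible(engine)
}

# master: drain COMPLETE / SHUTDOWN_ACK frames
collect_messages <- function(engine) {
  repeat {
    m <- transport_recv(engine$ep_master, timeout = 0)
    if (is.null(m)) break
    msg <- vge_decode(m$frame)
    if (msg$kind == "COMPLETE") {
      p <- msg$payload
      handle_complete(engine, p$worker_id, p$submission_id, p$task_index,
                      p$exit_code, p$t_start, p$t_end)
    } else if (msg$kind == "SHUTDOWN_ACK") {
      engine$acks <- union(engine$acks, as.integer(msg$payload$worker_id))
    }
  }
  invisible(engine)
}

#' One scheduling cycle
#'
#' Refills pools as needed, assigns idle workers, lets in-process workers
#' pick up their frames and start (or instantly finish) execution, and
#' records any completions. [engine_run()] repeats this until the work (or
#' one submission) is finished.
#'
#' @param engine A [vge_engine()].
#' @return The engine, invisibly.
#' @export
engine_cycle <- function(engine) {
  schedule_step(engine)
  pump_workers(engine)
  collect_messages(engine)
  invisible(engine)
}

#' Drive the engine until work finishes
#'
#' @param engine A [vge_engine()].
#' @param submission_id If given, return as soon as that submission is all
#'   done; otherwise run until no unit is left unterminated.
#' @param timeout Wall-clock bound in seconds; exceeding it is an error
#'   (class `"vge_timeout"`).
#' @return The engine, invisibly.
#' @export
engine_run <- function(engine, submission_id = NULL, timeout = 3600) {
  t0 <- now_s()
  live <- function() any(engine$w_status != "STOPPED")
  repeat {
    engine_cycle(engine)
    done <- if (!is.null(submission_id)) {
      query_status(engine, submission_id)$all_done
    } else {
      st <- engine$units
      !any(st$state[seq_len(st$n)] %in% c("PENDING", "ASSIGNED", "RUNNING"))
    }
    if (done) break
    if (!live() || length(engine$w_status) == 0L)
      abort("no live workers but unfinished units remain", class = "vge_stalled")
    if (now_s() - t0 > timeout)
      abort("engine_run timed out", class = "vge_timeout")
    if (engine$executor$type == "shell") Sys.sleep(engine$cfg$cycle_interval)
  }
  invisible(engine)
}

# --- shutdown ---------------------------------------------------------------

#' Stop the farm and summarise the run
#'
#' Stops accepting submissions, sends `SHUTDOWN` to every non-stopped
#' worker, waits (bounded) for their acks, writes
#' `<log_dir>/summary.tsv` (per-worker completion counts) and returns a run
#' summary.
#'
#' @param engine A [vge_engine()].
#' @param ack_timeout Seconds to wait for shutdown acks.
#' @return A list of class `"vge_summary"`: unit counts by terminal state,
#'   `never_assigned` (units still PENDING at shutdown), per-worker tibble,
#'   `makespan` (first execution start to last end, `NA` if nothing ran) and
#'   `unresponsive` worker ids.
#' @export
engine_shutdown <- function(engine, ack_timeout = 5) {
  engine$accepting <- FALSE
  targets <- which(engine$w_status != "STOPPED")
  for (w in targets)
    transport_send(engine$ep_master, vge_encode(vge_message("SHUTDOWN")),
                   worker_name(w))
  t0 <- now_s()
  while (length(setdiff(targets, engine$acks)) > 0 &&
         now_s() - t0 < ack_timeout) {
    pump_workers(engine)
    collect_messages(engine)
  }
  # reap any forked children still in flight so nothing outlives the farm
  if (engine$executor$type == "shell" && length(engine$executor$jobs) > 0) {
    jobs <- lapply(engine$executor$jobs, `[[`, "job")
    try(suppressWarnings(parallel::mccollect(jobs, wait = TRUE)), silent = TRUE)
    engine$executor$jobs <- list()
  }
  st <- engine$units
  idx <- seq_len(st$n)
  ran <- idx[!is.na(st$t_end[idx])]
  summary <- structure(list(
    n_units = st$n,
    n_done = sum(st$state[idx] == "DONE"),
    n_failed = sum(st$state[idx] == "FAILED"),
    never_assigned = sum(st$state[idx] == "PENDING"),
    workers = vge_workers(engine),
    makespan = if (length(ran) > 0)
      max(st$t_end[ran]) - min(st$t_start[ran]) else NA_real_,
    unresponsive = setdiff(targets, engine$acks)
  ), class = "vge_summary")
  tsv <- file.path(engine$cfg$log_dir, "summary.tsv")
  utils::write.table(summary$workers, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  master_log(engine, "SHUTDOWN\tdone=%d\tfailed=%d\tnever_assigned=%d",
             summary$n_done, summary$n_failed, summary$never_assigned)
  summary
}

#' @export
print.vge_summary <- function(x, ...) {
  cat("<vge_summary>\n")
  cat(sprintf("  units: %d (done %d, failed %d, never assigned %d)\n",
              x$n_units, x$n_done, x$n_failed, x$never_assigned))
  cat(sprintf("  makespan: %s s\n",
              if (is.na(x$makespan)) "NA" else sprintf("%.3f", x$makespan)))
  if (length(x$unresponsive) > 0)
    cat("  unresponsive workers:", paste(x$unresponsive, collapse = ", "), "\n")
  invisible(x)
}

#' @export
glance.vge_summary <- function(x, ...) {
  tibble(n_units = x$n_units, n_done = x$n_done, n_failed = x$n_failed,
         never_assigned = x$never_assigned, makespan = x$makespan,
         n_workers = nrow(x$workers),
         n_unresponsive = length(x$unresponsive))
}

#' Timeline of executed units
#'
#' @param engine A [vge_engine()].
#' @return A [vge_timeline] tibble (one row per unit that reached a terminal
#'   state with recorded execution times), usable with [timeline_export()],
#'   [glance()][generics::glance] and [ggplot2::autoplot()].
#' @export
engine_timeline <- function(engine) {
  u <- vge_units(engine)
  u <- u[!is.na(u$t_end) & !is.na(u$t_start), ]
  new_timeline(tibble(
    submission = u$submission_id, task_index = u$task_index,
    worker_id = u$worker_id, t_start = u$t_start, t_end = u$t_end
  ), n_workers = length(engine$w_status))
}
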