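# Brute-force time-stepping scheduler, independent of simulate_schedule():
# walks event times explicitly, keeps an explicit FIFO queue, and assigns
# queued units to idle workers in ascending worker id at each instant.
# Only for tiny instances.
oracle_schedule <- function(requests, n_workers) {
  if (inherits(requests, "sim_request")) requests <- list(requests)
  R <- length(requests)
  deps <- vapply(requests, `[[`, integer(1), "depends_on")
  n_units <- vapply(requests, `[[`, integer(1), "n_units")
  registered <- logical(R)
  req_end <- rep(NA_real_, R)    # known once all units assigned
  ends_seen <- lapply(seq_len(R), function(r) numeric(0))
  queue <- list()                # FIFO of list(r, i, duration)
  worker_free <- numeric(n_workers)
  rows <- list()
  t <- 0
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 100000L) stop("oracle did not terminate")
    # eligibility of unregistered requests, as far as it is knowable now
    elig <- rep(NA_real_, R)
    for (r in seq_len(R)) {
      if (registered[r]) next
      e <- requests[[r]]$submit_time
      d <- deps[r]
      if (!is.na(d)) {
        if (length(ends_seen[[d]]) < n_units[d]) next  # predecessor not done
        e <- max(e, max(ends_seen[[d]], 0))
      }
      elig[r] <- e
    }
    ready <- which(!registered & !is.na(elig) & elig <= t)
    for (r in ready[order(elig[ready], ready)]) {
      for (i in seq_len(n_units[r]))
        queue[[length(queue) + 1L]] <- list(r = r, i = i,
                                            duration = requests[[r]]$duration)
      registered[r] <- TRUE
    }
    for (w in seq_len(n_workers)) {
      if (length(queue) == 0) break
      if (worker_free[w] > t) next
      u <- queue[[1]]; queue <- queue[-1]
      rows[[length(rows) + 1L]] <- data.frame(
        submission = u$r, task_index = u$i, worker_id = w,
        t_start = t, t_end = t + u$duration)
      worker_free[w] <- t + u$duration
      ends_seen[[u$r]] <- c(ends_seen[[u$r]], t + u$duration)
    }
    all_assigned <- all(registered) && length(queue) == 0
    if (all_assigned && all(worker_free <= t)) break
    nexts <- c(worker_free[worker_free > t], elig[!registered & !is.na(elig) & elig > t])
    if (all_assigned && length(nexts) == 0) break
    if (length(nexts) == 0) {
      # nothing schedulable yet: jump to the next knowable event
      if (all(worker_free <= t)) stop("oracle stalled")
      nexts <- worker_free[worker_free > t]
    }
    t <- min(nexts)
  }
  out <- do.call(rbind, rows)
  out[order(out$t_start, out$worker_id), ]
}

random_sim_workload <- function(max_requests = 3, max_units = 12,
                                max_workers = 8) {
  R <- sample.int(max_requests, 1)
  reqs <- lapply(seq_len(R), function(r) {
    dep <- if (r > 1 && stats::runif(1) < 0.4) sample.int(r - 1L, 1) else NA_integer_
    sim_request(sample.int(max_units, 1),
                duration = sample(c(0.5, 1, 2, 3.5), 1),
                submit_time = sample(c(0, 0, 1, 2.5), 1),
                depends_on = dep)
  })
  list(requests = reqs, n_workers = sample.int(max_workers, 1))
}
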