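#' Closed-form scheduling calculators
#'
#' For `n` equal-duration array jobs on `W` workers dispatched greedily in
#' FIFO order, the schedule is a sequence of `ceiling(n/W)` rounds, so:
#'
#' * `ideal_makespan(n, W, d) = ceiling(n/W) * d` — the zero-overhead
#'   elapsed time (the "ideal" reference line in start-time plots);
#' * `rounds_bounds(n, W) = (floor(n/W), ceiling(n/W))` — the realized
#'   minimum and maximum number of jobs any single worker executes.
#'
#' @param n_jobs Number of array jobs (>= 0).
#' @param n_workers Number of workers (>= 1 when `n_jobs > 0`).
#' @param duration Seconds per job (uniform).
#' @return `ideal_makespan()`: seconds. `rounds_bounds()`: named integer
#'   vector `c(min = floor(n/W), max = ceiling(n/W))`.
#' @export
#' @examples
#' ideal_makespan(100000, 1999, 120)  # 51 rounds x 120 s = 6120 s
#' rounds_bounds(10000, 1999)         # every worker runs 5 or 6 jobs
ideal_makespan <- function(n_jobs, n_workers, duration) {
  stopifnot(is_count(n_jobs), is.numeric(duration), duration >= 0)
  if (n_jobs == 0) return(0)
  if (!is_count(n_workers, min = 1L))
    abort("`n_workers` must be >= 1 when there are jobs to run",
          class = "sim_error")
  ceiling(n_jobs / n_workers) * duration
}

#' @rdname ideal_makespan
#' @export
rounds_bounds <- function(n_jobs, n_workers) {
  stopifnot(is_count(n_jobs), is_count(n_workers, min = 1L))
  c(min = as.integer(floor(n_jobs / n_workers)),
    max = as.integer(ceiling(n_jobs / n_workers)))
}

#' Describe a simulated submission
#'
#' @param n_units Number of array elements (>= 1).
#' @param duration Seconds per element (uniform within the request; >= 0).
#' @param submit_time Seconds at which the request reaches the master.
#' @param depends_on Index (into the request list) of a predecessor request;
#'   this request becomes eligible only when every unit of the predecessor
#'   has ended — the blocking-submission semantics of [vge_task()].
#' @param label Submission label carried into the timeline.
#' @return A list of class `"sim_request"`.
#' @export
sim_request <- function(n_units, duration, submit_time = 0,
                        depends_on = NA_integer_, label = NULL) {
  stopifnot(is_count(n_units, min = 1L), is.numeric(duration), duration >= 0,
            is.numeric(submit_time), submit_time >= 0)
  structure(list(n_units = as.integer(n_units), duration = duration,
                 submit_time = submit_time,
                 depends_on = as.integer(depends_on), label = label),
            class = "sim_request")
}

#' Discrete-event schedule simulation
#'
#' Plays a workload through the farm's scheduling policy without running
#' anything: greedy FIFO dispatch (oldest eligible unit to the
#' earliest-free worker, ties broken by lowest worker id), submissions
#' eligible at their submit time or — when `depends_on` is set — when their
#' predecessor has fully finished. Each assignment additionally occupies
#' the master for `overhead` seconds, serially; the master performs one
#' assignment at a time, so with many short jobs the overhead stream itself
#' can become the bottleneck. `overhead = 0` reproduces the zero-overhead
#' ideal exactly.
#'
#' @param requests A list of [sim_request()]s (a single request is
#'   accepted bare). Dependencies must be acyclic and refer to earlier
#'   list positions or later ones — any cycle is an error.
#' @param n_workers Number of workers (>= 1).
#' @param overhead Master seconds consumed per assignment (>= 0).
#' @return A [vge_timeline] with one row per simulated unit.
#' @export
#' @examples
#' tl <- simulate_schedule(sim_request(4, 1), n_workers = 2)
#' timeline_makespan(tl)  # 2
simulate_schedule <- function(requests, n_workers, overhead = 0) {
  if (inherits(requests, "sim_request")) requests <- list(requests)
  stopifnot(length(requests) > 0,
            all(vapply(requests, inherits, logical(1), "sim_request")),
            is_count(n_workers, min = 1L),
            is.numeric(overhead), overhead >= 0)
  R <- length(requests)
  deps <- vapply(requests, `[[`, integer(1), "depends_on")
  if (any(!is.na(deps) & (deps < 1L | deps > R)))
    abort("depends_on must index another request", class = "sim_error")

  worker_free <- numeric(n_workers)
  master_free <- 0
  req_end <- numeric(R)        # completion time of each request's last unit
  n_total <- sum(vapply(requests, `[[`, integer(1), "n_units"))
  sub <- integer(n_total); tix <- integer(n_total); wid <- integer(n_total)
  ts <- numeric(n_total); te <- numeric(n_total)
  k <- 0L

  # Requests register in order of effective eligibility (submit time, or the
  # predecessor's completion for dependent requests), ties broken by list
  # position: registration order at a live master. Units of a request queue
  # contiguously, so processing whole requests in that order IS global FIFO.
  placed <- logical(R)
  while (!all(placed)) {
    cand <- which(!placed & (is.na(deps) | placed[ifelse(is.na(deps), 1L, deps)]))
    if (length(cand) == 0)
      abort("cyclic dependencies among requests", class = "sim_error")
    elig <- vapply(cand, function(r) {
      e <- requests[[r]]$submit_time
      if (!is.na(deps[r])) e <- max(e, req_end[deps[r]])
      e
    }, numeric(1))
    r <- cand[order(elig, cand)][1L]
    eligible <- elig[match(r, cand)]
    rq <- requests[[r]]
    last_end <- eligible
    for (i in seq_len(rq$n_units)) {
      # assignment instant: first moment a worker and the master are both
      # free; among workers free by then, take the lowest id (the order a
      # live master scans its idle list)
      begin <- max(eligible, master_free, min(worker_free))
      w <- which(worker_free <= begin)[1L]
      master_free <- begin + overhead
      t_start <- begin + overhead
      t_end <- t_start + rq$duration
      worker_free[w] <- t_end
      k <- k + 1L
      sub[k] <- r; tix[k] <- i; wid[k] <- w; ts[k] <- t_start; te[k] <- t_end
      last_end <- max(last_end, t_end)
    }
    req_end[r] <- last_end
    placed[r] <- TRUE
  }
  new_timeline(tibble(submission = sub, task_index = tix, worker_id = wid,
                      t_start = ts, t_end = te),
               n_workers = n_workers)
}

#' Metadata-server load advisor
#'
#' Distributed (Lustre-family) file systems funnel every file creation,
#' removal or attribute change through a small number of metadata servers.
#' A farm start-up that creates one log per worker issues `W` metadata
#' operations nearly at once; at tens of thousands of workers that burst
#' can exceed what an MDS sustains and stall the whole machine. This check
#' compares an operation burst against a sustainable-rate limit.
#'
#' @param n_metadata_ops Number of metadata operations in the window.
#' @param window_seconds Length of the burst window (> 0).
#' @param limit Sustainable operations/second; the default is the commonly
#'   quoted limit of a Lustre-family MDS.
#' @return A one-row tibble: `rate` (ops/second) and `exceeds` (strictly
#'   above the limit; hitting the limit exactly does not flag).
#' @export
#' @examples
#' mds_load_check(20000, 1)   # a per-worker log-creation storm: exceeds
#' mds_load_check(1300, 1)    # at the limit: not exceeded (strict >)
mds_load_check <- function(n_metadata_ops, window_seconds, limit = 1300) {
  stopifnot(is.numeric(n_metadata_ops), n_metadata_ops >= 0,
            is.numeric(limit), limit > 0)
  if (!is.numeric(window_seconds) || window_seconds <= 0)
    abort("`window_seconds` must be > 0", class = "sim_error")
  rate <- n_metadata_ops / window_seconds
  tibble(rate = rate, limit = limit, exceeds = rate > limit)
}
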