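#' FIFO job pools
#'
#' The master keeps three pools of pending array-job units, layered to cut
#' how often the large registration pool is touched:
#'
#' * `MAIN` — every submitted unit is appended here at registration;
#' * `SECOND` — a bulk copy of MAIN, taken whenever both local pools drain;
#' * `FIRST` — at most `worker_count` units extracted from SECOND, the only
#'   pool the per-cycle assignment loop reads.
#'
#' Pools store unit keys (integers into the engine's unit table), not copies
#' of unit state — a unit's state has exactly one home. Insertion order is
#' preserved everywhere, so the order in which units leave FIRST equals their
#' registration order into MAIN.
#'
#' @param role One of `"MAIN"`, `"SECOND"`, `"FIRST"`.
#' @return `new_job_pool()` returns an empty pool (an environment of class
#'   `"job_pool"`).
#' @name job_pool
NULL

#' @rdname job_pool
#' @export
new_job_pool <- function(role = c("MAIN", "SECOND", "FIRST")) {
  role <- match.arg(role)
  pool <- new.env(parent = emptyenv())
  pool$role <- role
  pool$ids <- integer()
  pool$head <- 1L   # dequeue position; avoids O(n^2) head-dropping
  class(pool) <- "job_pool"
  pool
}

#' @rdname job_pool
#' @param pool A `job_pool`.
#' @export
pool_size <- function(pool) length(pool$ids) - pool$head + 1L

#' @rdname job_pool
#' @export
pool_ids <- function(pool) {
  if (pool$head > length(pool$ids)) integer() else pool$ids[pool$head:length(pool$ids)]
}

pool_append <- function(pool, ids) {
  pool$ids <- c(pool$ids, as.integer(ids))
  invisible(pool)
}

pool_clear <- function(pool) {
  pool$ids <- integer()
  pool$head <- 1L
  invisible(pool)
}

# drop a unit wherever it queues (fail-fast abort path)
pool_remove <- function(pool, ids) {
  keep <- !(pool$ids %in% ids)
  keep[seq_len(pool$head - 1L)] <- TRUE
  removed <- sum(!keep)
  if (removed > 0) {
    live <- pool$ids[pool$head:length(pool$ids)]
    live <- live[!(live %in% ids)]
    pool$ids <- live
    pool$head <- 1L
  }
  invisible(removed)
}

#' @export
print.job_pool <- function(x, ...) {
  cat(sprintf("<job_pool %s: %d unit(s)>\n", x$role, pool_size(x)))
  invisible(x)
}

#' Bulk copy from the registration pool
#'
#' Moves every unit from the MAIN pool to the SECOND pool, preserving their
#' relative (FIFO) order, and empties MAIN. This is the bulk transfer the
#' master performs "at a certain time" — in this engine, exactly when both
#' local pools have drained (see [refill()]).
#'
#' @param main A pool with role `MAIN`.
#' @param second A pool with role `SECOND`.
#' @return Number of units moved, invisibly visible (a plain integer).
#' @export
transfer_all <- function(main, second) {
  check_role(main, "MAIN")
  check_role(second, "SECOND")
  moving <- pool_ids(main)
  pool_append(second, moving)
  pool_clear(main)
  length(moving)
}

#' Extract a worker-count-sized batch
#'
#' Moves the `min(worker_count, size(second))` oldest units from SECOND to
#' FIRST, preserving order. FIRST must be empty: the engine refills it only
#' once it has fully drained, never tops it up, so FIRST never exceeds the
#' worker count.
#'
#' @param second A pool with role `SECOND`.
#' @param first An empty pool with role `FIRST`.
#' @param worker_count Batch size bound (>= 0).
#' @return Number of units moved.
#' @export
extract_batch <- function(second, first, worker_count) {
  check_role(second, "SECOND")
  check_role(first, "FIRST")
  stopifnot(is_count(worker_count))
  if (pool_size(first) > 0)
    abort("FIRST pool must be drained before it is refilled",
          class = "pool_contract_error")
  k <- min(as.integer(worker_count), pool_size(second))
  if (k > 0) {
    taken <- pool_ids(second)[seq_len(k)]
    pool_append(first, taken)
    pool_advance(second, k)
  }
  k
}

#' Dequeue the oldest unit
#'
#' @param first A pool with role `FIRST`.
#' @return The oldest unit key, or `NULL` when the pool is empty.
#' @export
dequeue_next <- function(first) {
  check_role(first, "FIRST")
  if (pool_size(first) == 0L) return(NULL)
  id <- first$ids[first$head]
  pool_advance(first, 1L)
  id
}

check_role <- function(pool, role) {
  if (!inherits(pool, "job_pool") || !identical(pool$role, role))
    abort(sprintf("expected a job pool with role %s", role),
          class = "pool_contract_error")
  invisible(pool)
}

pool_advance <- function(pool, k) {
  pool$head <- pool$head + as.integer(k)
  # compact occasionally so long-lived pools do not hold dead prefixes
  if (pool$head > 1024L && pool$head > length(pool$ids) / 2) {
    pool$ids <- pool_ids(pool)
    pool$head <- 1L
  }
  invisible(pool)
}
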