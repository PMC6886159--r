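`%||%` <- function(a, b) if (is.null(a)) b else a

sorted_payload <- function(p) if (length(p) > 0) p[order(names(p))] else p

# fresh engine in a throwaway log dir
make_engine <- function(worker_count = 2, executor = "instant", ...) {
  vge_engine(farm_config(worker_count = worker_count, executor = executor,
                         log_dir = tempfile("farm-"), ...))
}

# random but JSON-stable payload scalars for codec property tests
random_payload <- function() {
  n <- sample(0:5, 1)
  if (n == 0) return(list())
  vals <- lapply(seq_len(n), function(i) {
    switch(sample(4, 1),
      paste(sample(c(letters, " ", "\"", "\\", "/", "\n"), sample(1:12, 1),
                   replace = TRUE), collapse = ""),
      sample.int(10000, 1),
      TRUE,
      stats::runif(1))
  })
  names(vals) <- paste0("k", sample(100, n))
  vals
}

random_message <- function() {
  kinds <- c("SUBMIT", "SUBMIT_ACK", "STATUS_QUERY", "STATUS_REPLY",
             "ASSIGN", "COMPLETE", "SHUTDOWN", "SHUTDOWN_ACK")
  vge_message(sample(kinds, 1), random_payload())
}

# drive an engine manually, recording every issued assignment
run_engine_logged <- function(eng, max_cycles = 100000) {
  assignments <- list()
  for (i in seq_len(max_cycles)) {
    a <- schedule_step(eng)
    if (nrow(a) > 0) assignments[[length(assignments) + 1L]] <- a
    taskfarm:::pump_workers(eng)
    taskfarm:::collect_messages(eng)
    st <- eng$units
    if (!any(st$state[seq_len(st$n)] %in% c("PENDING", "ASSIGNED", "RUNNING")))
      break
  }
  dplyr::bind_rows(assignments)
}
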