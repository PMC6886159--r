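---
title: "Array-job farming: model, design choices, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Array-job farming: model, design choices, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taskfarm)
```

## The problem

Sequencing pipelines are chains of *array jobs*: one command expanded
into N independent task instances, with stage k+1 allowed to start only
after every instance of stage k has finished. Grid engines provide this
as a service; massively parallel machines usually do not, offering only
synchronous MPI-style allocation. `taskfarm` implements the standard
bridge: a user-space master–worker farm that *emulates* the grid-engine
array-job contract on top of a flat pool of processes, plus a simulator
that predicts what the farm will do.

## The scheduling model

The master is the single home of all state. A submission
(`task_request()`) carries the array-job triple — command text,
`max_task`, `basename` — and `expand_request()` turns it into
`max_task` units with 1-based task indices. Units move along exactly
one lifecycle path,

`PENDING -> ASSIGNED -> RUNNING -> DONE | FAILED`,

enforced by `check_transition()`; any other edge is an error. `DONE`
means exit code 0, `FAILED` anything else; either way the unit counts
as *finished*, which is what unblocks a waiting `vge_task()`.

### Three pools, one reason

All pending units live in FIFO pools holding unit keys, never copies:

* **MAIN** — append-only registration pool; every submission lands here.
* **SECOND** — bulk copy of MAIN, taken by `transfer_all()`.
* **FIRST** — at most `worker_count` units, extracted by
  `extract_batch()`; the only pool the per-cycle assignment loop reads.

The layering exists to decouple assignment cost from queue length: the
assignment loop scans a bounded pool, and the big registration pool is
touched only during rare bulk transfers. The trigger for those
transfers is a genuine design choice (the pattern itself only requires
"from time to time"); we refill **when FIRST has drained and SECOND is
empty** — deterministic, and it provably minimises MAIN accesses to one
bulk move per drained backlog. The consequence, visible in tests, is
that `extract_batch()` refuses to top up a non-empty FIRST.

Global FIFO follows from composition: each pool preserves insertion
order, so units leave FIRST in registration order. Ties between
requests arriving in the same instant are broken by submission id, then
task index.

### Dispatch and completion

`schedule_step()` pairs the oldest FIRST unit with the lowest-id idle
worker until either side runs out, sending `ASSIGN` frames;
`handle_complete()` records the exit code verbatim, frees the worker,
and warns (without state change) on duplicate or misattributed
completions, so assignment is exactly-once by construction. A worker
whose endpoint is unreachable is marked `STOPPED` and its in-flight
unit fails with sentinel exit 255; a command script that cannot be read
fails with 254; `fail_fast` aborts a submission's still-queued units
with 125. Sentinels live in the 126–255/abnormal range so they cannot
collide with an ordinary script's small exit codes, and aborted units
traverse the legal lifecycle (with zero-length timestamps) rather than
jumping states.

### Blocking submission as dependency control

`vge_task()` submits and then blocks until all `max_task` units are
finished, returning the exit-code tibble. Pipeline dependencies need no
DAG language: writing one call after another *is* the dependency
declaration. We chose client-side **polling** (default 0.5 s,
configurable) over a push channel for completion notification: it keeps
the wire protocol to four request/reply pairs and makes the blocking
semantics identical on the in-memory and socket backends. The cost — up
to one poll interval of latency per stage boundary — is negligible
against stage runtimes this tool targets.

A failed unit does **not** raise in `vge_task()`: whether a failed
scatter should stop a pipeline is the pipeline's decision, so the codes
are surfaced and `simple_pipeline()` (by default) skips its second
stage when stage 1 reports failures.

## Transports and executors

All conversations use one frame format: a 4-byte big-endian length
prefix, then UTF-8 JSON with fields `kind`, `correlation_id`, `payload`,
keys sorted recursively so encoding is deterministic. Two carriers are
provided: an in-memory broker (exactly-once, ordered; what tests run
on) and loopback TCP for client–master traffic (`vge_serve()`), with
the submission endpoint bound to `127.0.0.1` because client and master
are assumed to share a node. A third carrier targeting MPI
point-to-point messaging (master at rank 0) would slot behind the same
codec, but no R MPI binding is declared here, so the package ships the
two carriers it can test; backend transparency — identical schedules on
both — is itself a tested property.

Command execution is an executor policy:

* `"shell"` (default): each unit forks a POSIX `sh` via
  `parallel::mcparallel()`, so up to `worker_count` units run
  concurrently; exit codes propagate unaltered.
* `"instant"`: units complete synchronously with exit 0 and zero
  duration. This is for scheduling studies — a 10,000-unit dispatch
  experiment should measure dispatch, not 10,000 process forks. The
  executors are observably identical to the scheduler (same pools, same
  frames, same counts), which is also tested.

## The metadata-server lesson

On Lustre-family file systems every create/remove is a metadata-server
request, and an MDS sustains on the order of 1300 requests/s. A farm
whose W workers each create their own log at launch issues W near-
simultaneous requests — at tens of thousands of workers, an
order-of-magnitude overload (`mds_load_check(20000, 1)`). The package
therefore makes file creation a master-only activity: one log per
worker pre-created by a single actor before any worker starts
(`precreate_logs()`, idempotent so restarts preserve appends), and one
materialized script per *submission*, shared by its units and
parameterized by environment, instead of one per unit. Tests assert the
creation ledger: W log creations, all before the first execution, plus
one script per submission.

## The simulator

`simulate_schedule()` is an event-driven replay of the same policy:
greedy FIFO over requests ordered by effective eligibility (submit
time, or predecessor completion for `depends_on` requests; ties by list
position), with each assignment consuming `overhead` seconds of master
time, serially. The assignment instant is the first moment the master
and some worker are both free; among workers free by that instant the
lowest id wins — matching the order a live master scans its idle list,
so engine and simulator produce identical per-worker counts for the
same workload. Per-assignment overhead is a *parameter*, not a claim:
measured values are hardware-specific, so the simulator asks rather
than asserts. With `overhead = 0` the uniform-workload makespan equals
`ideal_makespan()` exactly, and per-worker counts equal
`rounds_bounds()`.

Degenerate inputs are defined, not special-cased: zero jobs take zero
time; zero-duration jobs with positive overhead serialise entirely on
the master (the master is then the only resource); cyclic `depends_on`
graphs are rejected.

## Synthetic data: what it does and does not emulate

`generate_fastq()` produces strict 4-line FASTQ with the *shape* of a
short-read WGS run — 152 bp, paired-end by default, mate-consistent
identifiers — deterministically per seed, with the caller's RNG state
restored. Bases and qualities are i.i.d.; there is no genome, error
profile, coverage structure or duplicate structure. Passing tests
therefore demonstrate the *plumbing* — record-aligned splitting
(`split_fastq()` concatenates back byte-identically, remainder records
to the front chunks, pairing preserved chunk-by-chunk), dispatch,
dependency ordering — and say nothing about alignment quality, which is
out of scope: the aligner is an opaque command template, stubbed by a
record-count/checksum command so the pipeline is testable offline.

The number of chunks per file is a config parameter with no default
baked into the science: real scatter widths are chosen per machine
(a few chunks per worker is a reasonable start).

## Problem sizes used by the test-suite

The package validates its claims at sizes chosen to exercise every
regime while staying desk-friendly: closed-form/simulator agreement up
to the 100,000-job reference workload; live-engine dispatch runs of
10,000 and 10,007 zero-cost units on 8 workers (exact and non-exact
division); simulator-vs-brute-force-oracle equivalence on randomized
instances with at most 50 units and 8 workers; and one wall-clock run —
64 two-second sleeps on 8 forked workers — asserted to finish within
50% of its 16 s ideal, an intentionally loose bound since it is the
only hardware-dependent assertion in the suite.

## Package shape

Results — unit tables, statuses, timelines, chunk plans, summaries —
are tibbles with `tidy()`, `glance()` and `autoplot()` methods, so they
compose with dplyr/ggplot2 idiom. The engine itself is deliberately
*not* a data frame: pools and worker records need one mutable home with
reference semantics, so `vge_engine()` returns an environment-backed
object that the tibble accessors (`vge_units()`, `vge_workers()`,
`engine_timeline()`) snapshot.

## Known limitations

* No priorities, preemption, per-job resource requests, retries, or
  fair-share — the array-job contract emulated here has none.
* One master, no failover; a lost master loses the queue.
* The socket backend is loopback-oriented and unauthenticated by
  design; it is a same-node submission channel, not a network service.
* Worker concurrency uses `fork()`, i.e. Unix-alikes only.
* The simulator models dispatch and dependencies, not network topology,
  staging, or file-system bandwidth.
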