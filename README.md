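# taskfarm

Grid-engine array-job emulation on a master–worker task farm, in R.

Most large supercomputers schedule only synchronous MPI-style jobs and
provide no grid-engine (SGE/UGE-style) service, yet bioinformatics
pipelines are built almost entirely out of asynchronous *array jobs* —
one command expanded into N independent task instances — with stage
dependencies expressed by submission order. `taskfarm` implements the
middleware pattern that bridges the two worlds, plus a discrete-event
simulator that validates the scheduling behaviour analytically at desk
scale.

## The model

One **master** owns every job's state and three FIFO pools; W **workers**
execute commands and report back:

* a submission is the array-job triple (`command`, `max_task`,
  `basename`) and expands into `max_task` units, each run with
  `VGE_TASK_ID` set to its 1-based index (the `SGE_TASK_ID` analogue);
* units queue in a registration pool (**MAIN**); the master bulk-copies
  MAIN into a local pool (**SECOND**) only when its local pools are
  drained, and refills a worker-count-sized pool (**FIRST**) from
  SECOND — the assignment loop touches only FIRST, which keeps per-job
  master overhead flat as the queue grows;
* `vge_task()` **blocks** until every unit reaches `DONE` or `FAILED`.
  That is the whole dependency mechanism: a later `vge_task()` in a
  pipeline script cannot submit before an earlier one returns;
* worker log files are created by a single actor *before* any worker
  starts — W metadata operations instead of a start-up storm, which is
  what a Lustre-family metadata server (MDS) survives at scale.

For n equal-duration jobs on W workers, greedy FIFO dispatch runs
ceil(n/W) rounds, so the zero-overhead makespan is

    T_ideal = ceil(n / W) * d

and every worker executes floor(n/W) or ceil(n/W) jobs. The simulator
(`simulate_schedule()`) generalises this to mixed durations, staggered
submissions, inter-stage dependencies and a serial per-assignment master
overhead.

## Worked example

Run ten one-second commands on a four-worker farm, then size the large
reference workload analytically:

```r
library(taskfarm)

eng <- vge_engine(farm_config(worker_count = 4, executor = "shell"))
res <- vge_task("sleep 1", max_task = 10, basename = "nap", endpoint = eng)
res
#> # A tibble: 10 × 3
#>    task_index exit_code state
#>         <int>     <int> <chr>
#>  1          1         0 DONE
#>  2          2         0 DONE
#>  ...
#> 10         10         0 DONE

glance(engine_timeline(eng))
#> # A tibble: 1 × 6
#>   n_units n_workers makespan min_per_worker max_per_worker utilization
#>     <int>     <int>    <dbl>          <int>          <int>       <dbl>
#> 1      10         4     3.27              2              3       0.773
```

Ten jobs on four workers is three rounds, so the 3.27 s makespan sits
just above the 3 s ideal; per-worker counts are floor/ceil(10/4) = 2–3.
The same calculators reproduce the behaviour of a production-scale run:
100,000 jobs of 120 s on 1,999 workers take `ideal_makespan(100000,
1999, 120)` = 6120 s (51 rounds), and `rounds_bounds(10000, 1999)`
says every worker in the 10,000-job case runs 5 or 6 jobs.

A two-stage pipeline (scatter a paired-end FASTQ sample, then align
each chunk) in the simulator:

```r
tl <- simulate_schedule(list(
  sim_request(2, 30, label = "fastq_splitter"),
  sim_request(24, 45, depends_on = 1, label = "bwa_align")), n_workers = 8)
glance(tl)
#> # A tibble: 1 × 6
#>   n_units n_workers makespan min_per_worker max_per_worker utilization
#>     <int>     <int>    <dbl>          <int>          <int>       <dbl>
#> 1      26         8      165            3              4         0.864
```

No align unit starts before both splitter units end (30 s); the 24
chunks then take three 45-s rounds: 30 + 135 = 165 s.
`autoplot(tl)` draws the start-time staircase,
`plot_worker_filling(tl)` the per-worker occupancy bars. The live
pipeline equivalent is `simple_pipeline()` (or `run_demo()`), with the
aligner as a pluggable command template — a record-count/checksum stub
by default, `bwa mem ...` by substitution.

The start-up advisor flags metadata bursts: a farm whose workers create
their own logs issues one MDS request per worker nearly at once, and
`mds_load_check(20000, 1)` reports rate 20000 ops/s, `exceeds = TRUE`
against the 1300 ops/s default limit — the motivation for
single-actor log pre-creation (`precreate_logs()`).

A thin CLI wraps the same functions: `exec/vge` with subcommands
`gen`, `split`, `simulate`, `demo`, `start`, `submit`, `status`.

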