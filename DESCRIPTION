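Package: taskfarm
Title: Grid-Engine Array-Job Emulation on a Master-Worker Task Farm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Middleware that emulates grid-engine array-job services on
    machines that provide none: a blocking vge_task() submission call,
    array expansion, FIFO dispatch from a three-tier job pool to a pool of
    workers, and inter-stage dependency control by submission order.
    Includes a discrete-event schedule simulator with closed-form makespan
    and jobs-per-worker calculators, a metadata-server load advisor for
    Lustre-family file systems, and a demonstration scatter pipeline
    (synthetic paired-end FASTQ generation, record-aligned splitting, and
    a pluggable aligner stage). Timelines, statuses and run summaries are
    returned as tibbles with tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    rlang,
    tibble,
    utils,
    yaml
Suggests:
    callr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
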