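#' File-based resumable task queue
#'
#' Tasks are self-contained JSON records living under `workdir/tasks/` in
#' one of four state directories: `pending/`, `running/`, `done/`,
#' `failed/`. The task id is a deterministic hash of the task type and
#' inputs, so re-enqueueing identical work is a no-op and any number of
#' worker processes sharing the directory can divide the queue. Claiming is
#' an atomic `file.rename` from `pending/` to `running/`: on a POSIX
#' filesystem exactly one worker wins. Stale `running` tasks (a crashed
#' worker) are reclaimed after a timeout.
#'
#' @param type task type: `"subset_align"`, `"backbone_align"` or
#'   `"nested_run"`.
#' @param inputs named list of scalar inputs (paths, seeds, parameters).
#' @param output path the task will write.
#' @return a `task` record (list with `task_id`, `type`, `inputs`,
#'   `output`, `attempts`).
#' @export
make_task <- function(type, inputs, output) {
  canonical <- jsonlite::toJSON(list(type = type, inputs = inputs),
                                auto_unbox = TRUE, digits = NA)
  structure(list(task_id = hash_string(as.character(canonical)),
                 type = type, inputs = inputs, output = output,
                 attempts = 0L),
            class = "task")
}

task_dirs <- function(workdir) {
  file.path(workdir, "tasks", c("pending", "running", "done", "failed"))
}

init_task_queue <- function(workdir) {
  for (d in task_dirs(workdir)) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  invisible(workdir)
}

task_file <- function(workdir, state, task_id) {
  file.path(workdir, "tasks", state, paste0(task_id, ".json"))
}

read_task <- function(path) {
  rec <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(list(task_id = rec$task_id, type = rec$type,
                 inputs = as.list(rec$inputs), output = rec$output,
                 attempts = rec$attempts %||% 0L),
            class = "task")
}

write_task <- function(task, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(unclass(task), tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, path)
  invisible(path)
}

#' Enqueue a task (idempotent)
#'
#' A task already pending, running or done is left untouched (a done task's
#' output is simply reused on resume); a failed task is moved back to
#' pending for retry.
#'
#' @param task a [make_task()] record.
#' @param workdir the shared working directory.
#' @return the task id, invisibly.
#' @export
enqueue <- function(task, workdir) {
  init_task_queue(workdir)
  id <- task$task_id
  for (state in c("pending", "running", "done")) {
    if (file.exists(task_file(workdir, state, id))) return(invisible(id))
  }
  failed <- task_file(workdir, "failed", id)
  if (file.exists(failed)) {
    file.rename(failed, task_file(workdir, "pending", id))
    return(invisible(id))
  }
  write_task(task, task_file(workdir, "pending", id))
  invisible(id)
}

#' Claim the next pending task
#'
#' Atomically moves one pending task to `running/` via `file.rename` and
#' returns it; returns `NULL` when nothing is claimable. Running tasks whose
#' file is older than `stale_timeout` seconds are first moved back to
#' pending (crash recovery).
#'
#' @param workdir the shared working directory.
#' @param worker_id identifier recorded in the claimed task file.
#' @param stale_timeout seconds after which a running task is reclaimed.
#' @return a `task` or `NULL`.
#' @export
claim_next <- function(workdir, worker_id = "worker", stale_timeout = 3600) {
  init_task_queue(workdir)
  running_dir <- file.path(workdir, "tasks", "running")
  stale <- list.files(running_dir, full.names = TRUE)
  if (length(stale)) {
    age <- as.numeric(Sys.time()) - as.numeric(file.mtime(stale))
    for (f in stale[age > stale_timeout])
      file.rename(f, file.path(workdir, "tasks", "pending", basename(f)))
  }
  pending <- sort(list.files(file.path(workdir, "tasks", "pending")))
  for (f in pending) {
    src <- task_file(workdir, "pending", sub("\\.json$", "", f))
    dst <- file.path(running_dir, f)
    if (isTRUE(file.rename(src, dst))) {
      task <- read_task(dst)
      task$worker_id <- worker_id
      return(task)
    }
  }
  NULL
}

#' Mark a claimed task done or failed
#'
#' @param task the claimed `task`.
#' @param workdir the shared working directory.
#' @param success did the task produce its output?
#' @return invisibly, the final state directory.
#' @export
complete_task <- function(task, workdir, success) {
  id <- task$task_id
  src <- task_file(workdir, "running", id)
  state <- if (success) "done" else "failed"
  if (!success) {
    task$attempts <- (task$attempts %||% 0L) + 1L
    write_task(task, src)
  }
  file.rename(src, task_file(workdir, state, id))
  invisible(state)
}

log_event <- function(workdir, ...) {
  cat(paste0(paste0(...), "\n"), file = file.path(workdir, "log.txt"), append = TRUE)
}

#' Read the run log of a working directory
#' @param workdir the working directory.
#' @return character vector of log lines (empty if no log yet).
#' @export
read_log <- function(workdir) {
  f <- file.path(workdir, "log.txt")
  if (file.exists(f)) readLines(f) else character(0)
}
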