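#' Configure a divide-and-conquer alignment run
#'
#' Collects every knob of [run_pipeline()] with its default. Defaults follow
#' the method's standard operating point: at most 25 decomposition subsets,
#' 10 backbones of 200 rows, recursion enabled with the threshold set to the
#' greater of the backbone size and the target subset size, and compression
#' only above 100 GB of serialized alignment.
#'
#' @param input path to an unaligned FASTA file, or a named character
#'   vector of sequences.
#' @param workdir working directory (created if needed); holds all task
#'   files and intermediate artifacts and makes the run resumable.
#' @param guide_tree decomposition strategy: `"fallback"` (built-in k-mer NJ
#'   tree), `"random"`, a path to a user Newick file, a `phylo` object, or a
#'   function `(sequences) -> phylo` (e.g. wrapping an external tree
#'   estimator).
#' @param max_num_subsets decomposition width; target subset size is
#'   `ceiling(n / max_num_subsets)`.
#' @param num_backbones,backbone_size backbone sampling parameters.
#' @param aligner base aligner: `"builtin"`, an external command template
#'   (see [external_aligner()]), or a function `(sequences, seed) -> msa`.
#' @param recurse enable nested runs for oversized subsets.
#' @param recursion_threshold user override of the recursion threshold.
#' @param max_recursion_depth hard cap on nesting (error beyond it).
#' @param seed master seed; all randomness derives from it via
#'   [child_seed()] streams.
#' @param compress_threshold serialized-size threshold in bytes above which
#'   the final alignment is compressed (default 1e11 = 100 GB); `Inf`
#'   disables compression.
#' @param lossless_only restrict compression to lossless moves.
#' @param workers number of in-process worker loops dividing the task queue
#'   (additional OS processes can join via [run_worker()]).
#' @param gap_open,gap_extend built-in aligner gap penalties.
#' @param kmer_k k-mer length for the fallback guide tree.
#' @param backbone_paths optional user-supplied, already-aligned backbone
#'   FASTA files used instead of sampled backbones.
#' @param max_tasks execute at most this many tasks then stop (used to
#'   exercise interruption/resume); `Inf` runs to completion.
#' @param stale_timeout seconds before an abandoned running task is
#'   reclaimed.
#' @param instrument optional environment receiving instrumentation fields
#'   (`max_loaded_subalignments`).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, workdir, guide_tree = "fallback",
                            max_num_subsets = 25L, num_backbones = 10L,
                            backbone_size = 200L, aligner = "builtin",
                            recurse = TRUE, recursion_threshold = NULL,
                            max_recursion_depth = 3L, seed = 0L,
                            compress_threshold = 1e11, lossless_only = FALSE,
                            workers = 1L, gap_open = -4, gap_extend = -1,
                            kmer_k = NULL, backbone_paths = NULL,
                            max_tasks = Inf, stale_timeout = 3600,
                            instrument = NULL) {
  if (max_num_subsets < 1L || num_backbones < 0L || backbone_size < 1L ||
      workers < 1L || max_recursion_depth < 0L)
    config_error("non-positive pipeline parameter")
  structure(as.list(environment()), class = "pipeline_config", depth = 0L)
}

#' Align a dataset with the divide-and-conquer pipeline
#'
#' Runs the full method: guide tree, centroid edge decomposition, per-subset
#' alignment (base aligner or nested run, per the recursion threshold),
#' backbone sampling and alignment, alignment-graph construction, Markov
#' clustering, trace ordering, assembly, and (if over the size threshold)
#' compression. All work units go through the resumable file-based task
#' queue; re-invoking on a completed working directory returns the existing
#' output without re-executing anything, and an interrupted run continues
#' where it stopped. Output is deterministic for a fixed seed, independent
#' of the number of workers and of interruptions.
#'
#' @param config a [pipeline_config()].
#' @return list with `alignment` (the final `msa`), `path` (final FASTA),
#'   and `workdir`; or `NULL` invisibly if `max_tasks` stopped the run
#'   before completion.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  wd <- config$workdir
  dir.create(file.path(wd, "output"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(wd, "input"), showWarnings = FALSE)
  dir.create(file.path(wd, "subalignments"), showWarnings = FALSE)
  dir.create(file.path(wd, "backbones"), showWarnings = FALSE)
  dir.create(file.path(wd, "graph"), showWarnings = FALSE)
  init_task_queue(wd)
  out_path <- file.path(wd, "output", "final.fasta")
  if (file.exists(out_path)) {
    log_event(wd, "resume: final output already present, nothing to do")
    return(list(alignment = read_fasta(out_path, aligned = TRUE),
                path = out_path, workdir = wd))
  }

  # input sequences (persisted copy is authoritative on resume)
  in_path <- file.path(wd, "input", "unaligned.fasta")
  if (!file.exists(in_path)) {
    seqs <- if (is.character(config$input) && length(config$input) == 1L &&
                is.null(names(config$input))) {
      read_fasta(config$input, aligned = FALSE)
    } else validate_sequences(config$input)
    write_fasta(seqs, in_path)
  } else {
    seqs <- read_fasta(in_path, aligned = FALSE)
  }
  n <- length(seqs)
  plan <- make_plan(n, config$max_num_subsets, config$backbone_size,
                    config$recursion_threshold, config$recurse)
  aligner <- resolve_aligner(config$aligner, config$gap_open, config$gap_extend)

  subsets <- get_decomposition(seqs, plan, config)
  k <- length(subsets)
  log_event(wd, "decomposition: ", k, " subsets, target size ",
            plan$target_subset_size, ", recursion threshold ",
            plan$recursion_threshold)

  if (k == 1L) {
    # nothing to merge: the base aligner handles the whole (small) dataset
    aln <- aligner(seqs, seed = child_seed(config$seed, 1L))
    return(finalize_output(aln, config, out_path))
  }

  sub_paths <- enqueue_subset_tasks(seqs, subsets, plan, config)
  bb_paths <- enqueue_backbone_tasks(seqs, subsets, config)

  done <- run_task_loop(wd, config, aligner)
  if (!done) {
    log_event(wd, "stopped after max_tasks; run again to resume")
    return(invisible(NULL))
  }

  merged <- merge_subalignments(sub_paths, bb_paths, config)
  finalize_output(merged, config, out_path)
}

get_decomposition <- function(seqs, plan, config) {
  wd <- config$workdir
  decomp_file <- file.path(wd, "decomposition.json")
  if (file.exists(decomp_file))
    return(jsonlite::fromJSON(decomp_file, simplifyVector = FALSE) |>
             lapply(unlist))
  ids <- names(seqs)
  gt <- config$guide_tree
  subsets <- if (identical(gt, "random")) {
    random_decomposition(ids, plan$target_subset_size, child_seed(config$seed, 101L))
  } else {
    tree <- if (inherits(gt, "phylo")) gt
            else if (is.function(gt)) gt(seqs)
            else if (identical(gt, "fallback"))
              build_fallback_tree(seqs, k = config$kmer_k,
                                  seed = child_seed(config$seed, 100L))
            else parse_newick(gt)
    if (!setequal(tree$tip.label, ids))
      data_error("guide tree leaves do not match the dataset ids")
    write_newick(tree, file.path(wd, "input", "tree.nwk"))
    centroid_edge_decompose(tree, plan$target_subset_size)
  }
  subsets <- lapply(subsets, function(s) ids[ids %in% s])  # stable row order
  tmp <- paste0(decomp_file, ".tmp")
  jsonlite::write_json(subsets, tmp)
  file.rename(tmp, decomp_file)
  subsets
}

enqueue_subset_tasks <- function(seqs, subsets, plan, config) {
  wd <- config$workdir
  out_paths <- character(length(subsets))
  for (i in seq_along(subsets)) {
    fin <- file.path(wd, "input", sprintf("subset_%03d.fasta", i))
    if (!file.exists(fin)) write_fasta(seqs[subsets[[i]]], fin)
    fout <- file.path(wd, "subalignments", sprintf("subset_%03d.fasta", i))
    out_paths[i] <- fout
    size <- length(subsets[[i]])
    if (should_recurse(size, plan)) {
      if (attr(config, "depth") >= config$max_recursion_depth)
        config_error("recursion depth cap (", config$max_recursion_depth,
                     ") exceeded; raise max_recursion_depth or the threshold")
      log_event(wd, "recursion: subset ", i, " (", size,
                " sequences) will be aligned by a nested run")
      task <- make_task("nested_run",
                        list(fasta = fin,
                             nested_workdir = file.path(wd, "nested",
                                                        sprintf("subset_%03d", i)),
                             seed = child_seed(config$seed, i)),
                        fout)
    } else {
      task <- make_task("subset_align",
                        list(fasta = fin, seed = child_seed(config$seed, i)),
                        fout)
    }
    enqueue(task, wd)
  }
  out_paths
}

enqueue_backbone_tasks <- function(seqs, subsets, config) {
  wd <- config$workdir
  if (!is.null(config$backbone_paths)) {
    out <- character(length(config$backbone_paths))
    for (b in seq_along(config$backbone_paths)) {
      out[b] <- file.path(wd, "backbones", sprintf("user_%03d.fasta", b))
      if (!file.exists(out[b])) file.copy(config$backbone_paths[b], out[b])
    }
    return(out)
  }
  if (config$num_backbones == 0L) return(character(0))
  samples <- sample_backbones(subsets, config$num_backbones,
                              config$backbone_size,
                              child_seed(config$seed, 500L))
  out <- character(length(samples))
  for (b in seq_along(samples)) {
    fin <- file.path(wd, "input", sprintf("backbone_%03d.fasta", b))
    if (!file.exists(fin)) write_fasta(seqs[samples[[b]]$id], fin)
    fout <- file.path(wd, "backbones", sprintf("backbone_%03d.fasta", b))
    out[b] <- fout
    enqueue(make_task("backbone_align",
                      list(fasta = fin, seed = child_seed(config$seed, 600L + b)),
                      fout),
            wd)
  }
  out
}

execute_task <- function(task, config, aligner) {
  if (task$type %in% c("subset_align", "backbone_align")) {
    seqs <- read_fasta(task$inputs$fasta, aligned = FALSE)
    aln <- if (length(seqs) == 1L) msa(seqs)
           else aligner(seqs, seed = task$inputs$seed)
    check_aligner_output(aln, seqs)
    tmp <- paste0(task$output, ".tmp")
    write_fasta(aln, tmp)
    file.rename(tmp, task$output)
  } else if (task$type == "nested_run") {
    child <- config
    child$input <- task$inputs$fasta
    child$workdir <- task$inputs$nested_workdir
    child$seed <- task$inputs$seed
    child$workers <- 1L
    child$max_tasks <- Inf
    child$compress_threshold <- Inf   # only the top level compresses
    attr(child, "depth") <- attr(config, "depth") + 1L
    res <- run_pipeline(child)
    file.copy(res$path, paste0(task$output, ".tmp"), overwrite = TRUE)
    file.rename(paste0(task$output, ".tmp"), task$output)
  } else {
    stop_gcm("unknown task type: ", task$type, class = "gcmalign_task_error")
  }
  invisible(TRUE)
}

# round-robin in-process worker loop; returns TRUE iff the queue drained
run_task_loop <- function(wd, config, aligner, max_retries = 2L) {
  executed <- 0L
  repeat {
    claimed_any <- FALSE
    for (w in seq_len(config$workers)) {
      if (executed >= config$max_tasks) return(FALSE)
      task <- claim_next(wd, worker_id = paste0("worker", w),
                         stale_timeout = config$stale_timeout)
      if (is.null(task)) next
      claimed_any <- TRUE
      ok <- tryCatch({ execute_task(task, config, aligner); TRUE },
                     error = function(e) {
                       log_event(wd, "task ", task$task_id, " failed: ",
                                 conditionMessage(e))
                       FALSE
                     })
      complete_task(task, wd, ok)
      executed <- executed + 1L
      log_event(wd, "task ", task$task_id, " (", task$type, ") ",
                if (ok) "executed" else "FAILED", " by worker", w)
    }
    if (!claimed_any) break
  }
  # retry failures a bounded number of times
  failed_dir <- file.path(wd, "tasks", "failed")
  failed <- list.files(failed_dir, full.names = TRUE)
  if (length(failed)) {
    tasks <- lapply(failed, read_task)
    retryable <- vapply(tasks, function(t) t$attempts <= max_retries, logical(1))
    if (any(retryable)) {
      for (t in tasks[retryable]) enqueue(t, wd)
      return(run_task_loop(wd, config, aligner, max_retries))
    }
    stop_gcm("pipeline failed: task(s) ",
             paste(vapply(tasks, `[[`, "", "task_id"), collapse = ", "),
             " exhausted retries", class = "gcmalign_pipeline_error")
  }
  TRUE
}

merge_subalignments <- function(sub_paths, bb_paths, config) {
  wd <- config$workdir
  store <- subalignment_store(sub_paths)
  graph <- build_graph(store, as.list(bb_paths))
  write_graph_edgelist(graph, file.path(wd, "graph", "graph.txt"))
  clusters <- mcl_cluster(graph)
  valid <- enforce_cluster_validity(clusters, graph)
  write_clusters(valid, graph, file.path(wd, "graph", "clusters.txt"))
  trace <- order_clusters(valid, graph)
  merged <- assemble(trace, store, graph)
  if (is.environment(config$instrument))
    config$instrument$max_loaded_subalignments <- store_max_loaded(store)
  log_event(wd, "merge: ", length(trace), " output columns from ",
            sum(graph$n_cols), " subalignment columns")
  merged
}

finalize_output <- function(aln, config, out_path) {
  wd <- config$workdir
  if (is.finite(config$compress_threshold) &&
      estimate_size(aln) > config$compress_threshold) {
    res <- compress_alignment(aln, config$compress_threshold,
                              config$lossless_only)
    aln <- res$alignment
    jsonlite::write_json(res$report, file.path(wd, "output",
                                               "compression_report.json"),
                         auto_unbox = TRUE, digits = NA)
    log_event(wd, "compression: ", res$report$columns_dissolved,
              " columns dissolved, ", res$report$pairs_lost, " pairs lost")
  }
  tmp <- paste0(out_path, ".tmp")
  write_fasta(aln, tmp)
  file.rename(tmp, out_path)
  log_event(wd, "pipeline complete: ", out_path)
  list(alignment = aln, path = out_path, workdir = wd)
}

#' Run a standalone worker loop on a shared working directory
#'
#' Lets additional OS processes join a run started elsewhere: the worker
#' claims and executes tasks until the queue is empty. The coordinating
#' [run_pipeline()] call performs the merge once all tasks are done.
#'
#' @param workdir the shared working directory of a live run.
#' @param config the run's [pipeline_config()] (for aligner settings).
#' @param worker_id label recorded in the log.
#' @return number of tasks executed, invisibly.
#' @export
run_worker <- function(workdir, config, worker_id = "extworker") {
  aligner <- resolve_aligner(config$aligner, config$gap_open, config$gap_extend)
  executed <- 0L
  repeat {
    task <- claim_next(workdir, worker_id, stale_timeout = config$stale_timeout)
    if (is.null(task)) break
    ok <- tryCatch({ execute_task(task, config, aligner); TRUE },
                   error = function(e) FALSE)
    complete_task(task, workdir, ok)
    executed <- executed + 1L
  }
  invisible(executed)
}
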