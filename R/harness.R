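#' Enumerate cross-subject transfer tasks
#'
#' M2S (multi-source to single-target) produces one task per subject, with
#' the remaining `C - 1` subjects pooled as the source field; S2S
#' (single-source to single-target) produces all `C (C - 1)` ordered pairs.
#' Enumeration is exhaustive and deterministic: subjects are taken in sorted
#' id order, so the plan does not depend on the order the data happens to
#' arrive in.
#'
#' @param subject_ids Character vector of at least two subject ids.
#' @param mode `"m2s"` or `"s2s"`.
#' @return A tibble of class `task_plan` with columns `task_id`, `mode`,
#'   `target_id`, `source_ids` (list column).
#' @examples
#' plan_tasks(c("s1", "s2", "s3"), "s2s")
#' @export
plan_tasks <- function(subject_ids, mode = c("m2s", "s2s")) {
  mode <- match.arg(mode)
  ids <- sort(unique(as.character(subject_ids)))
  if (length(ids) < 2L) {
    stop("need at least 2 subjects to build transfer tasks", call. = FALSE)
  }
  if (mode == "m2s") {
    plan <- tibble::tibble(
      target_id = ids,
      source_ids = lapply(ids, function(t) setdiff(ids, t))
    )
  } else {
    pairs <- expand.grid(source = ids, target = ids,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
    pairs <- pairs[order(pairs$target, pairs$source), , drop = FALSE]
    plan <- tibble::tibble(
      target_id = pairs$target,
      source_ids = as.list(pairs$source)
    )
  }
  plan <- tibble::tibble(
    task_id = paste0(mode, ":", vapply(plan$source_ids, paste,
                                       character(1), collapse = "+"),
                     "->", plan$target_id),
    mode = mode,
    target_id = plan$target_id,
    source_ids = plan$source_ids
  )
  class(plan) <- c("task_plan", class(plan))
  plan
}

# epoch_set list -> per-subject tangent features, via the full front end
.features_for_subjects <- function(data, params, band = NULL,
                                   band_order = 50, shrinkage = 0) {
  names(data) <- vapply(data, `[[`, character(1), "subject_id")
  lapply(data, function(e) {
    if (!is.null(band)) {
      e <- bandpass_epochs(e, band[1], band[2], order = band_order)
    }
    s <- estimate_covariances(e, normalize = TRUE, shrinkage = shrinkage)
    if (identical(params$alignment_space, "none")) {
      # ablation branch: features in each subject's raw coordinates
      suppressWarnings(tangent_map(s, reference = "identity"))
    } else {
      tangent_map(align_subject(s, params$alignment_space),
                  reference = "identity")
    }
  })
}

#' Run a cross-subject evaluation plan
#'
#' Per subject: optional zero-phase FIR band-pass, covariance estimation,
#' centroid alignment (unless disabled), tangent features at the identity.
#' Per task: pool the source subjects' features, fit FARKA, predict the
#' target field, score accuracy against the held-back target labels. A task
#' that fails raises a warning and is recorded with `NA` accuracy; the run
#' continues. Everything is deterministic given the data and parameters.
#'
#' @param data List of [epoch_set()] objects covering every subject in the
#'   plan.
#' @param plan A [plan_tasks()] tibble.
#' @param params A [farka_params()].
#' @param band Optional length-2 numeric `c(lo_hz, hi_hz)` band-pass edges.
#' @param band_order FIR order when `band` is set.
#' @param shrinkage Covariance shrinkage in `[0, 1)`.
#' @return An object of class `farka_eval`: list with `tasks` (tibble of
#'   `task_id`, `mode`, `target_id`, `n_source`, `n_target`, `accuracy`),
#'   `mean_accuracy`, `params`, and `warnings`.
#' @examples
#' pop <- make_population(population_spec(n_subjects = 3,
#'   n_epochs_per_class = 8, ch = 4, n_samples = 128, seed = 2))
#' run_plan(pop, plan_tasks(c("s1", "s2", "s3"), "m2s"),
#'          farka_params(kernel = kernel_spec("linear")))
#' @export
run_plan <- function(data, plan, params = farka_params(), band = NULL,
                     band_order = 50, shrinkage = 0) {
  stopifnot(inherits(plan, "task_plan"), inherits(params, "farka_params"))
  ids <- vapply(data, `[[`, character(1), "subject_id")
  missing_ids <- setdiff(unique(c(plan$target_id, unlist(plan$source_ids))), ids)
  if (length(missing_ids) > 0L) {
    stop(sprintf("plan subjects absent from data: %s",
                 paste(missing_ids, collapse = ", ")), call. = FALSE)
  }
  feats <- .features_for_subjects(data, params, band, band_order, shrinkage)

  warns <- character(0)
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    src_ids <- plan$source_ids[[i]]
    tgt_id <- plan$target_id[i]
    acc <- tryCatch({
      src <- pool_features(feats[src_ids],
                           subject_id = paste(src_ids, collapse = "+"))
      tgt <- feats[[tgt_id]]
      model <- farka_fit(src, tgt, params)
      accuracy_score(predict(model), tgt$labels)
    }, error = function(err) {
      msg <- sprintf("task %s failed: %s", plan$task_id[i],
                     conditionMessage(err))
      warns <<- c(warns, msg)
      warning(msg, call. = FALSE)
      NA_real_
    })
    tibble::tibble(
      task_id = plan$task_id[i], mode = plan$mode[i], target_id = tgt_id,
      n_source = sum(vapply(feats[src_ids],
                            function(f) nrow(f$vectors), integer(1))),
      n_target = nrow(feats[[tgt_id]]$vectors),
      accuracy = acc
    )
  })
  tasks <- dplyr::bind_rows(rows)
  structure(
    list(tasks = tasks,
         mean_accuracy = mean(tasks$accuracy, na.rm = TRUE),
         params = params, warnings = warns),
    class = "farka_eval"
  )
}

#' @export
print.farka_eval <- function(x, ...) {
  cat(sprintf("<farka_eval> %d tasks (%s), mean accuracy %.4f\n",
              nrow(x$tasks), x$tasks$mode[1], x$mean_accuracy))
  print(x$tasks)
  if (length(x$warnings) > 0) {
    cat(sprintf("%d task warning(s)\n", length(x$warnings)))
  }
  invisible(x)
}

#' @rdname run_plan
#' @param x A `farka_eval`.
#' @param ... Unused.
#' @export
tidy.farka_eval <- function(x, ...) x$tasks

#' @rdname run_plan
#' @export
glance.farka_eval <- function(x, ...) {
  tibble::tibble(
    n_tasks = nrow(x$tasks),
    mode = x$tasks$mode[1],
    mean_accuracy = x$mean_accuracy,
    n_failed = sum(is.na(x$tasks$accuracy)),
    mu = x$params$mu, eta = x$params$eta,
    kernel = x$params$kernel$family,
    alignment = if (identical(x$params$alignment_space, "none")) "none"
                else x$params$alignment_space$space
  )
}

#' Hyperparameter sweep over a task plan
#'
#' Evaluates [run_plan()] on the cartesian product of the supplied grid
#' axes. Recognised axes: `mu`, `eta`, `kernel` (family names), `gamma`.
#' A one-point grid reduces to a single [run_plan()] call.
#'
#' @param data,plan,base_params,band,band_order,shrinkage As in
#'   [run_plan()].
#' @param grid Named list of vectors, e.g.
#'   `list(mu = seq(1, 5, 0.5))` or `list(eta = 1:15)`.
#' @return A tibble of class `farka_sweep`: one row per grid point with the
#'   swept parameter values, `mean_accuracy`, and the full `farka_eval` in
#'   the `report` list column. Rows follow the deterministic
#'   cartesian-product order of the grid.
#' @examples
#' pop <- make_population(population_spec(n_subjects = 2,
#'   n_epochs_per_class = 8, ch = 4, n_samples = 128, seed = 3))
#' sweep_farka(pop, plan_tasks(c("s1", "s2"), "s2s"),
#'             grid = list(mu = c(1, 2)),
#'             base_params = farka_params(kernel = kernel_spec("linear")))
#' @export
sweep_farka <- function(data, plan, grid, base_params = farka_params(),
                        band = NULL, band_order = 50, shrinkage = 0) {
  stopifnot(is.list(grid), length(grid) > 0, !is.null(names(grid)),
            all(names(grid) %in% c("mu", "eta", "kernel", "gamma")),
            all(lengths(grid) > 0))
  cells <- do.call(tidyr::expand_grid, grid)
  reports <- lapply(seq_len(nrow(cells)), function(i) {
    p <- base_params
    row <- cells[i, , drop = FALSE]
    if ("mu" %in% names(row)) p$mu <- row$mu
    if ("eta" %in% names(row)) p$eta <- row$eta
    if ("kernel" %in% names(row)) p$kernel$family <- row$kernel
    if ("gamma" %in% names(row)) p$kernel$gamma <- row$gamma
    run_plan(data, plan, p, band = band, band_order = band_order,
             shrinkage = shrinkage)
  })
  out <- dplyr::mutate(
    cells,
    mean_accuracy = vapply(reports, `[[`, numeric(1), "mean_accuracy"),
    report = reports
  )
  class(out) <- c("farka_sweep", class(out))
  out
}

#' @rdname sweep_farka
#' @param x A `farka_sweep`.
#' @param ... Unused.
#' @export
tidy.farka_sweep <- function(x, ...) {
  cells <- dplyr::select(tibble::as_tibble(x), -"report", -"mean_accuracy")
  dplyr::bind_rows(lapply(seq_len(nrow(x)), function(i) {
    dplyr::bind_cols(cells[i, ], x$report[[i]]$tasks)
  }))
}

#' @rdname sweep_farka
#' @export
glance.farka_sweep <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -"report")
}
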