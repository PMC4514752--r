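#' Generate seeded docking models for a synthetic complex
#'
#' Runs `n_models` independent placement + refinement pipelines with
#' per-model seeds derived from `seed`, returning one row per model. This
#' is the unit of work that the success-rate benchmarking resamples.
#'
#' @param cx A [make_synthetic_complex()] result.
#' @param n_models Number of models.
#' @param algorithm Placement algorithm: `"transform"` or `"transrot"`.
#' @param refine Refinement schedule: `"min"`, `"mcm"` or `"none"`.
#' @param seed Master seed; model `j` uses `seed * 1000 + j` (kept well
#'   inside the 32-bit integer range by the callers' small master seeds).
#' @param params [fa_params()].
#' @return `data.frame` with columns `model_id`, `algorithm`, `refine`,
#'   `seed`, `grid_score`, `fa_score`, `rmsd`, `flags`; the refined poses
#'   are attached as attribute `"poses"`.
#' @export
generate_models <- function(cx, n_models, algorithm = c("transform", "transrot"),
                            refine = c("min", "mcm", "none"), seed = 1,
                            params = fa_params()) {
  algorithm <- match.arg(algorithm)
  refine <- match.arg(refine)
  stopifnot(inherits(cx, "synthetic_complex"), n_models >= 1)
  rcfg <- if (refine != "none") refinement_config(refine) else NULL
  poses <- vector("list", n_models)
  rows <- vector("list", n_models)
  for (j in seq_len(n_models)) {
    sj <- (as.integer(seed) %% 1000000L) * 1000L + j
    p <- place_ligand(cx$ligand, cx$receptor, cx$grid, algorithm,
                      cx$cfg, params, seed = sj)
    gs <- p$grid_score
    if (refine != "none") {
      p <- refine_pose(p, cx$receptor, params, rcfg)
    } else if (is.na(p$fa_score)) {
      p$fa_score <- fa_score(p, cx$receptor, params)
    }
    p$rmsd <- ligand_rmsd(cx$native_heavy, heavy_coords(cx$ligand, p$coords))
    poses[[j]] <- p
    rows[[j]] <- data.frame(
      model_id = j, algorithm = algorithm, refine = refine, seed = sj,
      grid_score = gs, fa_score = p$fa_score, rmsd = p$rmsd,
      flags = paste(p$flags, collapse = ";"))
  }
  out <- do.call(rbind, rows)
  attr(out, "poses") <- poses
  out
}

#' Success-rate benchmark over model budgets
#'
#' For each synthetic complex, generates a pool of `n_models` docking
#' models (placement + refinement), then estimates, for each model budget
#' `k`, the probability that the budget succeeds: `n_resamples` random
#' subsamples of size `k` are drawn from the pool, each subsample's
#' lowest-`fa_score` model is selected, and the subsample succeeds when
#' that model's RMSD to the native pose is below `threshold`. The reported
#' curve is the mean and standard deviation, over resamples, of the
#' success fraction across complexes.
#'
#' @param complexes List of [make_synthetic_complex()] results.
#' @param algorithm,refine Protocol (see [generate_models()]).
#' @param n_models Pool size per complex (must cover the largest budget).
#' @param budgets Integer vector of model budgets (default
#'   `c(10, 25, 50, 100, 150)`, bracketing the ~150-model convergence
#'   point of the grid-scored Monte Carlo protocol).
#' @param threshold Success RMSD threshold, Angstrom (default 2.0).
#' @param n_resamples Random subsamples per budget (default 20).
#' @param seed Master seed.
#' @param params [fa_params()].
#' @return An object of class `benchmark_summary`: `models` (per-model
#'   table over all complexes), `curve` (budget, mean_success, sd_success),
#'   plus the protocol metadata.
#' @export
run_benchmark <- function(complexes, algorithm = c("transform", "transrot"),
                          refine = c("min", "mcm", "none"),
                          n_models = 150, budgets = c(10, 25, 50, 100, 150),
                          threshold = 2.0, n_resamples = 20, seed = 1,
                          params = fa_params()) {
  algorithm <- match.arg(algorithm)
  refine <- match.arg(refine)
  if (inherits(complexes, "synthetic_complex")) complexes <- list(complexes)
  if (n_models < max(budgets)) {
    stop("n_models must be at least the largest budget", call. = FALSE)
  }
  models <- do.call(rbind, lapply(seq_along(complexes), function(ci) {
    m <- generate_models(complexes[[ci]], n_models, algorithm, refine,
                         seed = seed * 100 + ci, params = params)
    attr(m, "poses") <- NULL
    cbind(complex_id = ci, m)
  }))

  set.seed(seed)
  curve <- do.call(rbind, lapply(budgets, function(k) {
    fracs <- vapply(seq_len(n_resamples), function(r) {
      succ <- vapply(seq_along(complexes), function(ci) {
        mm <- models[models$complex_id == ci, ]
        pick <- if (k >= nrow(mm)) seq_len(nrow(mm)) else sample.int(nrow(mm), k)
        sub <- mm[pick, ]
        sub$rmsd[which.min(sub$fa_score)] < threshold
      }, TRUE)
      mean(succ)
    }, 0)
    data.frame(budget = k, mean_success = mean(fracs), sd_success = stats::sd(fracs))
  }))
  structure(list(models = models, curve = curve, algorithm = algorithm,
                 refine = refine, threshold = threshold,
                 n_resamples = n_resamples, seed = seed),
            class = "benchmark_summary")
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat(sprintf("benchmark_summary: %s/%s, %d complex(es), threshold %.1f A\n",
              x$algorithm, x$refine, length(unique(x$models$complex_id)),
              x$threshold))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a benchmark summary into its success curve
#'
#' @param x A [run_benchmark()] result.
#' @param ... Unused.
#' @return The success-curve `data.frame` with protocol columns attached.
#' @export
tidy.benchmark_summary <- function(x, ...) {
  cbind(x$curve, algorithm = x$algorithm, refine = x$refine)
}

#' One-row overview of a benchmark summary
#'
#' @param x A [run_benchmark()] result.
#' @param ... Unused.
#' @return A one-row `data.frame`: protocol, number of complexes, success
#'   at the largest budget, fraction of all models under the threshold.
#' @export
glance.benchmark_summary <- function(x, ...) {
  data.frame(algorithm = x$algorithm, refine = x$refine,
             n_complexes = length(unique(x$models$complex_id)),
             n_models = nrow(x$models),
             success_at_max_budget = x$curve$mean_success[nrow(x$curve)],
             frac_models_under_threshold = mean(x$models$rmsd < x$threshold))
}

#' Fraction of sampled states near the native pose
#'
#' Sampling-enrichment measure for comparing the placement algorithms: the
#' fraction of all states visited during placement whose RMSD to the
#' native pose is below `threshold`. States are the per-cycle poses of the
#' Monte Carlo sampler (the `rmsd` column of its trajectory) or the logged
#' proposal RMSDs of the legacy protocol (see [make_state_log()]).
#'
#' @param trajectories A list of numeric RMSD vectors, `mc_trajectory`
#'   data.frames, or state logs.
#' @param threshold RMSD threshold, Angstrom (default 2.0).
#' @return Fraction in `[0, 1]`.
#' @export
sampling_enrichment <- function(trajectories, threshold = 2.0) {
  if (!is.list(trajectories) || inherits(trajectories, "data.frame")) {
    trajectories <- list(trajectories)
  }
  rmsds <- unlist(lapply(trajectories, function(tr) {
    if (is.environment(tr)) tr$rmsd
    else if (is.data.frame(tr)) tr$rmsd
    else as.numeric(tr)
  }))
  rmsds <- rmsds[!is.na(rmsds)]
  if (length(rmsds) == 0) stop("no sampled states supplied", call. = FALSE)
  mean(rmsds < threshold)
}

#' Plot a benchmark success curve
#'
#' Success fraction versus model budget with a +/- 1 sd ribbon over the
#' random subsamples.
#'
#' @param object A [run_benchmark()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.benchmark_summary <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(x = .data$budget, y = .data$mean_success)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(0, .data$mean_success - .data$sd_success),
      ymax = pmin(1, .data$mean_success + .data$sd_success)), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "models generated",
      y = sprintf("fraction of complexes docked < %.1f Å", object$threshold),
      title = sprintf("%s/%s success vs model budget", object$algorithm,
                      object$refine))
}

#' Plot a Monte Carlo placement trajectory
#'
#' Current grid score per cycle, with accepted proposals marked.
#'
#' @param object An `mc_trajectory` from [transform_place()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mc_trajectory <- function(object, ...) {
  df <- as.data.frame(object)
  df <- df[is.finite(df$current_score), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle, y = .data$current_score)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = df[df$accepted, ], size = 0.6,
                        ggplot2::aes(color = .data$move)) +
    ggplot2::labs(x = "cycle", y = "grid score", color = "move")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
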