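#' Compute the full regularization path by generalized boosted lasso
#'
#' Approximates the whole family of solutions of the penalized Poisson
#' objective `J(phi; t) = L(phi) + t * sum_i phi_i^p` as the sparsity weight
#' `t` decreases from its largest informative value down to 0, using
#' fixed-size coordinate steps of `epsilon` RPKM. Forward stage-wise steps
#' that minimize `L` alternate with backward corrections whenever a `+/-
#' epsilon` move lowers `J` at the current `t` by more than `xi`; `t` is
#' relaxed only on forward steps, by the ratio of fit improvement to penalty
#' increase, so the recorded `t` sequence is non-increasing. The path takes
#' roughly `O(1/epsilon)` steps and is fully deterministic (ties go to the
#' smallest candidate index).
#'
#' At the largest `t` exactly one isoform is active; as `t` shrinks the model
#' grows towards the unpenalized maximum-likelihood fit. Genes with no reads
#' at all yield a degenerate single-point path with the empty model.
#'
#' @param obs An [build_design()] result.
#' @param epsilon Step size in RPKM (default 0.1).
#' @param xi Descent tolerance (default 1e-10).
#' @param p Penalty exponent in (0, 1] (default 0.5).
#' @param max_iters Safety cap on iterations (default 200000).
#' @param keep_phi Keep the full iterate matrix (rows = path points)? Default
#'   `TRUE`; turn off to bound memory on large genes — the per-model-size
#'   best solutions needed for model selection are always retained.
#' @return A `solution_path`: list with `points` (tibble `k`, `t`, `L`, `J`,
#'   `h`, `step_kind`), `phi` (iterate matrix or `NULL`), `group_best`
#'   (tibble `h`, `k`, `t`, `L` with `phi` list column: the minimal-`L`
#'   solution at each model size), `terminated_by`, and the settings used.
#' @export
blasso_path <- function(obs, epsilon = 0.1, xi = 1e-10, p = 0.5,
                        max_iters = 200000L, keep_phi = TRUE) {
  stopifnot(inherits(obs, "observation_set"))
  if (epsilon <= 0) abort("epsilon must be positive")
  if (xi < 0) abort("xi must be non-negative")
  if (p <= 0 || p > 1) abort("p must lie in (0, 1]")

  res <- blasso_path_cpp(obs$A, obs$events$count, epsilon, xi, p,
                         as.integer(max_iters), LAMBDA_FLOOR, keep_phi)
  points <- tibble(
    k = seq_along(res$t) - 1L,
    t = res$t, L = res$L, J = res$J, h = res$h,
    step_kind = ifelse(res$kind > 0, "forward", "backward")
  )
  group_best <- tibble(
    h = res$group_h, k = res$group_k, t = res$group_t, L = res$group_L,
    phi = lapply(seq_along(res$group_h),
                 function(g) res$group_phi[g, , drop = TRUE])
  )
  if (res$terminated_by == "max_iters") {
    warn("regularization path hit max_iters before t reached 0")
  }
  structure(
    list(points = points, phi = res$phi, group_best = group_best,
         terminated_by = res$terminated_by,
         epsilon = epsilon, xi = xi, p = p, n = obs$n),
    class = "solution_path"
  )
}

#' @export
print.solution_path <- function(x, ...) {
  cat("<solution_path> ", nrow(x$points) - 1L, " steps over ", x$n,
      " candidates (p = ", x$p, ", epsilon = ", x$epsilon, ")\n",
      "  t: ", format(max(x$points$t)), " -> ", format(min(x$points$t)),
      "; model sizes visited: ",
      paste(sort(unique(x$points$h)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Summarize a solution path
#'
#' @param path A [blasso_path()] result.
#' @return A list with the iteration count `K`, forward/backward step counts,
#'   the `t` range, termination reason, and a tibble `first_seen` giving the
#'   first iteration at which each model size appears.
#' @export
path_diagnostics <- function(path) {
  stopifnot(inherits(path, "solution_path"))
  pts <- path$points
  first_seen <- pts |>
    dplyr::filter(.data$h > 0) |>
    dplyr::group_by(.data$h) |>
    dplyr::summarise(k = min(.data$k), .groups = "drop")
  list(
    K = nrow(pts) - 1L,
    n_forward = sum(pts$step_kind == "forward"),
    n_backward = sum(pts$step_kind == "backward"),
    t_max = max(pts$t), t_min = min(pts$t),
    terminated_by = path$terminated_by,
    first_seen = first_seen
  )
}

#' @export
tidy.solution_path <- function(x, ...) {
  x$points
}

#' @export
glance.solution_path <- function(x, ...) {
  tibble(
    K = nrow(x$points) - 1L,
    n_candidates = x$n,
    t_max = max(x$points$t),
    t_min = min(x$points$t),
    max_model_size = max(x$points$h),
    terminated_by = x$terminated_by,
    epsilon = x$epsilon,
    p = x$p
  )
}
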