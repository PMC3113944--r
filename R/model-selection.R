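#' Group a solution path by model size
#'
#' Solutions along the path are grouped by the number of expressed isoforms
#' (positive entries); within each group the point with minimal negative
#' log-likelihood `L` is the group's best representative (ties go to the
#' earliest iteration).
#'
#' @param path A [blasso_path()] result.
#' @return A tibble with one row per model size `h` present in the path:
#'   columns `h`, `k`, `t`, `L` and a `phi` list column, ordered by
#'   increasing `h`. A path that only ever visits the empty model yields
#'   zero rows.
#' @export
group_path <- function(path) {
  stopifnot(inherits(path, "solution_path"))
  if (is.null(path$phi)) {
    return(dplyr::arrange(path$group_best, .data$h))
  }
  # recompute from the recorded iterates (equivalent to the running
  # per-size bookkeeping kept during the path computation)
  pts <- path$points
  keep <- pts$h > 0
  if (!any(keep)) {
    return(tibble(h = integer(0), k = integer(0), t = numeric(0),
                  L = numeric(0), phi = list()))
  }
  idx <- split(which(keep), pts$h[keep])
  rows <- lapply(idx, function(ii) {
    best <- ii[which.min(pts$L[ii])]          # ties -> earliest iteration
    tibble(h = pts$h[best], k = pts$k[best], t = pts$t[best],
           L = pts$L[best], phi = list(path$phi[best, ]))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$h)
}

#' Select the final model by sequential likelihood-ratio testing
#'
#' Starting from the sparsest group-best solution, the current model A is
#' compared with the next larger available model B through the Wilks
#' statistic `D = 2 * (L_A - L_B)` (L is the Poisson negative
#' log-likelihood; the omitted constants cancel), referred to a chi-square
#' distribution with `kappa = h_B - h_A` degrees of freedom. If the larger
#' model improves the fit significantly (`p <= alpha`) it becomes current
#' and the search continues; otherwise the current model is returned. This
#' prefers the smallest number of expressed isoforms that explains the
#' observations.
#'
#' @param groups A [group_path()] result (or the path itself).
#' @param alpha Significance level of the stop rule (default 0.01).
#' @param obs Optional [build_design()] result, needed only when
#'   `refit = TRUE`.
#' @param refit Re-estimate expression by unpenalized maximum likelihood
#'   restricted to the selected support (default `FALSE`: the path point is
#'   returned as-is).
#' @return A `selection_result`: list with `phi` (chosen RPKM vector), `h`,
#'   `L`, and `lrt_trace` (tibble `h_small`, `h_large`, `D`, `kappa`,
#'   `p_value`, `accepted`).
#' @export
select_model <- function(groups, alpha = 0.01, obs = NULL, refit = FALSE) {
  if (inherits(groups, "solution_path")) groups <- group_path(groups)
  trace <- tibble(h_small = integer(0), h_large = integer(0),
                  D = numeric(0), kappa = integer(0),
                  p_value = numeric(0), accepted = logical(0))
  if (nrow(groups) == 0) {
    return(new_selection_result(phi = numeric(0), h = 0L, L = NA_real_,
                                lrt_trace = trace))
  }
  cur <- 1L
  for (nxt in seq_len(nrow(groups))[-1]) {
    D <- 2 * (groups$L[cur] - groups$L[nxt])
    kappa <- groups$h[nxt] - groups$h[cur]
    p_value <- if (D < 0) 1 else pchisq(D, df = kappa, lower.tail = FALSE)
    accepted <- p_value <= alpha
    trace <- dplyr::bind_rows(trace, tibble(
      h_small = groups$h[cur], h_large = groups$h[nxt],
      D = D, kappa = as.integer(kappa), p_value = p_value,
      accepted = accepted
    ))
    if (!accepted) break
    cur <- nxt
  }
  phi <- groups$phi[[cur]]
  L <- groups$L[cur]
  if (refit) {
    if (is.null(obs)) abort("refit = TRUE requires the observation set")
    phi <- refit_support(phi, obs)
    L <- neg_log_likelihood(phi, obs)
  }
  new_selection_result(phi = phi, h = as.integer(groups$h[cur]), L = L,
                       lrt_trace = trace)
}

new_selection_result <- function(phi, h, L, lrt_trace, threshold = NA_real_) {
  structure(list(phi = phi, h = h, L = L, lrt_trace = lrt_trace,
                 threshold = threshold),
            class = "selection_result")
}

# unpenalized Poisson ML restricted to the positive support
refit_support <- function(phi, obs) {
  sup <- which(phi > 0)
  if (length(sup) == 0) return(phi)
  fn <- function(x) {
    full <- numeric(length(phi)); full[sup] <- x
    neg_log_likelihood(full, obs)
  }
  fit <- optim(phi[sup], fn, method = "L-BFGS-B", lower = 0)
  out <- numeric(length(phi)); out[sup] <- fit$par
  out
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", x$h, " expressed isoform(s)", sep = "")
  if (x$h > 0) {
    cat("; RPKM: ",
        paste0("#", which(x$phi > 0), "=",
               format(x$phi[x$phi > 0], digits = 4), collapse = ", "),
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.selection_result <- function(x, ...) {
  idx <- which(x$phi > 0)
  tibble(isoform = idx, rpkm = x$phi[idx])
}

#' @export
glance.selection_result <- function(x, ...) {
  tibble(h = x$h, L = x$L, n_lrt = nrow(x$lrt_trace),
         threshold = x$threshold)
}

#' Expression threshold from the annotation ROC curve
#'
#' Predicted isoforms that match the annotation are treated as positives and
#' the rest as negatives; sweeping a "call expressed if RPKM >= T" threshold
#' over the observed RPKM values traces an ROC curve, and the chosen T
#' maximizes Youden's J = sensitivity - (1 - specificity). On a concave
#' empirical ROC curve this is the point where the sensitivity gain rate
#' equals the false-positive gain rate (slope 1). Ties go to the largest T.
#'
#' @param predictions Data frame with numeric `rpkm` and logical
#'   `is_annotated`.
#' @return A `roc_threshold` object: list with `threshold` and `roc`, a
#'   tibble of candidate thresholds with `tp`, `fp`, `sensitivity`,
#'   `specificity` and `youden`.
#' @export
roc_threshold <- function(predictions) {
  predictions <- as_tibble(predictions)
  stopifnot(all(c("rpkm", "is_annotated") %in% names(predictions)))
  pos <- predictions$rpkm[predictions$is_annotated]
  neg <- predictions$rpkm[!predictions$is_annotated]
  if (length(pos) == 0 || length(neg) == 0) {
    abort("ROC threshold is undefined: need at least one annotated and one unannotated prediction")
  }
  cuts <- sort(unique(predictions$rpkm))
  roc <- tibble(
    threshold = cuts,
    tp = vapply(cuts, function(tt) sum(pos >= tt), numeric(1)),
    fp = vapply(cuts, function(tt) sum(neg >= tt), numeric(1))
  )
  roc$sensitivity <- roc$tp / length(pos)
  roc$specificity <- 1 - roc$fp / length(neg)
  roc$youden <- roc$sensitivity + roc$specificity - 1
  # ties -> largest T (tolerance guards float noise in the ratios)
  best <- max(which(roc$youden >= max(roc$youden) - 1e-9))
  structure(list(threshold = roc$threshold[best], roc = roc),
            class = "roc_threshold")
}

#' @export
print.roc_threshold <- function(x, ...) {
  cat("<roc_threshold> T =", format(x$threshold, digits = 6), "RPKM\n")
  invisible(x)
}

#' Apply an expression threshold to a selection result
#'
#' @param result A [select_model()] result.
#' @param threshold RPKM threshold; isoforms below it are zeroed out.
#' @return The filtered `selection_result` with the threshold recorded.
#' @export
apply_threshold <- function(result, threshold) {
  stopifnot(inherits(result, "selection_result"))
  phi <- result$phi
  phi[phi < threshold] <- 0
  new_selection_result(phi = phi, h = sum(phi > 0), L = result$L,
                       lrt_trace = result$lrt_trace, threshold = threshold)
}

#' Classify predictions as known or novel against an annotation
#'
#' A multi-exon prediction is "known" when its ordered intron chain (the
#' (donor end, acceptor start) pairs) exactly equals that of an annotated
#' transcript; transcript start and end positions are allowed to differ.
#' Single-exon transcripts match by reciprocal overlap of at least 50%.
#'
#' @param predicted,annotation Data frames with a `transcript_id` column and
#'   an `exons` list column; each element is a data frame (or 2-column
#'   matrix) of `start`, `end` intervals, 0-based half-open, same coordinate
#'   system on both sides.
#' @return A list with `predictions` (the predicted table plus a `status`
#'   column of `"known"`/`"novel"`), `sensitivity` (identified known
#'   isoforms / all annotated isoforms; `NaN` when the annotation is empty)
#'   and `precision` (identified known / number of predictions).
#' @export
classify_against_annotation <- function(predicted, annotation) {
  predicted <- as_tibble(predicted)
  annotation <- as_tibble(annotation)

  pred_keys <- lapply(predicted$exons, intron_chain_key)
  ann_keys <- lapply(annotation$exons, intron_chain_key)
  ann_multi <- unlist(ann_keys[!vapply(ann_keys, is.null, logical(1))])
  ann_single <- annotation$exons[vapply(ann_keys, is.null, logical(1))]

  matched_ann <- rep(FALSE, length(ann_keys))
  status <- character(nrow(predicted))
  for (i in seq_len(nrow(predicted))) {
    key <- pred_keys[[i]]
    if (!is.null(key)) {
      hit <- !is.null(ann_multi) && key %in% ann_multi
      if (hit) {
        matched_ann[which(vapply(ann_keys, identical, logical(1), key))] <- TRUE
      }
    } else {
      ex <- normalize_exons(predicted$exons[[i]])
      hit <- any(vapply(ann_single, function(a) {
        a <- normalize_exons(a)
        single_exon_match(ex, a)
      }, logical(1)))
      if (hit) {
        idx <- which(vapply(ann_keys, is.null, logical(1)))
        for (j in idx) {
          if (single_exon_match(ex, normalize_exons(annotation$exons[[j]])))
            matched_ann[j] <- TRUE
        }
      }
    }
    status[i] <- if (hit) "known" else "novel"
  }
  predicted$status <- status
  sensitivity <- if (nrow(annotation) == 0) NaN else
    sum(matched_ann) / nrow(annotation)
  precision <- if (nrow(predicted) == 0) NaN else
    sum(status == "known") / nrow(predicted)
  list(predictions = predicted, sensitivity = sensitivity,
       precision = precision)
}

normalize_exons <- function(ex) {
  ex <- as.data.frame(ex)
  names(ex)[1:2] <- c("start", "end")
  ex[order(ex$start), , drop = FALSE]
}

# NULL for single-exon transcripts, else "donor:acceptor|donor:acceptor|..."
intron_chain_key <- function(ex) {
  ex <- normalize_exons(ex)
  k <- nrow(ex)
  if (k < 2) return(NULL)
  paste(paste0(ex$end[-k], ":", ex$start[-1]), collapse = "|")
}

single_exon_match <- function(a, b) {
  if (nrow(a) != 1 || nrow(b) != 1) return(FALSE)
  ov <- max(0, min(a$end, b$end) - max(a$start, b$start))
  ov >= 0.5 * (a$end - a$start) && ov >= 0.5 * (b$end - b$start)
}

#' Differential and condition-specific isoforms between two samples
#'
#' Known isoforms are called differential when the RPKM fold change between
#' the two samples reaches `min_fc` in either direction (a pseudo-RPKM of
#' 0.1 is added to both sides when the denominator is zero). Novel isoforms
#' are called condition-specific when expressed at `min_rpkm` or more in
#' sample A while undetected (below `detect_rpkm`) in sample B.
#'
#' @param sample_a,sample_b Data frames with columns `structure` (matching
#'   key, e.g. the intron chain), `status` (`"known"`/`"novel"`) and `rpkm`.
#'   Isoforms absent from a sample are treated as 0 RPKM.
#' @param min_fc Fold-change cutoff (default 2).
#' @param min_rpkm Expression floor for condition-specific novel isoforms
#'   (default 5 RPKM).
#' @param detect_rpkm Detection limit below which an isoform counts as
#'   absent (default 0, i.e. not reported at all).
#' @param pseudo_rpkm Added to both sides when a fold-change denominator is
#'   zero (default 0.1).
#' @return A list of two tibbles: `differential_known` (columns `structure`,
#'   `rpkm_a`, `rpkm_b`, `fold_change`) and `specific_novel` (columns
#'   `structure`, `rpkm_a`).
#' @export
fold_change_compare <- function(sample_a, sample_b, min_fc = 2, min_rpkm = 5,
                                detect_rpkm = 0, pseudo_rpkm = 0.1) {
  sample_a <- as_tibble(sample_a)
  sample_b <- as_tibble(sample_b)
  need <- c("structure", "status", "rpkm")
  stopifnot(all(need %in% names(sample_a)), all(need %in% names(sample_b)))

  merged <- dplyr::full_join(
    dplyr::select(sample_a, "structure", "status", rpkm_a = "rpkm"),
    dplyr::select(sample_b, "structure", "status", rpkm_b = "rpkm"),
    by = "structure"
  ) |>
    dplyr::mutate(
      status = dplyr::coalesce(.data$status.x, .data$status.y),
      rpkm_a = dplyr::coalesce(.data$rpkm_a, 0),
      rpkm_b = dplyr::coalesce(.data$rpkm_b, 0)
    )

  known <- dplyr::filter(merged, .data$status == "known")
  fc <- mapply(function(a, b) {
    if (a == 0 || b == 0) { a <- a + pseudo_rpkm; b <- b + pseudo_rpkm }
    a / b
  }, known$rpkm_a, known$rpkm_b)
  fc <- as.numeric(fc)
  diff_known <- known[fc >= min_fc | fc <= 1 / min_fc, ] |>
    dplyr::mutate(fold_change = fc[fc >= min_fc | fc <= 1 / min_fc]) |>
    dplyr::select("structure", "rpkm_a", "rpkm_b", "fold_change")

  novel <- dplyr::filter(merged, .data$status == "novel",
                         .data$rpkm_a >= min_rpkm,
                         .data$rpkm_b <= detect_rpkm) |>
    dplyr::select("structure", "rpkm_a")

  list(differential_known = as_tibble(diff_known),
       specific_novel = as_tibble(novel))
}
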