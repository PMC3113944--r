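#' Run configuration
#'
#' Bundles every tunable of the pipeline with its default: penalty exponent
#' `p = 0.5`, path step `epsilon = 0.1` RPKM, descent tolerance
#' `xi = 1e-10`, LRT stop level `alpha = 0.01`, no exon-fraction filter
#' (`0.5` reproduces the "more than half of the exons" eligibility rule used
#' on simulated genes), a 1000-candidate enumeration cap, abutting-exon
#' edges on, and no expression threshold.
#'
#' @param p Penalty exponent in (0, 1].
#' @param epsilon Path step size (RPKM).
#' @param xi Descent tolerance.
#' @param alpha LRT significance level.
#' @param min_exon_fraction Candidate filter fraction.
#' @param max_candidates Enumeration cap.
#' @param link_adjacent Connect abutting exons in the splice graph.
#' @param min_rpkm Expression threshold applied to the selected model
#'   (`NULL` for none).
#' @param refit Refit selected support by unpenalized ML.
#' @param max_iters Path iteration cap.
#' @return A `run_config` list.
#' @export
run_config <- function(p = 0.5, epsilon = 0.1, xi = 1e-10, alpha = 0.01,
                       min_exon_fraction = 0, max_candidates = 1000L,
                       link_adjacent = TRUE, min_rpkm = NULL, refit = FALSE,
                       max_iters = 200000L) {
  structure(
    list(p = p, epsilon = epsilon, xi = xi, alpha = alpha,
         min_exon_fraction = min_exon_fraction,
         max_candidates = max_candidates, link_adjacent = link_adjacent,
         min_rpkm = min_rpkm, refit = refit, max_iters = max_iters),
    class = "run_config"
  )
}

#' Identify and quantify the expressed isoforms of one gene
#'
#' The full per-gene pipeline: build the splice graph from exons and
#' junction counts, determine sources and sinks (from annotated transcript
#' bounds when given, otherwise from the graph itself), enumerate candidate
#' isoforms, assemble the Poisson observation model, compute the
#' regularization path, and select the final model by sequential
#' likelihood-ratio testing.
#'
#' @param exons Exon tibble (`start`, `end`, `length`, `count`), e.g. from
#'   [build_exons()] or a simulated gene.
#' @param junctions Junction tibble (`donor_end`, `acceptor_start`,
#'   `count`).
#' @param N Total mapped reads in the library.
#' @param read_length Read length (bp).
#' @param tx_bounds Optional annotated transcript bounds (`txStart`,
#'   `txEnd`) used to place sources and sinks.
#' @param config A [run_config()].
#' @param keep_phi Keep the full path iterate matrix (see [blasso_path()]).
#' @return A `gene_fit`: list with the `graph`, `candidates`, `obs`, `path`,
#'   `selection`, and `isoforms` — a tibble of the expressed isoforms
#'   (`isoform`, `exons`, `structure`, `length`, `rpkm`).
#' @export
identify_isoforms <- function(exons, junctions, N, read_length,
                              tx_bounds = NULL, config = run_config(),
                              keep_phi = FALSE) {
  exons <- as_tibble(exons)
  junctions <- as_junction_table(junctions)
  observed_jx <- junctions[junctions$count > 0, ]
  graph <- build_graph(exons, observed_jx,
                       link_adjacent = config$link_adjacent)
  ends <- if (is.null(tx_bounds)) infer_tss_pas(graph) else
    map_annotation_tss_pas(graph, tx_bounds)
  graph$sources <- ends$sources
  graph$sinks <- ends$sinks

  candidates <- enumerate_candidates(
    graph,
    min_exon_fraction = config$min_exon_fraction,
    max_candidates = config$max_candidates
  )
  empty_iso <- tibble(isoform = integer(0), exons = list(),
                      structure = character(0), length = numeric(0),
                      rpkm = numeric(0))
  if (nrow(candidates) == 0) {
    return(structure(list(graph = graph, candidates = candidates,
                          obs = NULL, path = NULL, selection = NULL,
                          isoforms = empty_iso),
                     class = "gene_fit"))
  }
  obs <- build_design(candidates, exons, observed_jx, N, read_length)
  path <- blasso_path(obs, epsilon = config$epsilon, xi = config$xi,
                      p = config$p, max_iters = config$max_iters,
                      keep_phi = keep_phi)
  selection <- select_model(path, alpha = config$alpha, obs = obs,
                            refit = config$refit)
  if (!is.null(config$min_rpkm)) {
    selection <- apply_threshold(selection, config$min_rpkm)
  }
  idx <- which(selection$phi > 0)
  isoforms <- candidates[idx, c("isoform", "exons", "structure", "length")]
  isoforms$rpkm <- selection$phi[idx]
  structure(
    list(graph = graph, candidates = candidates, obs = obs, path = path,
         selection = selection, isoforms = as_tibble(isoforms)),
    class = "gene_fit"
  )
}

#' @export
print.gene_fit <- function(x, ...) {
  cat("<gene_fit> ", nrow(x$candidates), " candidates -> ",
      nrow(x$isoforms), " expressed isoform(s)\n", sep = "")
  if (nrow(x$isoforms) > 0) print(x$isoforms[, c("isoform", "structure",
                                                 "length", "rpkm")])
  invisible(x)
}

#' @export
tidy.gene_fit <- function(x, ...) {
  x$isoforms
}

#' @export
glance.gene_fit <- function(x, ...) {
  tibble(
    n_exons = nrow(x$graph$exons),
    n_candidates = nrow(x$candidates),
    truncated = isTRUE(attr(x$candidates, "truncated")),
    K = if (is.null(x$path)) NA_integer_ else nrow(x$path$points) - 1L,
    h = if (is.null(x$selection)) 0L else x$selection$h,
    L = if (is.null(x$selection)) NA_real_ else x$selection$L
  )
}
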