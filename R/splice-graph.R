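#' Construct exons from covered segments and splice junctions
#'
#' Partitions contiguous covered segments of a gene region into exons, splitting
#' a segment wherever a junction point (a donor end or an acceptor start) falls
#' strictly inside it. Exons whose two ends are both junction points, segment
#' boundaries, or a mix thereof are the nodes from which candidate isoforms are
#' later assembled.
#'
#' All coordinates are 0-based half-open, the convention used internally
#' throughout the package (BED input is already in this system; GTF output is
#' converted at the boundary).
#'
#' @param segments Data frame of covered genomic intervals with columns `start`
#'   and `end` (0-based half-open), optionally `chrom` and `count`. Segments
#'   must be sorted and non-overlapping.
#' @param junctions Data frame of splice junctions with columns `donor_end`,
#'   `acceptor_start` and optionally `count`. See [junction_table()].
#' @return A tibble of exons with columns `chrom`, `start`, `end`, `length`
#'   and `count`, sorted by `start`. Counts of a split segment are divided
#'   proportionally to sub-exon length (they are normally re-counted from
#'   alignments afterwards; the proportional split keeps totals conserved).
#' @export
#' @examples
#' segs <- tibble::tibble(start = 0, end = 200, count = 100)
#' jx <- junction_table(donor_end = integer(), acceptor_start = integer())
#' build_exons(segs, jx)  # one exon, unsplit
build_exons <- function(segments, junctions) {
  segments <- as_tibble(segments)
  stopifnot(all(c("start", "end") %in% names(segments)))
  if (!"chrom" %in% names(segments)) segments$chrom <- "chr"
  if (!"count" %in% names(segments)) segments$count <- 0
  if (any(segments$start >= segments$end)) {
    abort("every segment must satisfy start < end")
  }
  o <- order(segments$start)
  segments <- segments[o, ]
  if (nrow(segments) > 1 &&
      any(segments$start[-1] < segments$end[-nrow(segments)])) {
    abort("segments must be non-overlapping")
  }
  junctions <- as_junction_table(junctions)

  pts <- sort(unique(c(junctions$donor_end, junctions$acceptor_start)))
  # every junction point must be on a segment boundary or inside a segment
  for (p in pts) {
    hit <- any(segments$start <= p & p <= segments$end)
    if (!hit) {
      abort(paste0("junction coordinate ", p,
                   " falls outside all covered segments"))
    }
  }

  pieces <- purrr::pmap(segments, function(chrom, start, end, count, ...) {
    cuts <- pts[pts > start & pts < end]
    bounds <- c(start, cuts, end)
    len <- diff(bounds)
    split_count <- count * len / (end - start)
    tibble(
      chrom = chrom,
      start = bounds[-length(bounds)],
      end = bounds[-1],
      length = len,
      count = split_count
    )
  })
  ex <- dplyr::bind_rows(pieces)
  ex[order(ex$start), ]
}

#' Assemble a junction table
#'
#' @param donor_end Coordinate where the upstream exon ends (0-based exclusive).
#' @param acceptor_start Coordinate where the downstream exon begins (0-based).
#' @param count Junction-spanning read count (default 0).
#' @return A tibble with columns `donor_end`, `acceptor_start`, `count`.
#' @export
junction_table <- function(donor_end, acceptor_start,
                           count = rep(0L, length(donor_end))) {
  jx <- tibble(donor_end = as.numeric(donor_end),
               acceptor_start = as.numeric(acceptor_start),
               count = as.numeric(count))
  as_junction_table(jx)
}

as_junction_table <- function(junctions) {
  junctions <- as_tibble(junctions)
  stopifnot(all(c("donor_end", "acceptor_start") %in% names(junctions)))
  if (!"count" %in% names(junctions)) junctions$count <- 0
  if (any(junctions$donor_end >= junctions$acceptor_start)) {
    abort("every junction must satisfy donor_end < acceptor_start")
  }
  if (any(junctions$count < 0)) abort("junction counts must be non-negative")
  junctions
}

#' Build the splice graph of a gene
#'
#' Exons are nodes; a directed edge joins exon j to exon k when a junction's
#' donor end coincides with the end of j and its acceptor start with the start
#' of k. With `link_adjacent = TRUE` (the default) an edge is also drawn
#' between every pair of abutting exons (end of one equals start of the next),
#' so that sub-exons produced by splitting a covered segment at an internal
#' junction point can be chained back into contiguous transcription.
#'
#' @param exons Exon tibble from [build_exons()] (columns `start`, `end`,
#'   `length`, `count`).
#' @param junctions Junction tibble (see [junction_table()]).
#' @param link_adjacent Also connect abutting exons (default `TRUE`).
#' @return A `splice_graph` object: a list with elements `exons`, `edges`
#'   (tibble with 1-based exon indices `from`, `to`, a `kind` of `"junction"`
#'   or `"adjacent"`, and `count`), and initially empty integer vectors
#'   `sources` and `sinks`.
#' @export
build_graph <- function(exons, junctions, link_adjacent = TRUE) {
  exons <- as_tibble(exons)
  junctions <- as_junction_table(junctions)
  m <- nrow(exons)

  from <- match(junctions$donor_end, exons$end)
  to <- match(junctions$acceptor_start, exons$start)
  bad <- which(is.na(from) | is.na(to))
  if (length(bad) > 0) {
    j <- bad[[1]]
    abort(paste0("junction (", junctions$donor_end[j], ", ",
                 junctions$acceptor_start[j],
                 ") matches no exon boundary"))
  }
  edges <- tibble(from = from, to = to, kind = rep("junction", length(from)),
                  count = junctions$count)

  if (link_adjacent && m > 1) {
    abut <- which(exons$end[-m] == exons$start[-1])
    if (length(abut) > 0) {
      edges <- dplyr::bind_rows(
        edges,
        tibble(from = abut, to = abut + 1L, kind = "adjacent", count = 0)
      )
    }
  }
  edges <- dplyr::distinct(edges, .data$from, .data$to, .keep_all = TRUE)
  if (any(edges$from >= edges$to)) {
    abort("internal error: edge pointing upstream (graph must be acyclic)")
  }
  structure(
    list(exons = exons, edges = edges,
         sources = integer(0), sinks = integer(0)),
    class = "splice_graph"
  )
}

#' @export
print.splice_graph <- function(x, ...) {
  cat("<splice_graph> ", nrow(x$exons), " exons, ", nrow(x$edges), " edges; ",
      length(x$sources), " sources, ", length(x$sinks), " sinks\n", sep = "")
  invisible(x)
}

#' Infer transcription start and poly-A sites from the graph itself
#'
#' An exon whose start coordinate is not the acceptor start of any junction is
#' a putative transcription start site (TSS); an exon whose end is not the
#' donor end of any junction is a putative poly-A site (PAS). This
#' annotation-free rule treats every boundary that no splicing event explains
#' as a transcript end.
#'
#' @param graph A [build_graph()] result.
#' @return A list with integer vectors `sources` and `sinks` (1-based exon
#'   indices).
#' @export
infer_tss_pas <- function(graph) {
  ex <- graph$exons
  jx <- graph$edges[graph$edges$kind == "junction", ]
  acceptor_starts <- ex$start[jx$to]
  donor_ends <- ex$end[jx$from]
  list(
    sources = which(!(ex$start %in% acceptor_starts)),
    sinks = which(!(ex$end %in% donor_ends))
  )
}

#' Map annotated transcript bounds onto graph exons
#'
#' Marks as sources the exons containing any annotated transcript start, and
#' as sinks the exons containing any transcript end; this mirrors taking
#' TSS/PAS from a known-isoform table rather than inferring them. Bounds that
#' fall in no exon (e.g. in an intron) are skipped with a warning; if none
#' map at all, the graph-based [infer_tss_pas()] rule is used as a fallback.
#'
#' @param graph A [build_graph()] result.
#' @param tx_bounds Data frame with columns `txStart` and `txEnd`, 0-based
#'   half-open, same coordinate system as the exons.
#' @return A list with integer vectors `sources` and `sinks`.
#' @export
map_annotation_tss_pas <- function(graph, tx_bounds) {
  ex <- graph$exons
  tx_bounds <- as_tibble(tx_bounds)
  stopifnot(all(c("txStart", "txEnd") %in% names(tx_bounds)))

  loc_start <- function(p) which(ex$start <= p & p < ex$end)
  loc_end <- function(p) which(ex$start < p & p <= ex$end)

  sources <- integer(0); sinks <- integer(0); missed <- numeric(0)
  for (i in seq_len(nrow(tx_bounds))) {
    s <- loc_start(tx_bounds$txStart[i])
    e <- loc_end(tx_bounds$txEnd[i])
    if (length(s) == 0) missed <- c(missed, tx_bounds$txStart[i]) else
      sources <- c(sources, s)
    if (length(e) == 0) missed <- c(missed, tx_bounds$txEnd[i]) else
      sinks <- c(sinks, e)
  }
  if (length(missed) > 0) {
    warn(paste0("annotated bound(s) mapping to no exon skipped: ",
                paste(missed, collapse = ", ")))
  }
  if (length(sources) == 0 && length(sinks) == 0) {
    warn("no annotated bound maps to any exon; falling back to graph-inferred TSS/PAS")
    return(infer_tss_pas(graph))
  }
  list(sources = sort(unique(sources)), sinks = sort(unique(sinks)))
}

#' Enumerate candidate isoforms as source-to-sink paths
#'
#' Every simple path from a source exon to a sink exon is a candidate isoform.
#' Enumeration is a depth-first search visiting neighbours in increasing index
#' order from the smallest source, so the returned set is ordered
#' lexicographically by exon indices and is fully deterministic. Paths whose
#' exon count is at most `min_exon_fraction` times the total number of exons
#' are dropped (the "more than half of the exons" eligibility rule used when
#' benchmarking on simulated genes corresponds to `min_exon_fraction = 0.5`).
#'
#' @param graph A [build_graph()] result.
#' @param sources,sinks Integer vectors of 1-based exon indices; default to the
#'   ones stored in the graph.
#' @param min_exon_fraction Drop paths with `n_exons <= fraction * m`
#'   (default 0, i.e. no filter).
#' @param max_candidates Enumeration cap per gene (default 1000); when hit,
#'   the search stops and the result is flagged as truncated.
#' @return A `candidate_set`: a tibble with columns `isoform` (integer id),
#'   `exons` (list column of increasing 1-based exon index vectors),
#'   `n_exons`, `length` (summed exon bp) and `structure` (the intron-chain
#'   independent membership key). Attributes `m` (number of exons in the gene)
#'   and `truncated` are attached.
#' @export
enumerate_candidates <- function(graph, sources = graph$sources,
                                 sinks = graph$sinks,
                                 min_exon_fraction = 0,
                                 max_candidates = 1000L) {
  m <- nrow(graph$exons)
  empty <- tibble(isoform = integer(0), exons = list(), n_exons = integer(0),
                  length = numeric(0), structure = character(0))
  if (m == 0) {
    return(new_candidate_set(empty, m = m, truncated = FALSE))
  }
  if (length(sources) == 0 || length(sinks) == 0) {
    abort("sources and sinks must be non-empty to enumerate candidates")
  }
  adj <- vector("list", m)
  for (i in seq_len(nrow(graph$edges))) {
    f <- graph$edges$from[i]
    adj[[f]] <- sort(c(adj[[f]], graph$edges$to[i]))
  }
  sinks <- sort(unique(sinks))
  min_exons <- min_exon_fraction * m

  paths <- list()
  truncated <- FALSE
  keep_path <- function(path) {
    if (min_exon_fraction > 0 && length(path) <= min_exons) return(TRUE)
    if (length(paths) >= max_candidates) {
      truncated <<- TRUE
      return(FALSE)
    }
    paths[[length(paths) + 1L]] <<- path
    TRUE
  }
  dfs <- function(path) {
    node <- path[length(path)]
    if (node %in% sinks) {
      if (!keep_path(path)) return(FALSE)
    }
    for (nb in adj[[node]]) {
      if (!dfs(c(path, nb))) return(FALSE)
    }
    TRUE
  }
  for (s in sort(unique(sources))) {
    if (!dfs(s)) break
  }

  if (length(paths) == 0) {
    return(new_candidate_set(empty, m = m, truncated = truncated))
  }
  keys <- vapply(paths, structure_key, character(1))
  keep <- !duplicated(keys)
  paths <- paths[keep]
  keys <- keys[keep]
  res <- tibble(
    isoform = seq_along(paths),
    exons = paths,
    n_exons = lengths(paths),
    length = vapply(paths, function(p) sum(graph$exons$length[p]), numeric(1)),
    structure = keys
  )
  new_candidate_set(res, m = m, truncated = truncated)
}

new_candidate_set <- function(tbl, m, truncated) {
  structure(tbl, m = m, truncated = truncated,
            class = c("candidate_set", class(tbl)))
}

#' Membership key of an exon chain
#'
#' Canonical string identifying which exons an isoform contains; two isoforms
#' are the same structure iff their keys are equal.
#'
#' @param exon_indices Increasing integer vector of exon indices.
#' @return A character scalar such as `"1-3-4"`.
#' @export
structure_key <- function(exon_indices) {
  paste(exon_indices, collapse = "-")
}

#' Binary membership matrix of a candidate set
#'
#' @param candidates A [enumerate_candidates()] result (or any tibble with an
#'   `exons` list column).
#' @param m Number of exons in the gene; defaults to the candidate set's own
#'   `m` attribute.
#' @return An `n x m` 0/1 matrix with one row per candidate isoform.
#' @export
membership_matrix <- function(candidates, m = attr(candidates, "m")) {
  n <- nrow(candidates)
  mm <- matrix(0L, nrow = n, ncol = m)
  for (i in seq_len(n)) mm[i, candidates$exons[[i]]] <- 1L
  mm
}
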