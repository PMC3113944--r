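# Fixtures and independent oracles shared across the test files. The oracles
# are deliberately naive (recursion, grid search, direct formula evaluation)
# and never call the code paths they check.

# three exons in a chain with introns, junction counts on both joins
chain_gene <- function(counts = c(50, 30, 40), jx_counts = c(10, 8)) {
  exons <- tibble::tibble(
    chrom = "chrT",
    start = c(0, 200, 500),
    end = c(100, 320, 650),
    length = c(100, 120, 150),
    count = counts
  )
  junctions <- isopath::junction_table(
    donor_end = c(100, 320),
    acceptor_start = c(200, 500),
    count = jx_counts
  )
  list(exons = exons, junctions = junctions)
}

# brute-force enumeration of all simple source->sink paths in a DAG given as
# an edge list of 1-based (from, to) pairs with from < to
brute_force_paths <- function(edges, sources, sinks, n_nodes) {
  paths <- list()
  recurse <- function(path) {
    node <- path[length(path)]
    if (node %in% sinks) paths[[length(paths) + 1L]] <<- path
    nxt <- edges$to[edges$from == node]
    for (v in sort(nxt)) recurse(c(path, v))
  }
  for (s in sort(sources)) recurse(s)
  paths
}

# direct Poisson negative log-likelihood, evaluated from first principles
direct_nll <- function(phi, A, x, floor = 1e-8) {
  lam <- as.vector(A %*% phi)
  total <- 0
  for (s in seq_along(x)) {
    total <- total + lam[s] -
      (if (x[s] > 0) x[s] * log(max(lam[s], floor)) else 0)
  }
  total
}

# hand-built observation set (bypasses build_design) for optimizer and
# likelihood formula tests
manual_obs <- function(A, x, N = 1e6, read_length = 76) {
  structure(
    list(
      events = tibble::tibble(
        kind = rep("exon", nrow(A)),
        exon = seq_len(nrow(A)),
        from = NA_integer_, to = NA_integer_,
        count = x,
        region_length = rep(100, nrow(A))
      ),
      A = A, N = N, read_length = read_length, n = ncol(A)
    ),
    class = "observation_set"
  )
}

# exhaustive grid minimum of J(.; t) over a box, grid step `by`
grid_min_J <- function(A, x, t, p, upper, by) {
  n <- ncol(A)
  pts <- as.matrix(expand.grid(rep(list(seq(0, upper, by = by)), n)))
  lam <- pts %*% t(A)                       # n_pts x S
  pos <- x > 0
  L <- rowSums(lam) -
    as.vector(log(pmax(lam[, pos, drop = FALSE], 1e-8)) %*% x[pos])
  pen <- rowSums((pts^p) * (pts > 0))
  min(L + t * pen)
}

# per-t oracle comparison: for n_t sampled distinct path t values, compare
# J of the final iterate at that t with the brute-force grid minimum; the
# tolerance is xi + 2 * (largest epsilon-step change of J at the iterate)
path_oracle_gaps <- function(path, obs, A, x, n_t = 5, upper = 8,
                             eps = path$epsilon, p = path$p) {
  pts <- path$points
  tv <- unique(pts$t[pts$t > 0])
  if (length(tv) == 0) {
    return(tibble::tibble(t = numeric(0), gap = numeric(0),
                          tol = numeric(0)))
  }
  sel_t <- tv[unique(round(seq(1, length(tv), length.out = n_t)))]
  gap <- tol <- numeric(0)
  for (t_k in sel_t) {
    k <- max(which(pts$t == t_k))
    g_min <- grid_min_J(A, x, t = t_k, p = p, upper = upper, by = eps / 2)
    phi_k <- path$phi[k, ]
    fd <- 0
    for (i in seq_along(phi_k)) {
      up <- phi_k; up[i] <- up[i] + eps
      fd <- max(fd, abs(isopath::objective(up, obs, t_k, p) - pts$J[k]))
      if (phi_k[i] >= eps) {
        dn <- phi_k; dn[i] <- dn[i] - eps
        fd <- max(fd, abs(isopath::objective(dn, obs, t_k, p) - pts$J[k]))
      }
    }
    gap <- c(gap, pts$J[k] - g_min)
    tol <- c(tol, path$xi + 2 * fd)
  }
  tibble::tibble(t = sel_t, gap = gap, tol = tol)
}

# builds a synthetic solution_path with prescribed sizes and L values so the
# grouping and LRT logic can be exercised against hand-computed answers
fake_path <- function(h, L, phi_rows, t = rev(seq_along(h))) {
  stopifnot(length(h) == length(L), length(h) == nrow(phi_rows))
  structure(
    list(
      points = tibble::tibble(
        k = seq_along(h) - 1L, t = t, L = L, J = L, h = h,
        step_kind = "forward"),
      phi = phi_rows,
      group_best = NULL,
      terminated_by = "t_nonpositive",
      epsilon = 0.1, xi = 1e-10, p = 0.5, n = ncol(phi_rows)
    ),
    class = "solution_path"
  )
}

new_fake_selection <- function(phi) {
  structure(list(phi = phi, h = sum(phi > 0), L = 0,
                 lrt_trace = tibble::tibble(), threshold = NA_real_),
            class = "selection_result")
}

# simulated gene + fit in one call; used by several suites
fit_simulated_gene <- function(gene, sim_seed, config = isopath::run_config(
                                 min_exon_fraction = 0.5)) {
  sc <- isopath::simulate_counts(gene, seed = sim_seed)
  tb <- tibble::tibble(txStart = min(gene$exons$start),
                       txEnd = max(gene$exons$end))
  suppressWarnings(isopath::identify_isoforms(
    sc$exons, sc$junctions, sc$N, sc$read_length,
    tx_bounds = tb, config = config
  ))
}
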