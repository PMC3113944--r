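# Poisson observation model: each event s (an exon or a junction) has a read
# count X_s ~ Poisson(lambda_s) with lambda_s = sum_i a_si * phi_i, phi in
# RPKM. The coefficients a_si encode the RPKM normalisation, so that one
# isoform at 1 RPKM over a 1 kb exon in a 1e6-read library expects 1 read.

LAMBDA_FLOOR <- 1e-8

#' Build the observation set and design coefficients of a gene
#'
#' Creates one event per exon and one per detected junction, with known
#' coefficients linking candidate-isoform RPKM to expected read counts:
#' for exon j, `a_si = N * l_j * 1e-9 * c_ij` where `c_ij` indicates exon
#' membership; for junction (j,k), `a_si = N * (read_length - 1) * 1e-9`
#' whenever exons j and k are consecutive in isoform i. The junction region
#' length `read_length - 1` counts the read start positions that span the
#' boundary.
#'
#' Events with a positive count but all-zero coefficients (reads that no
#' candidate isoform can explain) are removed and reported via the
#' `dropped_events` attribute.
#'
#' @param candidates A [enumerate_candidates()] result.
#' @param exons Exon tibble with `length` and `count`.
#' @param junctions Junction tibble with `donor_end`, `acceptor_start`,
#'   `count`; coordinates must match exon boundaries.
#' @param N Total mapped reads in the library.
#' @param read_length Read length in bp (must be at least 2).
#' @param junction_region_length Length assigned to junction events; defaults
#'   to `read_length - 1`.
#' @return An `observation_set`: list with `events` (tibble: `kind`, `exon`,
#'   `from`, `to`, `count`, `region_length`), coefficient matrix `A`
#'   (events x isoforms), `N`, `read_length`, `n`.
#' @export
build_design <- function(candidates, exons, junctions, N, read_length,
                         junction_region_length = read_length - 1) {
  if (N <= 0) abort("N (total mapped reads) must be positive")
  if (read_length < 2) abort("read_length must be at least 2")
  if (nrow(candidates) == 0) abort("candidate set is empty")
  exons <- as_tibble(exons)
  junctions <- as_junction_table(junctions)
  n <- nrow(candidates)
  m <- nrow(exons)

  memb <- membership_matrix(candidates, m = m)
  # exon events
  a_exon <- t(memb) * (N * exons$length * 1e-9)     # m x n
  ev_exon <- tibble(kind = "exon", exon = seq_len(m),
                    from = NA_integer_, to = NA_integer_,
                    count = exons$count, region_length = exons$length)

  # junction events
  from <- match(junctions$donor_end, exons$end)
  to <- match(junctions$acceptor_start, exons$start)
  if (anyNA(from) || anyNA(to)) {
    abort("junction coordinates do not match exon boundaries")
  }
  njx <- length(from)
  a_jx <- matrix(0, nrow = njx, ncol = n)
  for (s in seq_len(njx)) {
    for (i in seq_len(n)) {
      path <- candidates$exons[[i]]
      pos <- match(from[s], path)
      if (!is.na(pos) && pos < length(path) && path[pos + 1L] == to[s]) {
        a_jx[s, i] <- N * junction_region_length * 1e-9
      }
    }
  }
  ev_jx <- tibble(kind = rep("junction", njx), exon = NA_integer_,
                  from = from, to = to, count = junctions$count,
                  region_length = rep(junction_region_length, njx))

  events <- dplyr::bind_rows(ev_exon, ev_jx)
  A <- rbind(a_exon, a_jx)

  unexplained <- events$count > 0 & rowSums(A) == 0
  dropped <- events[unexplained, ]
  if (any(unexplained)) {
    warn(paste0(sum(unexplained),
                " event(s) with reads but no covering candidate removed"))
    events <- events[!unexplained, ]
    A <- A[!unexplained, , drop = FALSE]
  }
  structure(
    list(events = events, A = A, N = N, read_length = read_length, n = n),
    class = "observation_set", dropped_events = dropped
  )
}

#' @export
print.observation_set <- function(x, ...) {
  cat("<observation_set> ", nrow(x$events), " events (",
      sum(x$events$kind == "exon"), " exon, ",
      sum(x$events$kind == "junction"), " junction), ",
      x$n, " candidate isoforms, N = ", format(x$N, big.mark = ","), "\n",
      sep = "")
  invisible(x)
}

#' Poisson negative log-likelihood of an expression vector
#'
#' `L(phi) = sum_s [lambda_s - X_s * log(lambda_s)]` with
#' `lambda_s = sum_i a_si phi_i`; the constant `log(X_s!)` terms are omitted
#' as they cancel in every comparison used downstream (path steps and
#' likelihood-ratio differences). The logarithm is floored at 1e-8 expected
#' reads so that L is finite at phi = 0, where the path algorithm starts.
#'
#' @param phi Non-negative RPKM vector, one entry per candidate isoform.
#' @param obs An [build_design()] result.
#' @return The negative log-likelihood (a scalar).
#' @export
neg_log_likelihood <- function(phi, obs) {
  stopifnot(length(phi) == obs$n)
  if (any(phi < 0)) abort("phi must be non-negative")
  lam <- drop(obs$A %*% phi)
  x <- obs$events$count
  pos <- x > 0
  sum(lam) - sum(x[pos] * log(pmax(lam[pos], LAMBDA_FLOOR)))
}

#' Penalized objective of the sparse Poisson MAP model
#'
#' `J(phi; t) = L(phi) + t * sum_i phi_i^p` with `0 < p <= 1`; `p = 1` is the
#' lasso/Laplace prior and `p = 0.5` (the default used throughout) imposes a
#' stronger, non-convex sparsity constraint. Zero entries contribute exactly 0.
#'
#' @inheritParams neg_log_likelihood
#' @param t Regularization weight (non-negative).
#' @param p Penalty exponent in (0, 1].
#' @return The penalized objective (a scalar).
#' @export
objective <- function(phi, obs, t, p = 0.5) {
  if (p <= 0 || p > 1) abort("p must lie in (0, 1]")
  if (t < 0) abort("t must be non-negative")
  neg_log_likelihood(phi, obs) + t * sum(phi[phi > 0]^p)
}

#' Reads Per Kilobase per Million mapped reads
#'
#' @param count Read count on a region.
#' @param length_bp Region length in bp (positive).
#' @param N Total mapped reads (positive).
#' @return `count / ((length_bp / 1e3) * (N / 1e6))`.
#' @export
#' @examples
#' rpkm_from_count(10, 1000, 1e6)  # 10 RPKM
rpkm_from_count <- function(count, length_bp, N) {
  if (any(length_bp <= 0)) abort("length_bp must be positive")
  if (any(N <= 0)) abort("N must be positive")
  count / ((length_bp / 1e3) * (N / 1e6))
}
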