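# Synthetic gene and read-count generation used to validate the pipeline.
# Reads land on exon or junction regions with probability proportional to
# isoform RPKM times region length, the same event model the Poisson design
# assumes, so empirical event means converge to the design lambdas.

#' Generate a random synthetic gene with known isoform truth
#'
#' Draws a gene of `n_exons` exons laid out with introns in between (exon
#' lengths uniform on 50-300 bp, intron lengths 200-2000 bp) and
#' `n_expressed` distinct true isoforms. Each isoform keeps the first and
#' last exon (shared transcript start/end anchors, as when start and poly-A
#' sites come from annotation) and skips a random subset of interior exons
#' while always retaining more than half of all exons, mirroring common
#' skipping patterns. True RPKM levels are drawn log-uniformly over
#' `rpkm_range`. The implied library size `N` is set so that the expected
#' number of reads on the gene equals `n_reads`.
#'
#' @param n_exons Number of exons (at least 2 unless `n_expressed = 1` and a
#'   single-exon gene is wanted).
#' @param n_expressed Number of truly expressed isoforms.
#' @param rpkm_range Length-2 range of true RPKM values (default c(10, 1000)).
#' @param read_length Read length in bp (default 76).
#' @param n_reads Expected reads mapped to the gene (default 2000).
#' @param seed Optional integer seed; the gene is reproducible given it.
#' @return A `true_gene`: list with `exons` (tibble `chrom`, `start`, `end`,
#'   `length`), `isoforms` (tibble `isoform`, `exons` list column,
#'   `structure`, `length`, `rpkm`), `junctions` (tibble of the true
#'   donor/acceptor pairs), `read_length`, `n_reads`, `N` (implied library
#'   size).
#' @export
random_gene <- function(n_exons, n_expressed, rpkm_range = c(10, 1000),
                        read_length = 76, n_reads = 2000, seed = NULL) {
  max_structures <- if (n_exons <= 2) 1 else {
    interior <- n_exons - 2
    max_skip <- max(0, min(interior, ceiling(n_exons / 2) - 1))
    sum(choose(interior, 0:max_skip))
  }
  if (n_expressed < 1 || n_expressed > max_structures) {
    abort(paste0("cannot draw ", n_expressed,
                 " distinct isoform structures from ", n_exons, " exons"))
  }
  draw <- function() {
    lens <- sample(50:300, n_exons, replace = TRUE)
    introns <- sample(200:2000, max(n_exons - 1, 0), replace = TRUE)
    start <- cumsum(c(0, head(lens, -1) + introns))
    exons <- tibble(chrom = "chrS", start = start, end = start + lens,
                    length = lens)

    interior <- setdiff(seq_len(n_exons), c(1L, n_exons))
    max_skip <- max(0, min(length(interior), ceiling(n_exons / 2) - 1))
    structures <- list()
    while (length(structures) < n_expressed) {
      k <- sample.int(max_skip + 1L, 1L) - 1L
      skip <- if (k > 0) sort(sample(interior, k)) else integer(0)
      iso <- setdiff(seq_len(n_exons), skip)
      key <- structure_key(iso)
      if (!key %in% names(structures)) structures[[key]] <- iso
    }
    rpkm <- exp(stats::runif(n_expressed, log(rpkm_range[1]),
                             log(rpkm_range[2])))
    iso_len <- vapply(structures, function(p) sum(exons$length[p]),
                      numeric(1))
    isoforms <- tibble(
      isoform = seq_len(n_expressed),
      exons = unname(structures),
      structure = names(structures),
      length = unname(iso_len),
      rpkm = rpkm
    )
    jx <- unique(dplyr::bind_rows(lapply(structures, function(p) {
      if (length(p) < 2) return(NULL)
      tibble(donor_end = exons$end[head(p, -1)],
             acceptor_start = exons$start[p[-1]])
    })))
    if (nrow(jx) == 0) {
      jx <- tibble(donor_end = numeric(0), acceptor_start = numeric(0))
    }
    jx <- jx[order(jx$donor_end, jx$acceptor_start), ]

    n_junc <- vapply(structures, function(p) length(p) - 1L, integer(1))
    eff_len <- isoforms$length + n_junc * (read_length - 1)
    expected_per_rpkm <- 1e-9 * sum(rpkm * eff_len)
    N <- n_reads / expected_per_rpkm

    structure(
      list(exons = exons, isoforms = isoforms, junctions = jx,
           read_length = read_length, n_reads = n_reads, N = N),
      class = "true_gene"
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Construct a gene with two highly similar competing isoforms
#'
#' A deliberately hard deconvolution case: a chain of `n_exons` exons
#' expresses two isoforms that each skip one distinct interior exon and are
#' otherwise identical. The union of their junctions also admits the
#' skip-both and skip-neither recombinations as candidate paths, so sparsity
#' in the prior is what keeps the spurious pair out of the model. Both true
#' isoforms share one RPKM level.
#'
#' @param n_exons Number of exons (at least 6).
#' @param rpkm Common true expression of the two isoforms (default 150).
#' @param read_length Read length (default 76).
#' @param n_reads Expected reads on the gene (default 3000).
#' @param seed Optional integer seed.
#' @return A `true_gene`, as from [random_gene()].
#' @export
similar_isoform_gene <- function(n_exons = 8, rpkm = 150, read_length = 76,
                                 n_reads = 3000, seed = NULL) {
  if (n_exons < 6) abort("need at least 6 exons for distinct skip patterns")
  draw <- function() {
    lens <- sample(50:300, n_exons, replace = TRUE)
    introns <- sample(200:2000, n_exons - 1, replace = TRUE)
    start <- cumsum(c(0, head(lens, -1) + introns))
    exons <- tibble(chrom = "chrS", start = start, end = start + lens,
                    length = lens)
    skips <- sort(sample(2:(n_exons - 1), 2))
    structures <- list(setdiff(seq_len(n_exons), skips[1]),
                       setdiff(seq_len(n_exons), skips[2]))
    iso_len <- vapply(structures, function(p) sum(exons$length[p]),
                      numeric(1))
    isoforms <- tibble(
      isoform = 1:2,
      exons = structures,
      structure = vapply(structures, structure_key, character(1)),
      length = iso_len,
      rpkm = rep(rpkm, 2)
    )
    jx <- unique(dplyr::bind_rows(lapply(structures, function(p) {
      tibble(donor_end = exons$end[head(p, -1)],
             acceptor_start = exons$start[p[-1]])
    })))
    jx <- jx[order(jx$donor_end, jx$acceptor_start), ]
    n_junc <- lengths(structures) - 1L
    eff_len <- iso_len + n_junc * (read_length - 1)
    N <- n_reads / (1e-9 * sum(rpkm * eff_len))
    structure(
      list(exons = exons, isoforms = isoforms, junctions = jx,
           read_length = read_length, n_reads = n_reads, N = N),
      class = "true_gene"
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' @export
print.true_gene <- function(x, ...) {
  cat("<true_gene> ", nrow(x$exons), " exons, ", nrow(x$isoforms),
      " expressed isoform(s), read length ", x$read_length,
      ", ~", x$n_reads, " reads\n", sep = "")
  invisible(x)
}

#' Simulate exon and junction read counts from a true gene
#'
#' Each of the gene's reads picks a true isoform with probability
#' proportional to RPKM times effective transcript length (exonic length
#' plus `read_length - 1` per junction), then an event within that isoform
#' with probability proportional to region length: `l_j` for exon `j` and
#' `read_length - 1` for each junction (the number of start positions whose
#' span crosses the boundary). Counts are therefore one multinomial draw
#' over events whose expectations match the Poisson design lambdas, and
#' exon plus junction counts sum exactly to the number of reads.
#'
#' With `weight_by_length = FALSE` isoforms are picked proportional to RPKM
#' alone; this breaks the agreement between simulated counts and the RPKM
#' definition and exists only to probe that sensitivity.
#'
#' @param gene A [random_gene()] result (or hand-built `true_gene`).
#' @param seed Optional integer seed; same seed, same counts.
#' @param n_reads Number of reads to place on the gene; defaults to the
#'   gene's `n_reads`.
#' @param weight_by_length Weight isoform choice by effective length
#'   (default `TRUE`).
#' @return A `sim_counts`: list with `exons` (the gene's exon tibble plus
#'   `count`), `junctions` (donor/acceptor plus `count`), `N`,
#'   `read_length`, `n_reads`.
#' @export
simulate_counts <- function(gene, seed = NULL, n_reads = gene$n_reads,
                            weight_by_length = TRUE) {
  stopifnot(inherits(gene, "true_gene"))
  if (n_reads > 0 && all(gene$isoforms$rpkm <= 0)) {
    abort("cannot place reads on a gene whose isoforms all have zero RPKM")
  }
  r1 <- gene$read_length - 1
  m <- nrow(gene$exons)
  jx <- gene$junctions
  njx <- nrow(jx)

  # event weight matrix: rows = m exon events then njx junction events
  w <- matrix(0, nrow = m + njx, ncol = nrow(gene$isoforms))
  for (i in seq_len(nrow(gene$isoforms))) {
    p <- gene$isoforms$exons[[i]]
    w[p, i] <- gene$exons$length[p]
    if (length(p) >= 2 && njx > 0) {
      d <- gene$exons$end[head(p, -1)]
      a <- gene$exons$start[p[-1]]
      hit <- match(paste(d, a), paste(jx$donor_end, jx$acceptor_start))
      w[m + hit, i] <- r1
    }
  }
  iso_w <- gene$isoforms$rpkm
  if (weight_by_length) {
    prob <- drop(w %*% iso_w)
  } else {
    eff <- colSums(w)
    prob <- drop(w %*% (iso_w / pmax(eff, 1)))
  }
  draw <- function() {
    counts <- drop(stats::rmultinom(1, size = n_reads, prob = prob))
    exons <- gene$exons
    exons$count <- counts[seq_len(m)]
    junctions <- jx
    junctions$count <- if (njx > 0) counts[m + seq_len(njx)] else numeric(0)
    structure(
      list(exons = exons, junctions = junctions, N = gene$N,
           read_length = gene$read_length, n_reads = n_reads),
      class = "sim_counts"
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' @export
print.sim_counts <- function(x, ...) {
  cat("<sim_counts> ", sum(x$exons$count), " exon reads + ",
      sum(x$junctions$count), " junction reads (N = ",
      format(round(x$N), big.mark = ","), ")\n", sep = "")
  invisible(x)
}

#' Fraction of true isoforms recovered within tolerance
#'
#' A truly expressed isoform (RPKM at least `min_rpkm`) counts as positive
#' when an estimate with the identical structure exists and its relative
#' expression error is at most `rel_tol` (boundary included).
#'
#' @param estimates Data frame with columns `structure` and `rpkm`.
#' @param truth Data frame with columns `structure` and `rpkm`.
#' @param rel_tol Relative tolerance (default 0.05).
#' @param min_rpkm Expression floor defining "expressed" truth (default 1).
#' @return Positives divided by the number of expressed true isoforms
#'   (`NaN` when there are none).
#' @export
positive_fraction <- function(estimates, truth, rel_tol = 0.05,
                              min_rpkm = 1) {
  truth <- dplyr::filter(as_tibble(truth), .data$rpkm >= min_rpkm)
  if (nrow(truth) == 0) return(NaN)
  estimates <- as_tibble(estimates)
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    j <- match(truth$structure[i], estimates$structure)
    !is.na(j) &&
      abs(estimates$rpkm[j] - truth$rpkm[i]) / truth$rpkm[i] <= rel_tol
  }, logical(1))
  mean(hit)
}

#' Specificity of the reported isoform set
#'
#' Negatives are the reported structures that are not among the expressed
#' truth (RPKM at least `min_rpkm`) plus the true isoforms below the floor;
#' specificity is the fraction of those negatives *not* reported at or above
#' the floor. With no negatives at all the metric degenerates and is
#' reported as 1 with a `degenerate` attribute set.
#'
#' @inheritParams positive_fraction
#' @return Specificity in `[0, 1]` (attribute `degenerate` flags the
#'   no-negatives case).
#' @export
specificity_metric <- function(estimates, truth, rel_tol = 0.05,
                               min_rpkm = 1) {
  estimates <- as_tibble(estimates)
  truth <- as_tibble(truth)
  pos_truth <- truth$structure[truth$rpkm >= min_rpkm]
  reported <- estimates$structure[estimates$rpkm >= min_rpkm]
  false_reports <- setdiff(reported, pos_truth)
  low_truth <- truth$structure[truth$rpkm < min_rpkm]
  negatives <- union(false_reports, low_truth)
  if (length(negatives) == 0) {
    return(structure(1, degenerate = TRUE))
  }
  structure(sum(!negatives %in% reported) / length(negatives),
            degenerate = FALSE)
}

#' Fraction of expressed true isoforms present in the candidate set
#'
#' @param candidates A [enumerate_candidates()] result.
#' @param truth Data frame with columns `structure` and `rpkm`.
#' @param min_rpkm Expression floor defining "expressed" truth (default 1).
#' @return Covered fraction (`NaN` when no truth is expressed).
#' @export
candidate_coverage <- function(candidates, truth, min_rpkm = 1) {
  truth <- dplyr::filter(as_tibble(truth), .data$rpkm >= min_rpkm)
  if (nrow(truth) == 0) return(NaN)
  mean(truth$structure %in% candidates$structure)
}
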