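test_that("path grouping keeps the minimal-L point per model size", {
  # sizes [1,2,2,3]: best of the size-2 pair is the lower L
  phi <- rbind(c(0.1, 0, 0), c(0.1, 0.2, 0), c(0.2, 0.3, 0), c(0.2, 0.3, 0.1))
  path <- fake_path(h = c(1L, 2L, 2L, 3L), L = c(10, 6, 5, 4.5), phi)
  groups <- group_path(path)
  expect_equal(groups$h, c(1L, 2L, 3L))
  expect_equal(groups$L, c(10, 5, 4.5))
  expect_equal(groups$k[groups$h == 2], 2)
  expect_equal(groups$phi[[2]], c(0.2, 0.3, 0))

  # equal L within a group: the earlier iteration wins
  path2 <- fake_path(h = c(2L, 2L), L = c(7, 7),
                     rbind(c(0.1, 0.2), c(0.3, 0.4)))
  g2 <- group_path(path2)
  expect_equal(g2$k, 0)
  expect_equal(g2$phi[[1]], c(0.1, 0.2))
})

test_that("grouping computed from iterates matches the path's own records", {
  g <- chain_gene()
  graph <- build_graph(g$exons, g$junctions)
  cands <- enumerate_candidates(graph, 1, 3)
  obs <- build_design(cands, g$exons, g$junctions, N = 1e6, read_length = 76)
  path <- blasso_path(obs, keep_phi = TRUE)
  from_iterates <- group_path(path)
  from_records <- dplyr::arrange(path$group_best, h)
  expect_equal(from_iterates$h, from_records$h)
  expect_equal(from_iterates$k, from_records$k)
  expect_equal(from_iterates$L, from_records$L)
  expect_equal(from_iterates$phi, from_records$phi)
})

test_that("sequential LRT prefers the smaller model unless fit improves", {
  phi <- rbind(c(0.5, 0, 0), c(0.5, 0.5, 0))

  # identical L: D = 0, p = 1 > alpha, smaller model kept
  sel <- select_model(fake_path(c(1L, 2L), c(8, 8), phi))
  expect_equal(sel$h, 1L)
  expect_equal(sel$lrt_trace$D, 0)
  expect_equal(sel$lrt_trace$p_value, 1)

  # better-fitting but not significantly: still the smaller model
  d_ns <- stats::qchisq(0.98, df = 1)  # p = 0.02 > 0.01
  sel <- select_model(fake_path(c(1L, 2L), c(8, 8 - d_ns / 2), phi))
  expect_equal(sel$h, 1L)

  # strongly better: larger model chosen
  d_sig <- stats::qchisq(0.999, df = 1)
  sel <- select_model(fake_path(c(1L, 2L), c(8, 8 - d_sig / 2), phi))
  expect_equal(sel$h, 2L)

  # a single group is returned unchanged
  sel <- select_model(fake_path(1L, 5, matrix(c(0.4, 0, 0), 1)))
  expect_equal(sel$h, 1L)
  expect_equal(nrow(sel$lrt_trace), 0)
  expect_equal(sel$phi, c(0.4, 0, 0))

  # worse larger model (negative D): p forced to 1, smaller kept
  sel <- select_model(fake_path(c(1L, 2L), c(8, 9), phi))
  expect_equal(sel$h, 1L)
  expect_equal(sel$lrt_trace$p_value, 1)
})

test_that("selection flips exactly at the chi-square boundary", {
  # kappa = 1: critical D is the 0.99 quantile of chi-square(1), ~6.635;
  # cross-checked by numerically integrating the density
  crit <- stats::qchisq(0.99, df = 1)
  expect_equal(crit, 6.6349, tolerance = 1e-4)
  by_integration <- stats::integrate(function(z) stats::dchisq(z, df = 1),
                                     crit, Inf)$value
  expect_equal(by_integration, 0.01, tolerance = 1e-4)

  phi <- rbind(c(0.5, 0, 0), c(0.5, 0.5, 0))
  just_below <- select_model(fake_path(c(1L, 2L), c(8, 8 - (crit - 1e-6) / 2),
                                       phi))
  just_above <- select_model(fake_path(c(1L, 2L), c(8, 8 - (crit + 1e-6) / 2),
                                       phi))
  expect_equal(just_below$h, 1L)
  expect_equal(just_above$h, 2L)
})

test_that("skipped model sizes use the size difference as degrees of freedom", {
  phi <- rbind(c(0.5, 0, 0), c(0.5, 0.5, 0.5))
  d <- 10
  sel <- select_model(fake_path(c(1L, 3L), c(8, 8 - d / 2), phi))
  expect_equal(sel$lrt_trace$kappa, 2L)
  expect_equal(sel$lrt_trace$p_value,
               stats::pchisq(d, df = 2, lower.tail = FALSE))
})

test_that("select_model never keeps a larger model with no fit gain", {
  # monotone parsimony over a random batch of synthetic paths
  set.seed(9)
  for (r in 1:25) {
    n_pts <- sample(3:6, 1)
    h <- sort(sample(1:4, n_pts, replace = TRUE))
    L <- 20 - cumsum(runif(n_pts, 0, 4))
    phi <- matrix(0.1, n_pts, 4)
    for (i in seq_len(n_pts)) phi[i, ] <- c(rep(0.1, h[i]), rep(0, 4 - h[i]))
    sel <- select_model(fake_path(as.integer(h), L, phi))
    groups <- group_path(fake_path(as.integer(h), L, phi))
    smaller_better <- groups$h < sel$h & groups$L <= sel$L
    expect_false(any(smaller_better))
    expect_true(all(sel$lrt_trace$p_value > 0 & sel$lrt_trace$p_value <= 1))
  }
})

test_that("ROC threshold equals the exhaustive Youden maximizer", {
  # interleaved 6-point set from the two classes
  preds <- tibble::tibble(
    rpkm = c(0.5, 1.0, 2.0, 3.0, 4.0, 6.0),
    is_annotated = c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE)
  )
  res <- roc_threshold(preds)
  # independent exhaustive scan over every cut point
  cuts <- sort(unique(preds$rpkm))
  youden <- vapply(cuts, function(tt) {
    sens <- mean(preds$rpkm[preds$is_annotated] >= tt)
    fpr <- mean(preds$rpkm[!preds$is_annotated] >= tt)
    sens - fpr
  }, numeric(1))
  best <- max(cuts[youden >= max(youden) - 1e-9])
  expect_equal(res$threshold, best)
  expect_equal(res$threshold, 3.0)  # hand check: sens 2/3, fpr 0 at T = 3

  # perfect separation: T is the smallest positive rpkm
  sep <- tibble::tibble(rpkm = c(0.2, 0.4, 5, 7, 9),
                        is_annotated = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(roc_threshold(sep)$threshold, 5)

  # single-class input is an error
  expect_error(roc_threshold(tibble::tibble(rpkm = 1:3,
                                            is_annotated = rep(TRUE, 3))),
               "undefined")
})

test_that("ROC threshold is rank-based and duplication-invariant", {
  set.seed(21)
  for (r in 1:10) {
    n <- sample(6:15, 1)
    preds <- tibble::tibble(rpkm = round(runif(n, 0, 10), 2),
                            is_annotated = runif(n) < 0.5)
    if (!any(preds$is_annotated) || all(preds$is_annotated)) next
    base <- roc_threshold(preds)$threshold
    dup <- roc_threshold(dplyr::bind_rows(preds, preds))$threshold
    expect_equal(dup, base)
    mono <- preds
    mono$rpkm <- exp(preds$rpkm / 3)   # strictly monotone transform
    expect_equal(roc_threshold(mono)$threshold, exp(base / 3))
  }
})

test_that("thresholding zeroes sub-threshold isoforms and records T", {
  sel <- new_fake_selection(c(0.1, 3.0, 3.5))
  cut <- apply_threshold(sel, 1.216)
  expect_equal(cut$h, 2L)
  expect_equal(cut$phi, c(0, 3.0, 3.5))
  expect_equal(cut$threshold, 1.216)
})

test_that("known/novel status is decided by the intron chain", {
  ann <- tibble::tibble(
    transcript_id = "known1",
    exons = list(tibble::tibble(start = c(0, 200, 400),
                                end = c(100, 300, 500)))
  )
  # identical transcript: known
  p1 <- tibble::tibble(transcript_id = "p1", exons = ann$exons)
  expect_equal(classify_against_annotation(p1, ann)$predictions$status,
               "known")
  # same introns, different end exon boundaries: still known
  p2 <- tibble::tibble(
    transcript_id = "p2",
    exons = list(tibble::tibble(start = c(20, 200, 400),
                                end = c(100, 300, 620)))
  )
  expect_equal(classify_against_annotation(p2, ann)$predictions$status,
               "known")
  # different intron chain: novel
  p3 <- tibble::tibble(
    transcript_id = "p3",
    exons = list(tibble::tibble(start = c(0, 400), end = c(100, 500)))
  )
  expect_equal(classify_against_annotation(p3, ann)$predictions$status,
               "novel")

  # ratios: 3 predictions, 1 annotated out of a 10-transcript annotation
  ann10 <- tibble::tibble(
    transcript_id = paste0("t", 1:10),
    exons = lapply(0:9, function(o) {
      tibble::tibble(start = c(0, 200) + o * 10000,
                     end = c(100, 300) + o * 10000)
    })
  )
  preds <- tibble::tibble(
    transcript_id = c("a", "b", "c"),
    exons = c(ann10$exons[1], list(
      tibble::tibble(start = 5e6, end = 5e6 + 100),
      tibble::tibble(start = c(7e6, 7e6 + 500), end = c(7e6 + 100, 7e6 + 600))
    ))
  )
  res <- classify_against_annotation(preds, ann10)
  expect_equal(res$sensitivity, 1 / 10)
  expect_equal(res$precision, 1 / 3)

  # coordinate shift invariance
  shift <- function(tbl, by) {
    tbl$exons <- lapply(tbl$exons, function(e) {
      e$start <- e$start + by; e$end <- e$end + by; e
    })
    tbl
  }
  res_shift <- classify_against_annotation(shift(preds, 1e7),
                                           shift(ann10, 1e7))
  expect_equal(res_shift$predictions$status, res$predictions$status)
  expect_equal(res_shift$sensitivity, res$sensitivity)

  # empty annotation: everything novel, sensitivity undefined
  res0 <- classify_against_annotation(preds, ann10[0, ])
  expect_true(all(res0$predictions$status == "novel"))
  expect_true(is.nan(res0$sensitivity))
})

test_that("single-exon transcripts match by reciprocal 50% overlap", {
  ann <- tibble::tibble(transcript_id = "s",
                        exons = list(tibble::tibble(start = 0, end = 100)))
  hit <- tibble::tibble(transcript_id = "p",
                        exons = list(tibble::tibble(start = 40, end = 120)))
  miss <- tibble::tibble(transcript_id = "p",
                         exons = list(tibble::tibble(start = 60, end = 300)))
  expect_equal(classify_against_annotation(hit, ann)$predictions$status,
               "known")
  expect_equal(classify_against_annotation(miss, ann)$predictions$status,
               "novel")
})

test_that("fold-change screening selects differential and specific isoforms", {
  a <- tibble::tibble(
    structure = c("s1", "s2", "s3", "n1", "n2"),
    status = c("known", "known", "known", "novel", "novel"),
    rpkm = c(10, 10, 4, 6, 3)
  )
  b <- tibble::tibble(
    structure = c("s1", "s2", "s3"),
    status = c("known", "known", "known"),
    rpkm = c(4, 6, 10)
  )
  res <- fold_change_compare(a, b, min_fc = 2, min_rpkm = 5)
  # s1: 10/4 = 2.5x selected; s2: 10/6 < 2 not; s3: 4/10 = 0.4 <= 1/2 selected
  expect_setequal(res$differential_known$structure, c("s1", "s3"))
  # n1 at 6 RPKM absent in b: condition-specific; n2 below the floor: not
  expect_equal(res$specific_novel$structure, "n1")

  # zero denominator uses the pseudo-RPKM on both sides
  a2 <- tibble::tibble(structure = "z", status = "known", rpkm = 1)
  b2 <- tibble::tibble(structure = "z", status = "known", rpkm = 0)
  res2 <- fold_change_compare(a2, b2)
  expect_equal(res2$differential_known$fold_change, 1.1 / 0.1)

  # empty inputs give empty outputs
  res3 <- fold_change_compare(a[0, ], b[0, ])
  expect_equal(nrow(res3$differential_known), 0)
  expect_equal(nrow(res3$specific_novel), 0)
})
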