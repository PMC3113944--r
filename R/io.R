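# Readers and writers. Internal coordinates are 0-based half-open
# throughout; BED is already in that system, GTF is converted to 1-based
# inclusive on output and back on input. Readers reject malformed records
# with the offending line number rather than silently coercing.

#' Read splice junctions from a TopHat-style junctions BED file
#'
#' Each BED12 record spans a junction: the two blocks are the anchors on the
#' flanking exons, the score column carries the number of supporting reads.
#' The junction's donor end is `chromStart + blockSizes[1]` and its acceptor
#' start is `chromStart + blockStarts[2]` (0-based half-open).
#'
#' @param path Path to the BED file. `track`/`browser` header lines and
#'   blank lines are skipped.
#' @return A tibble with columns `chrom`, `donor_end`, `acceptor_start`,
#'   `count`, `name`, `strand`.
#' @export
read_junctions_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  out <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || grepl("^(track|browser|#)", line)) next
    f <- strsplit(line, "\t")[[1]]
    if (length(f) < 12) {
      abort(paste0(path, ":", ln, ": expected 12 BED fields, found ",
                   length(f)))
    }
    score <- suppressWarnings(as.numeric(f[5]))
    if (is.na(score) || score < 0) {
      abort(paste0(path, ":", ln, ": score (read count) must be a ",
                   "non-negative number, found '", f[5], "'"))
    }
    n_blocks <- suppressWarnings(as.integer(f[10]))
    sizes <- suppressWarnings(as.numeric(strsplit(f[11], ",")[[1]]))
    starts <- suppressWarnings(as.numeric(strsplit(f[12], ",")[[1]]))
    if (is.na(n_blocks) || n_blocks != 2 || length(sizes) < 2 ||
        length(starts) < 2 || anyNA(sizes[1:2]) || anyNA(starts[1:2])) {
      abort(paste0(path, ":", ln,
                   ": junction records need exactly 2 blocks"))
    }
    chrom_start <- suppressWarnings(as.numeric(f[2]))
    if (is.na(chrom_start)) {
      abort(paste0(path, ":", ln, ": malformed chromStart '", f[2], "'"))
    }
    out[[length(out) + 1L]] <- tibble(
      chrom = f[1],
      donor_end = chrom_start + sizes[1],
      acceptor_start = chrom_start + starts[2],
      count = score,
      name = f[4],
      strand = f[6]
    )
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(0), donor_end = numeric(0),
                  acceptor_start = numeric(0), count = numeric(0),
                  name = character(0), strand = character(0)))
  }
  dplyr::bind_rows(out)
}

#' Read a UCSC knownGene-style annotation table
#'
#' Tab-separated, no header; the first ten fields are `name`, `chrom`,
#' `strand`, `txStart`, `txEnd`, `cdsStart`, `cdsEnd`, `exonCount`,
#' `exonStarts`, `exonEnds`, with the exon lists comma-terminated. Records
#' whose exon list length disagrees with `exonCount` are rejected with their
#' line number.
#'
#' @param path Path to the table.
#' @return A tibble with columns `name`, `chrom`, `strand`, `txStart`,
#'   `txEnd` and an `exons` list column of `start`/`end` tibbles (0-based
#'   half-open).
#' @export
read_knowngene <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  out <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (trimws(line) == "" || grepl("^#", line)) next
    f <- strsplit(line, "\t")[[1]]
    if (length(f) < 10) {
      abort(paste0(path, ":", ln, ": expected at least 10 fields, found ",
                   length(f)))
    }
    n_ex <- suppressWarnings(as.integer(f[8]))
    starts <- suppressWarnings(as.numeric(
      strsplit(sub(",$", "", f[9]), ",")[[1]]))
    ends <- suppressWarnings(as.numeric(
      strsplit(sub(",$", "", f[10]), ",")[[1]]))
    if (is.na(n_ex) || length(starts) != n_ex || length(ends) != n_ex ||
        anyNA(starts) || anyNA(ends)) {
      abort(paste0(path, ":", ln, ": exonCount (", f[8],
                   ") disagrees with the exon lists"))
    }
    out[[length(out) + 1L]] <- tibble(
      name = f[1], chrom = f[2], strand = f[3],
      txStart = as.numeric(f[4]), txEnd = as.numeric(f[5]),
      exons = list(tibble(start = starts, end = ends))
    )
  }
  if (length(out) == 0) {
    return(tibble(name = character(0), chrom = character(0),
                  strand = character(0), txStart = numeric(0),
                  txEnd = numeric(0), exons = list()))
  }
  dplyr::bind_rows(out)
}

#' Write a knownGene-style annotation table
#'
#' Inverse of [read_knowngene()]; parse -> write -> parse is the identity.
#'
#' @param annotation Tibble as returned by [read_knowngene()].
#' @param path Output path.
#' @export
write_knowngene <- function(annotation, path) {
  lines <- vapply(seq_len(nrow(annotation)), function(i) {
    ex <- annotation$exons[[i]]
    paste(annotation$name[i], annotation$chrom[i], annotation$strand[i],
          format(annotation$txStart[i], scientific = FALSE),
          format(annotation$txEnd[i], scientific = FALSE),
          format(annotation$txStart[i], scientific = FALSE),
          format(annotation$txStart[i], scientific = FALSE),
          nrow(ex),
          paste0(paste(format(ex$start, scientific = FALSE, trim = TRUE),
                       collapse = ","), ","),
          paste0(paste(format(ex$end, scientific = FALSE, trim = TRUE),
                       collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write predicted isoforms as GTF 2.2
#'
#' One `transcript` line followed by its `exon` lines per isoform, 1-based
#' inclusive coordinates, with `gene_id`, `transcript_id`, `RPKM` (three
#' decimals) and `status` ("known"/"novel") attributes. Output order is by
#' chromosome, start, then transcript id, so two runs on the same input are
#' byte-identical.
#'
#' @param transcripts Tibble with columns `gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `rpkm`, `status` and an `exons` list column
#'   (`start`/`end`, 0-based half-open).
#' @param path Output path.
#' @export
write_gtf <- function(transcripts, path) {
  transcripts <- as_tibble(transcripts)
  tx_start <- vapply(transcripts$exons, function(e) min(e$start), numeric(1))
  o <- order(transcripts$chrom, tx_start, transcripts$transcript_id)
  transcripts <- transcripts[o, ]
  tx_start <- tx_start[o]
  lines <- character(0)
  for (i in seq_len(nrow(transcripts))) {
    ex <- normalize_exons(transcripts$exons[[i]])
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; RPKM "%.3f"; status "%s";',
      transcripts$gene_id[i], transcripts$transcript_id[i],
      transcripts$rpkm[i], transcripts$status[i])
    chrom <- transcripts$chrom[i]
    mk <- function(feature, s0, e0) {
      paste(chrom, "isopath", feature,
            format(s0 + 1, scientific = FALSE, trim = TRUE),
            format(e0, scientific = FALSE, trim = TRUE),
            ".", transcripts$strand[i], ".", attrs, sep = "\t")
    }
    lines <- c(lines, mk("transcript", min(ex$start), max(ex$end)),
               vapply(seq_len(nrow(ex)),
                      function(j) mk("exon", ex$start[j], ex$end[j]),
                      character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GTF written by [write_gtf()] back into a transcript table
#'
#' @param path GTF path.
#' @return A tibble in the same shape [write_gtf()] consumes.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  recs <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (trimws(line) == "" || grepl("^#", line)) next
    f <- strsplit(line, "\t")[[1]]
    if (length(f) < 9) {
      abort(paste0(path, ":", ln, ": expected 9 GTF fields, found ",
                   length(f)))
    }
    get_attr <- function(key) {
      mm <- regmatches(f[9], regexec(paste0(key, ' "([^"]*)"'), f[9]))[[1]]
      if (length(mm) < 2) NA_character_ else mm[2]
    }
    recs[[length(recs) + 1L]] <- tibble(
      chrom = f[1], feature = f[3],
      start = as.numeric(f[4]) - 1, end = as.numeric(f[5]),
      strand = f[7], gene_id = get_attr("gene_id"),
      transcript_id = get_attr("transcript_id"),
      rpkm = as.numeric(get_attr("RPKM")), status = get_attr("status")
    )
  }
  recs <- dplyr::bind_rows(recs)
  ex <- recs[recs$feature == "exon", ]
  tx <- recs[recs$feature == "transcript", ]
  tx$exons <- lapply(tx$transcript_id, function(id) {
    e <- ex[ex$transcript_id == id, c("start", "end")]
    e[order(e$start), ]
  })
  tx[, c("gene_id", "transcript_id", "chrom", "strand", "rpkm", "status",
         "exons")]
}

#' Write a gene's counts document
#'
#' The counts interchange document is a small JSON file carrying everything
#' one gene needs to be analysed without alignment tooling: exon
#' definitions with read counts, junction counts, library size and read
#' length, plus optional annotated transcript bounds and (for simulated
#' genes) the ground truth.
#'
#' @param counts A `sim_counts` object or a list with `exons`, `junctions`,
#'   `N`, `read_length`.
#' @param path Output path.
#' @param gene_id Gene identifier stored in the document.
#' @param tx_bounds Optional `txStart`/`txEnd` data frame.
#' @param truth Optional truth table (`structure`, `rpkm`).
#' @export
write_counts <- function(counts, path, gene_id = "gene",
                         tx_bounds = NULL, truth = NULL) {
  doc <- list(
    gene_id = gene_id,
    N_total = counts$N,
    read_length = counts$read_length,
    exons = as.data.frame(
      counts$exons[, intersect(c("chrom", "start", "end", "count"),
                               names(counts$exons))]),
    junctions = as.data.frame(
      counts$junctions[, c("donor_end", "acceptor_start", "count")])
  )
  if (!is.null(tx_bounds)) doc$tx_bounds <- as.data.frame(tx_bounds)
  if (!is.null(truth)) doc$truth <- as.data.frame(truth)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a counts document written by [write_counts()]
#'
#' @param path JSON path.
#' @return A list with `gene_id`, `N`, `read_length`, `exons`, `junctions`
#'   tibbles, and `tx_bounds`/`truth` when present.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  exons <- as_tibble(doc$exons)
  if (!"length" %in% names(exons)) exons$length <- exons$end - exons$start
  junctions <- as_tibble(doc$junctions)
  if (nrow(junctions) == 0) {
    junctions <- tibble(donor_end = numeric(0), acceptor_start = numeric(0),
                        count = numeric(0))
  }
  out <- list(gene_id = doc$gene_id, N = doc$N_total,
              read_length = doc$read_length, exons = exons,
              junctions = junctions)
  if (!is.null(doc$tx_bounds)) out$tx_bounds <- as_tibble(doc$tx_bounds)
  if (!is.null(doc$truth)) out$truth <- as_tibble(doc$truth)
  out
}
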