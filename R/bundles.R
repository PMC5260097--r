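#' Reference bundles and the bundle index
#'
#' A *bundle* is a maximal continuous genomic region covered by overlapping
#' fragments and/or known gene models, allowing gaps of at most
#' `gap_threshold` bp (default 50). Bundles are the independent units of
#' expression estimation: fragments in one bundle are never compatible with
#' transcripts in another, because distinct bundles are separated by more
#' than the gap threshold.
#'
#' A `bundle_index` stores, per sample, the sorted bundles of each
#' chromosome together with the global mapped-fragment total, so that a
#' novel transcript's minimum spanning bundle can be found without touching
#' the alignment file.
#'
#' @name bundle_index
NULL

BUNDLE_INDEX_VERSION <- "1"

#' Build a per-sample bundle index
#'
#' Merges fragment spans and reference transcript spans transitively: two
#' intervals join when they overlap or lie within `gap_threshold` bp of each
#' other (a gap of exactly `gap_threshold` merges; one more bp splits). Each
#' maximal merged interval becomes a bundle carrying its member transcripts
#' and the count of fragments whose span overlaps it.
#'
#' @param alignment_path Coordinate-sorted, indexed BAM file.
#' @param ann An [annotation()] (may be empty).
#' @param gap_threshold Maximum tolerated gap in bp.
#' @param sample_id Sample label stored in the index; defaults to the
#'   alignment file name without extension.
#' @param fragments Optional prefetched whole-file [fragment_set] for the
#'   same file (avoids re-reading the alignments).
#' @return A `bundle_index` object.
#' @examples
#' \dontrun{
#' idx <- build_bundle_index("sample1.bam", read_gtf("genes.gtf"))
#' }
#' @export
build_bundle_index <- function(alignment_path, ann,
                               gap_threshold = 50,
                               sample_id = NULL, fragments = NULL) {
  stopifnot(inherits(ann, "annotation"), gap_threshold >= 0)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[sb]am$", "", basename(alignment_path))
  }
  fs <- if (is.null(fragments)) {
    fetch_fragments(alignment_path, region = NULL)
  } else {
    fragments
  }
  hdr <- Rsamtools::scanBamHeader(alignment_path)[[1L]]$targets

  tx_ids <- names(ann$transcripts)
  tx_spans <- if (length(tx_ids)) {
    data.frame(
      chrom = vapply(ann$transcripts, `[[`, "", "chrom"),
      start = vapply(ann$transcripts, function(t) t$exons$start[1L], 0),
      end = vapply(ann$transcripts, function(t) t$exons$end[nrow(t$exons)], 0),
      id = tx_ids, stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               id = character(0), stringsAsFactors = FALSE)
  }
  missing_chroms <- setdiff(unique(tx_spans$chrom), names(hdr))
  if (length(missing_chroms)) {
    warning("annotation chromosome(s) absent from alignment header: ",
            paste(missing_chroms, collapse = ", "),
            "; their bundles are built from gene models alone")
  }

  frag_spans <- fs$fragments[, c("chrom", "span_start", "span_end")]
  names(frag_spans) <- c("chrom", "start", "end")
  chroms <- sort(unique(c(tx_spans$chrom, frag_spans$chrom)))
  bundles <- lapply(chroms, function(ch) {
    ft <- frag_spans[frag_spans$chrom == ch, , drop = FALSE]
    tt <- tx_spans[tx_spans$chrom == ch, , drop = FALSE]
    s <- c(ft$start, tt$start); e <- c(ft$end, tt$end)
    m <- merge_intervals(s, e, gap_threshold)
    # every span belongs to exactly one merged interval
    grp <- merge_group_ids(s, e, gap_threshold)
    nf <- nrow(ft)
    fgrp <- grp[seq_len(nf)]
    cnt <- tabulate(fgrp, nbins = nrow(m))
    bas <- rep(0, nrow(m))
    if (nf) {
      agg <- tapply(fs$fragments$bases[fs$fragments$chrom == ch], fgrp, sum)
      bas[as.integer(names(agg))] <- as.numeric(agg)
    }
    members <- rep(list(character(0)), nrow(m))
    if (nrow(tt)) {
      tgrp <- grp[nf + seq_len(nrow(tt))]
      for (g in unique(tgrp)) members[[g]] <- sort(tt$id[tgrp == g])
    }
    data.frame(chrom = ch, start = m$start, end = m$end,
               local_fragment_total = as.integer(cnt),
               local_bases = bas,
               members = I(members), stringsAsFactors = FALSE)
  })
  bundles <- do.call(rbind, bundles)
  if (is.null(bundles)) {
    bundles <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), local_fragment_total = integer(0),
                          local_bases = numeric(0),
                          members = I(list()), stringsAsFactors = FALSE)
  }
  rownames(bundles) <- NULL
  structure(
    list(sample_id = sample_id, bundles = bundles,
         global_fragment_total = nrow(fs$fragments),
         global_bases = sum(fs$fragments$bases),
         gap_threshold = gap_threshold),
    class = "bundle_index"
  )
}

#' @export
print.bundle_index <- function(x, ...) {
  cat(sprintf(paste0("<bundle_index> sample '%s': %d bundle(s), ",
                     "%d mapped fragment(s), gap threshold %g bp\n"),
              x$sample_id, nrow(x$bundles), x$global_fragment_total,
              x$gap_threshold))
  invisible(x)
}

#' Save / load a bundle index
#'
#' Versioned tab-separated text format: `#`-prefixed header lines
#' (`version`, `sample_id`, `global_fragment_total`, `global_bases`,
#' `gap_threshold`) followed by one row per bundle: chrom, start, end,
#' local fragment total, local aligned bases, comma-joined member
#' transcript ids. `load_bundle_index(save_bundle_index(i))` is lossless.
#'
#' @param index A `bundle_index`.
#' @param path File path.
#' @return `save_bundle_index()`: `path` invisibly; `load_bundle_index()`:
#'   the restored `bundle_index`.
#' @export
save_bundle_index <- function(index, path) {
  stopifnot(inherits(index, "bundle_index"))
  b <- index$bundles
  hdr <- c(
    paste0("#version\t", BUNDLE_INDEX_VERSION),
    paste0("#sample_id\t", index$sample_id),
    paste0("#global_fragment_total\t",
           format(index$global_fragment_total, scientific = FALSE)),
    paste0("#global_bases\t", format(index$global_bases, scientific = FALSE)),
    paste0("#gap_threshold\t", format(index$gap_threshold, scientific = FALSE))
  )
  rows <- if (nrow(b)) {
    sprintf("%s\t%d\t%d\t%d\t%s\t%s",
            b$chrom, as.integer(b$start), as.integer(b$end),
            b$local_fragment_total,
            format(b$local_bases, scientific = FALSE, trim = TRUE),
            vapply(b$members, paste, "", collapse = ","))
  } else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, rows), con, sep = "\n")
  invisible(path)
}

#' @rdname save_bundle_index
#' @export
load_bundle_index <- function(path) {
  if (!file.exists(path)) stop("index file not found: ", path)
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  kv <- strsplit(hdr_lines, "\t", fixed = TRUE)
  keys <- sub("^#", "", vapply(kv, `[[`, "", 1L))
  vals <- vapply(kv, function(x) if (length(x) > 1L) x[[2L]] else "", "")
  need <- c("version", "sample_id", "global_fragment_total", "global_bases",
            "gap_threshold")
  if (!all(need %in% keys)) {
    stop("bundle index format error: missing header field(s) ",
         paste(setdiff(need, keys), collapse = ", "))
  }
  h <- stats::setNames(vals, keys)
  if (h[["version"]] != BUNDLE_INDEX_VERSION) {
    stop("bundle index format error: version '", h[["version"]],
         "' not supported (expected ", BUNDLE_INDEX_VERSION, ")")
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) < 5L)) {
      stop("bundle index format error: malformed bundle row")
    }
    fld <- function(i) vapply(parts, function(p) p[i], "")
    memb <- vapply(parts, function(p) if (length(p) >= 6L) p[6L] else "", "")
    start <- suppressWarnings(as.numeric(fld(2L)))
    end <- suppressWarnings(as.numeric(fld(3L)))
    cnt <- suppressWarnings(as.integer(fld(4L)))
    bas <- suppressWarnings(as.numeric(fld(5L)))
    if (anyNA(start) || anyNA(end) || anyNA(cnt) || anyNA(bas)) {
      stop("bundle index format error: non-numeric coordinate or count")
    }
    bundles <- data.frame(
      chrom = fld(1L), start = start, end = end,
      local_fragment_total = cnt, local_bases = bas,
      members = I(lapply(memb, function(m) {
        if (nzchar(m)) strsplit(m, ",", fixed = TRUE)[[1L]] else character(0)
      })),
      stringsAsFactors = FALSE)
  } else {
    bundles <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), local_fragment_total = integer(0),
                          local_bases = numeric(0), members = I(list()),
                          stringsAsFactors = FALSE)
  }
  structure(
    list(sample_id = h[["sample_id"]], bundles = bundles,
         global_fragment_total = as.numeric(h[["global_fragment_total"]]),
         global_bases = as.numeric(h[["global_bases"]]),
         gap_threshold = as.numeric(h[["gap_threshold"]])),
    class = "bundle_index"
  )
}

#' Export bundles as BED for inspection
#'
#' @param index A `bundle_index`.
#' @param path Output BED file (0-based half-open, as BED requires).
#' @export
export_bed <- function(index, path) {
  b <- index$bundles
  lines <- sprintf("%s\t%d\t%d\tbundle_%d\t%d\t.",
                   b$chrom, as.integer(b$start), as.integer(b$end),
                   seq_len(nrow(b)), b$local_fragment_total)
  writeLines(lines, path)
  invisible(path)
}

#' Infer the minimum spanning bundle (MSB) of a novel transcript
#'
#' Starting from the transcript's genomic span, merges in every bundle that
#' overlaps the current region or lies within the index's gap threshold of
#' it, and repeats until a fixed point. The result is the smallest
#' bundle-consistent region containing the transcript — exactly the bundle
#' that would be produced by rebuilding bundles from scratch with the
#' novel transcript's span added to the interval set.
#'
#' @param novel A [transcript_model()] (absent from the index's annotation).
#' @param index A `bundle_index` for the sample.
#' @param ann The [annotation()] the index was built against; used to attach
#'   the reference transcripts inside the MSB.
#' @return An object of class `msb_result` with elements `region` (one-row
#'   interval data.frame), `reference_transcripts` (list of
#'   `transcript_model`s whose span overlaps the region), `novel_transcript`
#'   and `source_bundles` (rows of the index merged in).
#' @export
infer_msb <- function(novel, index, ann) {
  stopifnot(inherits(novel, "transcript_model"),
            inherits(index, "bundle_index"),
            inherits(ann, "annotation"))
  gap <- index$gap_threshold
  span <- tx_span(novel)
  b <- index$bundles[index$bundles$chrom == novel$chrom, , drop = FALSE]
  cur_s <- span$start; cur_e <- span$end
  merged <- rep(FALSE, nrow(b))
  repeat {
    cand <- !merged &
      interval_gap(b$start, b$end, cur_s, cur_e) <= gap
    if (!any(cand)) break
    merged <- merged | cand
    cur_s <- min(cur_s, b$start[merged])
    cur_e <- max(cur_e, b$end[merged])
  }
  region <- genome_interval(novel$chrom, cur_s, cur_e)
  refs <- Filter(function(t) {
    t$chrom == region$chrom &&
      t$exons$start[1L] < region$end &&
      t$exons$end[nrow(t$exons)] > region$start
  }, ann$transcripts)
  structure(
    list(region = region,
         reference_transcripts = unname(refs),
         novel_transcript = novel,
         source_bundles = b[merged, , drop = FALSE]),
    class = "msb_result"
  )
}

#' @export
print.msb_result <- function(x, ...) {
  cat(sprintf("<msb_result> %s:%g-%g for '%s': %d reference transcript(s), %d source bundle(s)\n",
              x$region$chrom, x$region$start, x$region$end,
              x$novel_transcript$transcript_id,
              length(x$reference_transcripts), nrow(x$source_bundles)))
  invisible(x)
}
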