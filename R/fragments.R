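#' Aligned fragments
#'
#' The counting unit throughout the package is the *fragment*: one sequenced
#' cDNA insert, i.e. both mates of a pair taken together (the F in FPKM).
#' Unpaired reads count as single-mate fragments. A `fragment_set` holds
#' fragments in long format for speed:
#'
#' * `fragments`: one row per fragment — `fragment_id`, `chrom`,
#'   `span_start`, `span_end` (leftmost to rightmost aligned bp, 0-based
#'   half-open), `paired`, `bases` (summed aligned block lengths).
#' * `blocks`: aligned blocks (`M`/`=`/`X` CIGAR ops), one row per block,
#'   keyed by `frag` (row index into `fragments`).
#' * `introns`: splice gaps (`N` ops), same keying.
#'
#' @name fragment_set
NULL

new_fragment_set <- function(fragments, blocks, introns) {
  structure(list(fragments = fragments, blocks = blocks, introns = introns),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> %d fragment(s), %d block(s), %d intron(s)\n",
              nrow(x$fragments), nrow(x$blocks), nrow(x$introns)))
  invisible(x)
}

#' Number of fragments in a fragment_set
#' @param x A `fragment_set`.
#' @export
n_fragments <- function(x) nrow(x$fragments)

empty_fragment_set <- function() {
  new_fragment_set(
    data.table::data.table(fragment_id = character(0), chrom = character(0),
                           span_start = numeric(0), span_end = numeric(0),
                           paired = logical(0), bases = numeric(0)),
    data.table::data.table(frag = integer(0), start = numeric(0),
                           end = numeric(0)),
    data.table::data.table(frag = integer(0), start = numeric(0),
                           end = numeric(0))
  )
}

#' Fetch aligned fragments from a BAM file
#'
#' Reads mapped primary alignments (secondary, supplementary and unmapped
#' records are excluded), merges mates by query name into fragments, and
#' returns each fragment once. `M`/`=`/`X` CIGAR operations become aligned
#' blocks, `N` operations become introns.
#'
#' When `region` is given the BAM index is used and a fragment is returned
#' iff its span (leftmost to rightmost aligned bp over both mates) overlaps
#' the region. The query window is padded by `pad` bp so that a mate lying
#' outside the region whose inner gap covers it is still recovered; for
#' regions that respect bundle boundaries this is exact.
#'
#' @param alignment_path Path to a BAM file (coordinate-sorted; indexed when
#'   `region` is used).
#' @param region `NULL` for the whole file, or a one-row `data.frame` with
#'   `chrom`, `start`, `end` (0-based half-open), e.g. from
#'   [genome_interval()].
#' @param pad Padding (bp) added to region queries before span filtering.
#' @return A [fragment_set].
#' @export
fetch_fragments <- function(alignment_path, region = NULL, pad = 5000) {
  if (!file.exists(alignment_path)) {
    stop("alignment file not found: ", alignment_path)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  what <- c("qname", "flag", "rname", "pos", "cigar")
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(flag = flags, what = what)
    res <- Rsamtools::scanBam(alignment_path, param = param)[[1L]]
  } else {
    region <- as.data.frame(region)
    stopifnot(nrow(region) == 1L,
              all(c("chrom", "start", "end") %in% names(region)))
    bf <- Rsamtools::BamFile(alignment_path)
    hdr <- Rsamtools::scanBamHeader(alignment_path)[[1L]]$targets
    if (!region$chrom %in% names(hdr)) {
      warning("chromosome '", region$chrom,
              "' absent from alignment header; returning no fragments")
      return(empty_fragment_set())
    }
    qstart <- max(1, region$start + 1 - pad)             # 1-based closed
    qend <- min(as.numeric(hdr[[region$chrom]]), region$end + pad)
    if (qend < qstart) return(empty_fragment_set())      # beyond the contig
    which <- GenomicRanges::GRanges(region$chrom,
                                    IRanges::IRanges(qstart, qend))
    param <- Rsamtools::ScanBamParam(flag = flags, what = what,
                                     which = which)
    res <- Rsamtools::scanBam(alignment_path, param = param)[[1L]]
  }
  if (length(res$qname) == 0L) return(empty_fragment_set())

  cig <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    res$cigar, pos = res$pos, ops = c("M", "=", "X"))
  ntr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    res$cigar, pos = res$pos, ops = "N")

  nb <- S4Vectors::elementNROWS(cig)
  ub <- unlist(cig, use.names = FALSE)
  rec_blocks <- data.table::data.table(
    rec = rep(seq_along(res$qname), nb),
    start = as.numeric(IRanges::start(ub)) - 1,          # -> 0-based half-open
    end = as.numeric(IRanges::end(ub)))
  ni <- S4Vectors::elementNROWS(ntr)
  ui <- unlist(ntr, use.names = FALSE)
  rec_introns <- data.table::data.table(
    rec = rep(seq_along(res$qname), ni),
    start = as.numeric(IRanges::start(ui)) - 1,
    end = as.numeric(IRanges::end(ui)))

  recs <- data.table::data.table(
    rec = seq_along(res$qname),
    qname = res$qname,
    chrom = as.character(res$rname),
    paired = bitwAnd(res$flag, 1L) > 0L)
  # one fragment per query name (mates merged, counted once)
  recs[, frag := as.integer(factor(qname, levels = unique(qname)))]
  frag <- start <- end <- qname <- chrom <- paired <- NULL  # NSE notes
  frags <- recs[, list(fragment_id = qname[1L], chrom = chrom[1L],
                       paired = any(paired)), by = frag]
  rec_blocks[, frag := recs$frag[rec]]
  rec_introns[, frag := recs$frag[rec]]
  spans <- rec_blocks[, list(span_start = min(start), span_end = max(end),
                             bases = sum(end - start)), by = frag]
  frags <- merge(frags, spans, by = "frag", sort = TRUE)

  if (!is.null(region)) {
    keep <- frags$span_start < region$end & frags$span_end > region$start &
      frags$chrom == region$chrom
    frags <- frags[keep]
  }
  if (nrow(frags) == 0L) return(empty_fragment_set())
  # re-key fragments 1..n
  key <- integer(max(frags$frag)); key[frags$frag] <- seq_len(nrow(frags))
  blocks <- rec_blocks[frag %in% frags$frag,
                       list(frag = key[frag], start, end)]
  introns <- rec_introns[frag %in% frags$frag,
                         list(frag = key[frag], start, end)]
  data.table::setorder(blocks, frag, start, end)
  introns <- unique(introns)  # both mates may signal the same splice
  data.table::setorder(introns, frag, start, end)
  frags[, frag := NULL]
  new_fragment_set(
    frags[, list(fragment_id, chrom, span_start, span_end, paired, bases)],
    blocks, introns)
}

#' Count mapped fragments in a whole BAM file
#'
#' Distinct query names among mapped primary records; also returns total
#' aligned bases for the base-length accounting mode.
#' @inheritParams fetch_fragments
#' @return List with `n_fragments` and `bases`.
#' @keywords internal
count_all_fragments <- function(alignment_path) {
  fs <- fetch_fragments(alignment_path, region = NULL)
  list(n_fragments = nrow(fs$fragments), bases = sum(fs$fragments$bases))
}
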