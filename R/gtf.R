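#' Transcript models and annotations
#'
#' A `transcript_model` is an exon chain with gene/transcript identity on a
#' strand; an `annotation` is a collection of transcript models keyed by
#' transcript id together with the gene -> transcript mapping. Exons are
#' stored 0-based half-open, sorted, and must not overlap one another.
#'
#' @param transcript_id,gene_id Identifiers (non-empty strings).
#' @param chrom Chromosome name.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @param exons `data.frame` with `start`/`end` columns, 0-based half-open.
#' @return An object of class `transcript_model`.
#' @examples
#' tx <- transcript_model("T1", "G1", "chr1", "+",
#'                        data.frame(start = c(100, 300), end = c(200, 400)))
#' tx_length(tx)   # 200
#' tx_span(tx)     # [100, 400)
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand = ".",
                             exons) {
  stopifnot(is.character(transcript_id), nzchar(transcript_id),
            is.character(gene_id), nzchar(gene_id),
            is.character(chrom), nzchar(chrom))
  if (!strand %in% c("+", "-", ".")) stop("strand must be one of '+', '-', '.'")
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.numeric(exons$start); exons$end <- as.numeric(exons$end)
  if (nrow(exons) == 0L) stop("transcript '", transcript_id, "' has no exons")
  if (any(exons$end <= exons$start)) {
    stop("transcript '", transcript_id, "' has an empty or inverted exon")
  }
  exons <- exons[order(exons$start, exons$end), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    stop("transcript '", transcript_id, "' has overlapping exons")
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s:%s [%d exon(s), %d bp]\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), tx_length(x)))
  invisible(x)
}

#' Transcript span and mature length
#'
#' `tx_span()` returns the genomic interval from the first exon start to the
#' last exon end; `tx_length()` the summed exon length (the mature,
#' spliced length); `tx_introns()` the gaps between consecutive exons.
#' @param tx A `transcript_model`.
#' @return `tx_span()`: one-row interval data.frame; `tx_length()`: numeric
#'   bp; `tx_introns()`: data.frame of `start`/`end`.
#' @export
tx_span <- function(tx) {
  genome_interval(tx$chrom, tx$exons$start[1L], tx$exons$end[nrow(tx$exons)])
}

#' @rdname tx_span
#' @export
tx_length <- function(tx) sum(tx$exons$end - tx$exons$start)

#' @rdname tx_span
#' @export
tx_introns <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2L) return(data.frame(start = numeric(0), end = numeric(0)))
  data.frame(start = tx$exons$end[-n], end = tx$exons$start[-1L])
}

#' Build an annotation from transcript models
#'
#' @param transcripts List of `transcript_model` objects with unique ids.
#' @return An object of class `annotation` with elements `transcripts`
#'   (named list) and `genes` (named list mapping gene_id to transcript ids).
#' @export
annotation <- function(transcripts = list()) {
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  if (anyDuplicated(ids)) {
    stop("duplicate transcript_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(transcripts) <- ids
  gene_ids <- vapply(transcripts, `[[`, "", "gene_id")
  genes <- split(ids, gene_ids)
  genes <- genes[order(names(genes))]
  structure(list(transcripts = transcripts, genes = genes),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("<annotation> %d transcript(s) in %d gene(s)\n",
              length(x$transcripts), length(x$genes)))
  invisible(x)
}

#' @export
length.annotation <- function(x) length(x$transcripts)

#' Read a GTF annotation
#'
#' Parses the Ensembl/GENCODE GTF dialect (1-based inclusive coordinates,
#' `key "value";` attributes) through \pkg{rtracklayer} and converts exon
#' records into 0-based half-open [transcript_model()]s grouped by
#' `transcript_id`. Non-exon feature lines are ignored.
#'
#' @param path Path to a GTF file.
#' @return An [annotation()].
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("failed to parse GTF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0L) return(annotation(list()))
  mc <- names(S4Vectors::mcols(gr))
  txid <- if ("transcript_id" %in% mc) as.character(gr$transcript_id)
          else rep(NA_character_, length(gr))
  gid <- if ("gene_id" %in% mc) as.character(gr$gene_id)
         else rep(NA_character_, length(gr))
  bad <- which(is.na(txid) | !nzchar(txid))
  if (length(bad)) {
    stop("GTF parse error: exon record(s) ", paste(bad, collapse = ", "),
         " (in file order) lack a transcript_id attribute")
  }
  bad <- which(is.na(gid) | !nzchar(gid))
  if (length(bad)) {
    stop("GTF parse error: exon record(s) ", paste(bad, collapse = ", "),
         " lack a gene_id attribute")
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,  # 1-based inclusive -> 0-based
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = txid, gene_id = gid, stringsAsFactors = FALSE
  )
  df$strand[df$strand == "*"] <- "."
  txs <- lapply(split(df, df$transcript_id), function(d) {
    if (length(unique(d$chrom)) > 1L) {
      stop("transcript '", d$transcript_id[1L],
           "' has exons on multiple chromosomes")
    }
    transcript_model(d$transcript_id[1L], d$gene_id[1L], d$chrom[1L],
                     d$strand[1L], d[, c("start", "end")])
  })
  annotation(unname(txs))
}

#' Write an annotation as GTF
#'
#' Emits one `exon` line per exon in 1-based inclusive coordinates with
#' attributes `gene_id` then `transcript_id`. The output is stable:
#' transcripts are ordered by chromosome, span start and id, so
#' `read_gtf(write_gtf(a))` reproduces `a` and a second round trip is
#' byte-identical.
#'
#' @param ann An [annotation()].
#' @param path Output file path.
#' @param source_label Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path, source_label = "msbquant") {
  stopifnot(inherits(ann, "annotation"))
  txs <- ann$transcripts
  lines <- character(0)
  if (length(txs)) {
    ord <- order(
      vapply(txs, `[[`, "", "chrom"),
      vapply(txs, function(t) t$exons$start[1L], 0),
      vapply(txs, `[[`, "", "transcript_id")
    )
    lines <- unlist(lapply(txs[ord], function(tx) {
      sprintf(
        '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
        tx$chrom, source_label,
        as.integer(tx$exons$start + 1), as.integer(tx$exons$end),
        tx$strand, tx$gene_id, tx$transcript_id
      )
    }), use.names = FALSE)
  }
  con <- file(path, open = "wb")  # fixed newline convention for byte identity
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Map genomic positions to mature-transcript coordinates
#'
#' @param tx A `transcript_model`.
#' @param pos Numeric vector of genomic positions (0-based). Positions must
#'   lie within the exon union, except that `pos == exon end` is accepted as
#'   the exclusive endpoint of that exon.
#' @return 0-based transcript coordinates (NA where unmappable).
#' @keywords internal
genomic_to_tx <- function(tx, pos) {
  ex <- tx$exons
  cum <- cumsum(c(0, ex$end - ex$start))
  out <- rep(NA_real_, length(pos))
  for (i in seq_len(nrow(ex))) {
    inside <- !is.na(pos) & pos >= ex$start[i] & pos <= ex$end[i]
    out[inside] <- cum[i] + pos[inside] - ex$start[i]
  }
  out
}
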