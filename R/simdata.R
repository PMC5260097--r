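#' Simulation configuration
#'
#' Describes a small artificial genome and a sequencing experiment on it:
#' multi-exon genes laid left to right on one chromosome, separated by an
#' explicit list of intergenic gaps that must include values on both sides
#' of the 50 bp bundle-merging threshold (so that bundle construction is
#' exercised in both regimes); isoforms built as exon-chain subsets of
#' their gene; fragments sampled uniformly along each isoform's mature
#' sequence with normally distributed lengths.
#'
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Length-2 range (min, max) of isoforms per gene.
#' @param exon_len,intron_len Length-2 bp ranges for exons and introns.
#' @param intergenic_gaps Explicit bp gaps between consecutive genes
#'   (recycled); must contain at least one value `<= 50` and one `> 50`.
#' @param abundances Optional per-isoform truth weights (relative FPKM
#'   scale). `NULL` draws them log-normally (meanlog 1, sdlog 1).
#' @param frag_len_mean,frag_len_sd Fragment length distribution (bp),
#'   truncated to `[read_len, isoform length]`.
#' @param read_len Read length (bp) of each mate.
#' @param n_fragments Total fragments to simulate.
#' @param seed Mandatory RNG seed; all outputs are deterministic given it.
#' @param frag_seed Seed for the fragment sampling only (defaults to
#'   `seed`). Two configs sharing `seed` but differing in `frag_seed`
#'   produce replicate samples: identical genome, annotation and truth
#'   abundances, independent sequencing noise.
#' @param chrom Chromosome name of the artificial genome.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5,
                       isoforms_per_gene = c(2, 4),
                       exon_len = c(150, 400),
                       intron_len = c(100, 500),
                       intergenic_gaps = c(10, 60, 200, 1000),
                       abundances = NULL,
                       frag_len_mean = 200, frag_len_sd = 50,
                       read_len = 75,
                       n_fragments = 5000,
                       seed,
                       frag_seed = NULL,
                       chrom = "chrS") {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_genes >= 1, all(isoforms_per_gene >= 1),
            all(exon_len > 0), all(intron_len > 0),
            all(intergenic_gaps > 0),
            frag_len_mean >= 1, frag_len_sd >= 0,
            read_len >= 1, n_fragments >= 0)
  if (!any(intergenic_gaps <= 50) || !any(intergenic_gaps > 50)) {
    stop("intergenic_gaps must include values both <= 50 and > 50 bp")
  }
  structure(list(n_genes = n_genes,
                 isoforms_per_gene = sort(isoforms_per_gene[1:2]),
                 exon_len = sort(exon_len[1:2]),
                 intron_len = sort(intron_len[1:2]),
                 intergenic_gaps = intergenic_gaps,
                 abundances = abundances,
                 frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
                 read_len = read_len, n_fragments = n_fragments,
                 seed = as.integer(seed),
                 frag_seed = if (is.null(frag_seed)) as.integer(seed)
                             else as.integer(frag_seed),
                 chrom = chrom),
            class = "sim_config")
}

# run expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# sample an integer uniformly in [lo, hi]
runif_int <- function(n, lo, hi) {
  as.integer(lo + floor(stats::runif(n) * (hi - lo + 1)))
}

# draw the gene/isoform layout for a config (annotation + gene spans)
sim_layout <- function(config) {
  genes <- list()
  txs <- list()
  pos <- 1000
  gap_i <- 0L
  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("G%03d", g)
    n_iso <- runif_int(1L, config$isoforms_per_gene[1L],
                       config$isoforms_per_gene[2L])
    n_exons <- if (n_iso > 1L) runif_int(1L, 3L, 6L) else runif_int(1L, 1L, 4L)
    ex_len <- runif_int(n_exons, config$exon_len[1L], config$exon_len[2L])
    in_len <- if (n_exons > 1L) {
      runif_int(n_exons - 1L, config$intron_len[1L], config$intron_len[2L])
    } else integer(0)
    starts <- pos + cumsum(c(0, ex_len[-n_exons] + in_len))
    ends <- starts + ex_len
    strand <- if (stats::runif(1L) < 0.5) "+" else "-"
    # isoforms: distinct exon subsets, first and last exon always kept
    subsets <- list(seq_len(n_exons))
    tries <- 0L
    while (length(subsets) < n_iso && tries < 50L) {
      tries <- tries + 1L
      keep <- c(1L,
                which(stats::runif(max(0L, n_exons - 2L)) < 0.6) + 1L,
                n_exons)
      keep <- sort(unique(keep))
      if (!any(vapply(subsets, identical, TRUE, keep))) {
        subsets <- c(subsets, list(keep))
      }
    }
    for (k in seq_along(subsets)) {
      tid <- sprintf("%s.T%d", gid, k)
      sel <- subsets[[k]]
      txs[[tid]] <- transcript_model(
        tid, gid, config$chrom, strand,
        data.frame(start = starts[sel], end = ends[sel]))
    }
    genes[[gid]] <- c(start = starts[1L], end = ends[n_exons])
    gap_i <- gap_i %% length(config$intergenic_gaps) + 1L
    pos <- ends[n_exons] + config$intergenic_gaps[gap_i]
  }
  list(ann = annotation(unname(txs)), genes = genes,
       genome_len = pos + 2000)
}

# project mature-transcript intervals [a, b) (0-based) onto genomic blocks
# and a CIGAR string; returns list(pos = 1-based leftmost, cigar, end =
# 0-based half-open genomic end)
project_mate <- function(tx, a, b) {
  ex <- tx$exons
  len <- ex$end - ex$start
  cum0 <- cumsum(c(0, len))                 # mature breakpoints
  n <- length(a)
  i1 <- findInterval(a, cum0, rightmost.closed = FALSE)
  i2 <- findInterval(b - 1, cum0, rightmost.closed = FALSE)
  gpos <- ex$start[i1] + (a - cum0[i1])     # 0-based genomic start
  pos <- as.integer(gpos + 1)
  cigar <- character(n)
  gend <- numeric(n)
  single <- i1 == i2
  if (any(single)) {
    m <- (b - a)[single]
    cigar[single] <- paste0(m, "M")
    gend[single] <- gpos[single] + m
  }
  for (i in which(!single)) {
    js <- i1[i]:i2[i]
    mlen <- pmin(b[i], cum0[js + 1L]) - pmax(a[i], cum0[js])
    gaps <- ex$start[js[-1L]] - ex$end[js[-length(js)]]
    cigar[i] <- paste0(
      paste0(mlen[-length(mlen)], "M", gaps, "N", collapse = ""),
      mlen[length(mlen)], "M")
    gend[i] <- ex$end[i2[i]] - (cum0[i2[i] + 1L] - b[i])
  }
  list(pos = pos, cigar = cigar, end = gend)
}

#' Simulate an annotated genome with sequenced fragments
#'
#' Generates a single-chromosome artificial genome honouring the
#' configured intergenic gaps, samples properly-paired fragments from the
#' isoforms at the configured abundances, and writes: the annotation
#' (`annotation.gtf`), the alignments (`reads.sam` plus a coordinate-sorted
#' indexed `reads.bam`), a per-transcript truth table (`truth.tsv`), a
#' per-fragment source table (`fragments.tsv`) and a JSON echo of the
#' configuration (`config.json`). Everything is deterministic given the
#' config seed.
#'
#' The expected fragment count of isoform *t* is proportional to
#' `abundance_t x effective_length_t` (realised counts are multinomial), so
#' the truth table's `true_fpkm` — recomputed from the realised counts —
#' is the exact value an ideal FPKM quantification would report.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return List with `ann` (the [annotation()]), `truth` (data.frame),
#'   `paths` (named file paths) and `config`.
#' @export
simulate_rnaseq <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  # genome layout and truth abundances are tied to `seed`; fragment
  # sampling to `frag_seed`, so replicates share truth but not noise
  drawn <- with_seed(config$seed, {
    lay <- sim_layout(config)
    ab <- config$abundances
    if (is.null(ab)) {
      ab <- stats::rlnorm(length(lay$ann$transcripts), meanlog = 1, sdlog = 1)
    }
    list(lay = lay, ab = ab)
  })
  lay <- drawn$lay
  ab <- drawn$ab
  ann <- lay$ann
  txs <- ann$transcripts
  ids <- names(txs)
  mat_len <- vapply(txs, tx_length, 0)
  if (any(mat_len < config$read_len)) {
    stop("config error: isoform(s) shorter than the read length: ",
         paste(ids[mat_len < config$read_len], collapse = ", "))
  }
  flm <- frag_len_model(config$frag_len_mean, config$frag_len_sd, "fixed")
  eff <- vapply(txs, effective_length, 0, flm = flm)
  if (length(ab) != length(ids)) {
    stop("config error: abundances must have one value per isoform (",
         length(ids), ")")
  }
  with_seed(config$frag_seed, {
    w <- ab * eff
    counts <- if (config$n_fragments > 0) {
      as.integer(stats::rmultinom(1L, config$n_fragments, prob = w / sum(w)))
    } else integer(length(ids))

    sam_fields <- vector("list", length(ids))
    frag_rows <- vector("list", length(ids))
    for (j in seq_along(ids)) {
      nct <- counts[j]
      if (nct == 0L) next
      tx <- txs[[j]]
      L <- mat_len[j]
      fl <- round(stats::rnorm(nct, config$frag_len_mean, config$frag_len_sd))
      fl <- pmin(pmax(fl, config$read_len), L)
      a <- runif_int(nct, 0L, L - fl)       # mature start, 0-based
      rl <- config$read_len
      m1 <- project_mate(tx, a, a + rl)
      m2 <- project_mate(tx, a + fl - rl, a + fl)
      qname <- sprintf("%s.f%05d", ids[j], seq_len(nct))
      tlen <- m2$end - (m1$pos - 1)
      sam_fields[[j]] <- data.table::data.table(
        qname = c(qname, qname),
        flag = rep(c(99L, 147L), each = nct),
        pos = c(m1$pos, m2$pos),
        cigar = c(m1$cigar, m2$cigar),
        pnext = c(m2$pos, m1$pos),
        tlen = c(tlen, -tlen))
      frag_rows[[j]] <- data.table::data.table(
        fragment_id = qname, transcript_id = ids[j],
        mature_start = a, frag_len = fl)
    }
    sam <- data.table::rbindlist(sam_fields)
    frag_truth <- data.table::rbindlist(frag_rows)

    paths <- list(
      gtf = file.path(outdir, "annotation.gtf"),
      sam = file.path(outdir, "reads.sam"),
      bam = file.path(outdir, "reads.bam"),
      truth = file.path(outdir, "truth.tsv"),
      fragments = file.path(outdir, "fragments.tsv"),
      config = file.path(outdir, "config.json"))
    write_gtf(ann, paths$gtf)

    seq_str <- strrep("A", config$read_len)
    qual_str <- strrep("I", config$read_len)
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                sprintf("@SQ\tSN:%s\tLN:%d", config$chrom,
                        as.integer(lay$genome_len)))
    body <- character(0)
    if (nrow(sam)) {
      data.table::setorder(sam, pos, qname, flag)
      body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s",
                      sam$qname, sam$flag, config$chrom, sam$pos, sam$cigar,
                      sam$pnext, sam$tlen, seq_str, qual_str)
    }
    con <- file(paths$sam, open = "wb")
    writeLines(c(header, body), con, sep = "\n")
    close(con)
    Rsamtools::asBam(paths$sam,
                     destination = sub("\\.bam$", "", paths$bam),
                     overwrite = TRUE, indexDestination = TRUE)

    total <- sum(counts)
    # expected bundle of each transcript under the 50 bp rule
    spans_s <- vapply(txs, function(t) t$exons$start[1L], 0)
    spans_e <- vapply(txs, function(t) t$exons$end[nrow(t$exons)], 0)
    bundle_id <- merge_group_ids(spans_s, spans_e, gap_threshold = 50)
    truth <- data.frame(
      transcript_id = ids,
      gene_id = vapply(txs, `[[`, "", "gene_id"),
      true_count = counts,
      mature_length = mat_len,
      effective_length = eff,
      true_fpkm = if (total > 0) {
        counts / ((eff / 1000) * (total / 1e6))
      } else rep(0, length(counts)),
      abundance_weight = ab,
      bundle_id = bundle_id,
      stringsAsFactors = FALSE, row.names = NULL)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(frag_truth, paths$fragments, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cfg <- unclass(config)
    cfg$abundances <- as.numeric(ab)
    jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    list(ann = ann, truth = truth, paths = paths, config = config)
  })
}

#' Hold-out protocol for validating local quantification
#'
#' Uniformly samples `k` transcripts without replacement, removes them from
#' the annotation and returns them as "novel" queries — the evaluation
#' design in which known transcripts are re-submitted as novel so that the
#' local estimate can be checked against the standard whole-file one.
#'
#' @param ann An [annotation()].
#' @param k Number of transcripts to hold out (`k < length(ann)`).
#' @param seed RNG seed for the selection.
#' @return List with `reduced` (annotation minus the selection) and
#'   `held_out` (list of the selected `transcript_model`s).
#' @export
holdout_protocol <- function(ann, k, seed) {
  stopifnot(inherits(ann, "annotation"))
  n <- length(ann$transcripts)
  if (k >= n) stop("k (", k, ") must be smaller than the number of transcripts (", n, ")")
  if (k == 0L) return(list(reduced = ann, held_out = list()))
  sel <- with_seed(seed, sample(names(ann$transcripts), k))
  list(
    reduced = annotation(unname(ann$transcripts[
      setdiff(names(ann$transcripts), sel)])),
    held_out = unname(ann$transcripts[sel])
  )
}
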