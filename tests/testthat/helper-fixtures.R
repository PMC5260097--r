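# Shared fixture builders. Everything is generated in code at test time;
# simulations are memoised per session so several test files can share one.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

make_tx <- function(id, starts, ends, gene = paste0("g_", id),
                    chrom = "chrT", strand = "+") {
  transcript_model(id, gene, chrom, strand,
                   data.frame(start = starts, end = ends))
}

# write a hand-built SAM (records: data.frame with qname, flag, pos, cigar,
# and optionally pnext, tlen) and convert to a sorted indexed BAM
sam_fixture <- function(records, chrom = "chrT", chrom_len = 1e6,
                        dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sam <- file.path(dir, "fix.sam")
  n <- nrow(records)
  if (is.null(records$pnext)) records$pnext <- rep(0L, n)
  if (is.null(records$tlen)) records$tlen <- rep(0L, n)
  if (is.null(records$rnext)) records$rnext <- ifelse(records$pnext > 0, "=", "*")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, as.integer(chrom_len)))
  body <- character(0)
  if (nrow(records)) {
    records <- records[order(records$pos), , drop = FALSE]
    body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t%d\t*\t*",
                    records$qname, records$flag, chrom, records$pos,
                    records$cigar, records$rnext, records$pnext,
                    records$tlen)
  }
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, destination = file.path(dir, "fix"),
                          overwrite = TRUE, indexDestination = TRUE)
  bam
}

# a single unpaired record covering [start, end) 0-based (simple M cigar)
span_record <- function(qname, start, end) {
  data.frame(qname = qname, flag = 0L, pos = as.integer(start + 1),
             cigar = sprintf("%dM", as.integer(end - start)),
             stringsAsFactors = FALSE)
}

# small three-gene simulation shared across test files
small_sim <- function() {
  cached("small_sim", {
    d <- file.path(tempdir(), "msbquant_small_sim")
    simulate_rnaseq(
      sim_config(n_genes = 3, isoforms_per_gene = c(2, 3),
                 n_fragments = 20000, seed = 5), d)
  })
}

# build a fragment_set by hand (blocks/introns per fragment, 0-based)
frag_set <- function(blocks, introns = NULL, chrom = "chrT",
                     paired = FALSE, ids = NULL) {
  n <- length(blocks)
  if (is.null(introns)) introns <- rep(list(NULL), n)
  if (is.null(ids)) ids <- sprintf("f%03d", seq_len(n))
  paired <- rep_len(paired, n)
  bl <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    b <- blocks[[i]]
    data.table::data.table(frag = i, start = b$start, end = b$end)
  }))
  itr <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    g <- introns[[i]]
    if (is.null(g)) return(NULL)
    data.table::data.table(frag = i, start = g$start, end = g$end)
  }))
  if (nrow(itr) == 0L) {
    itr <- data.table::data.table(frag = integer(0), start = numeric(0),
                                  end = numeric(0))
  }
  frags <- data.table::data.table(
    fragment_id = ids, chrom = chrom,
    span_start = bl[, min(start), by = frag]$V1,
    span_end = bl[, max(end), by = frag]$V1,
    paired = paired,
    bases = bl[, sum(end - start), by = frag]$V1)
  msbquant:::new_fragment_set(frags, bl, itr)
}
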