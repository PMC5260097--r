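#' Fragment-length model
#'
#' Effective-length computation needs the mean insert size. The model is
#' either estimated locally from uniquely-assignable paired fragments (the
#' mean and sd of their implied lengths on the mature transcript) or fixed.
#'
#' @param mean Mean fragment length in bp (>= 1).
#' @param sd Standard deviation in bp (>= 0).
#' @param source `"estimated"` or `"fixed"`.
#' @return An object of class `frag_len_model`.
#' @export
frag_len_model <- function(mean = 200, sd = 50, source = "fixed") {
  stopifnot(mean >= 1, sd >= 0, source %in% c("estimated", "fixed"))
  structure(list(mean = mean, sd = sd, source = source),
            class = "frag_len_model")
}

#' @export
print.frag_len_model <- function(x, ...) {
  cat(sprintf("<frag_len_model> mean %.1f bp, sd %.1f bp (%s)\n",
              x$mean, x$sd, x$source))
  invisible(x)
}

#' Effective transcript length
#'
#' The number of distinct fragment start positions:
#' `max(1, length - round(mean fragment length) + 1)`.
#'
#' @param tx A [transcript_model()] (or a numeric mature length).
#' @param flm A [frag_len_model()].
#' @return Effective length in bp (>= 1).
#' @examples
#' effective_length(1000, frag_len_model(200, 50)) # 801
#' effective_length(150, frag_len_model(200, 50))  # 1
#' @export
effective_length <- function(tx, flm) {
  len <- if (inherits(tx, "transcript_model")) tx_length(tx) else as.numeric(tx)
  stopifnot(len >= 1)
  max(1, len - round(flm$mean) + 1)
}

#' Fragment-transcript compatibility
#'
#' A fragment is compatible with a transcript iff every aligned block lies
#' within the transcript's exon union, every splice gap of the fragment
#' exactly equals one of the transcript's introns, and (for paired
#' fragments) both mate endpoints project onto the mature transcript so an
#' implied fragment length exists. Different chromosome is simply `FALSE`.
#'
#' @param fragment A single-fragment [fragment_set] (or any fragment_set;
#'   the first fragment is used).
#' @param tx A [transcript_model()].
#' @return Logical scalar.
#' @export
is_compatible <- function(fragment, tx) {
  stopifnot(inherits(fragment, "fragment_set"), n_fragments(fragment) >= 1L)
  compatibility_matrix(fragment, list(tx))[1L, 1L]
}

#' Compatibility matrix for a fragment set
#'
#' Vectorised form of [is_compatible()]: one row per fragment, one column
#' per transcript.
#'
#' @param fs A [fragment_set].
#' @param transcripts List of `transcript_model`s.
#' @return Logical matrix `n_fragments x n_transcripts` with fragment ids
#'   as row names and transcript ids as column names.
#' @export
compatibility_matrix <- function(fs, transcripts) {
  nf <- nrow(fs$fragments)
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  M <- matrix(FALSE, nrow = nf, ncol = length(transcripts),
              dimnames = list(fs$fragments$fragment_id, ids))
  if (nf == 0L || length(transcripts) == 0L) return(M)
  bl <- fs$blocks
  itr <- fs$introns
  for (j in seq_along(transcripts)) {
    t <- transcripts[[j]]
    ok <- fs$fragments$chrom == t$chrom
    if (!any(ok)) next
    # exon union (adjacent exons collapse for containment tests)
    u <- merge_intervals(t$exons$start, t$exons$end, gap_threshold = 0)
    idx <- findInterval(bl$start, u$start)
    safe <- pmax(idx, 1L)
    block_ok <- idx >= 1L & bl$end <= u$end[safe]
    bad_frag <- tabulate(bl$frag[!block_ok], nbins = nf) > 0L
    ti <- tx_introns(t)
    tkeys <- paste(ti$start, ti$end)
    if (nrow(itr)) {
      intron_ok <- paste(itr$start, itr$end) %in% tkeys
      bad_frag <- bad_frag | tabulate(itr$frag[!intron_ok], nbins = nf) > 0L
    }
    M[, j] <- ok & !bad_frag
  }
  M
}

#' Estimate the fragment-length model within a region
#'
#' Uses paired fragments whose implied mature-sequence length is
#' unambiguous: the fragment is compatible with at least one of the
#' supplied transcripts, and every compatible transcript implies the same
#' length. (Restricting instead to uniquely-assignable fragments would
#' over-represent junction-straddling inserts, which are longer than
#' average, and bias the mean upward.) The mean/sd of those lengths give
#' the model. Falls back to a fixed `frag_len_model(200, 50)` when fewer
#' than `min_fragments` usable fragments exist, which keeps single-end
#' data working.
#'
#' @param fs A [fragment_set].
#' @param transcripts List of `transcript_model`s.
#' @param compat Optional precomputed [compatibility_matrix()].
#' @param min_fragments Minimum usable paired fragments before estimation
#'   is trusted.
#' @return A [frag_len_model()].
#' @export
estimate_frag_len <- function(fs, transcripts, compat = NULL,
                              min_fragments = 20) {
  if (is.null(compat)) compat <- compatibility_matrix(fs, transcripts)
  cand <- which(rowSums(compat) > 0L & fs$fragments$paired)
  if (length(cand) < min_fragments) return(frag_len_model())
  IL <- matrix(NA_real_, nrow = length(cand), ncol = length(transcripts))
  for (j in seq_along(transcripts)) {
    rows <- which(compat[cand, j])
    if (!length(rows)) next
    t <- transcripts[[j]]
    a <- genomic_to_tx(t, fs$fragments$span_start[cand[rows]])
    b <- genomic_to_tx(t, fs$fragments$span_end[cand[rows]])
    IL[rows, j] <- b - a
  }
  lo <- apply(IL, 1L, min, na.rm = TRUE)
  hi <- apply(IL, 1L, max, na.rm = TRUE)
  lens <- lo[is.finite(lo) & lo == hi & lo >= 1]
  if (length(lens) < min_fragments) return(frag_len_model())
  frag_len_model(mean = mean(lens),
                 sd = if (length(lens) > 1L) stats::sd(lens) else 0,
                 source = "estimated")
}

#' EM abundance estimation over an isoform mixture
#'
#' Isoform-mixture EM in the style of standard RNA-Seq quantifiers:
#' conditional on originating from transcript *t*, a compatible paired
#' fragment has density proportional to
#' `p_len(implied_length_t(f)) / effective_length(t)`, where `p_len` is the
#' normal fragment-length density of `flm` and `implied_length_t(f)` is the
#' fragment's length on *t*'s mature sequence (which differs between
#' isoforms when the mates straddle a skipped exon — the signal that
#' resolves most isoform ambiguity). Unpaired fragments carry no insert
#' information and use `1 / effective_length(t)`; the density is floored at
#' `1e-12` so every compatible fragment stays assignable; with `flm$sd == 0`
#' the length term is dropped entirely. The mixture weight `theta_t` is the
#' fraction of fragments from *t*.
#'
#' Initialisation is uniform over transcripts with at least one compatible
#' fragment, so the procedure is fully deterministic and transcripts with
#' identical evidence split equally. The E-step assigns each fragment
#' fractionally proportional to `theta_t x weight_t(f)` among its
#' compatible transcripts; the M-step re-estimates `theta`. Fragments
#' compatible with no transcript are excluded from the likelihood.
#' Fragments are collapsed into equivalence classes by their weight
#' pattern, which leaves the fixed point unchanged.
#'
#' @param fs A [fragment_set].
#' @param transcripts Non-empty list of `transcript_model`s.
#' @param flm A [frag_len_model()].
#' @param max_iter,tol Stopping rule: stop when `max |delta theta| < tol`
#'   or after `max_iter` iterations.
#' @param compat Optional precomputed [compatibility_matrix()].
#' @return An object of class `em_fit`: `expected_fragments` (named numeric,
#'   `theta * n_assignable`), `theta`, `effective_lengths`, `n_assignable`,
#'   `loglik_trace` (one entry per iteration; non-decreasing) and
#'   `n_iter`.
#' @export
em_quantify <- function(fs, transcripts, flm = frag_len_model(),
                        max_iter = 5000, tol = 1e-10, compat = NULL) {
  stopifnot(length(transcripts) >= 1L)
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  eff <- vapply(transcripts, effective_length, 0, flm = flm)
  if (is.null(compat)) compat <- compatibility_matrix(fs, transcripts)
  assignable <- rowSums(compat) > 0L
  N <- sum(assignable)
  out <- function(theta, trace, iters) {
    structure(list(
      expected_fragments = stats::setNames(theta * N, ids),
      theta = stats::setNames(theta, ids),
      effective_lengths = stats::setNames(eff, ids),
      n_assignable = N, loglik_trace = trace, n_iter = iters),
      class = "em_fit")
  }
  if (N == 0L) return(out(rep(0, length(ids)), numeric(0), 0L))

  W <- assignment_weights(fs, transcripts, eff, flm, compat)
  Wa <- W[assignable, , drop = FALSE]

  # equivalence classes of identical weight rows
  pat <- do.call(paste, c(as.data.frame(Wa), list(sep = "\r")))
  first <- !duplicated(pat)
  C <- Wa[first, , drop = FALSE]            # classes x transcripts
  counts <- as.numeric(table(factor(pat, levels = pat[first])))

  active <- colSums((C > 0) * counts) > 0
  theta <- ifelse(active, 1 / sum(active), 0)
  trace <- numeric(0)
  iters <- 0L
  for (it in seq_len(max_iter)) {
    wk <- sweep(C, 2L, theta, `*`)
    denom <- rowSums(wk)
    trace <- c(trace, sum(counts * log(denom)))
    gamma <- wk / denom
    theta_new <- colSums(gamma * counts) / N
    iters <- it
    if (max(abs(theta_new - theta)) < tol) { theta <- theta_new; break }
    theta <- theta_new
  }
  out(theta, trace, iters)
}

# fragment x transcript assignment weights. For a compatible paired
# fragment with implied length l on transcript t of mature length L:
#   w = [dnorm(l; mean, sd) / Z_t] / max(L - l + 1, 1)
# where Z_t normalises the length density to the lengths observable on t
# (truncated normal) and L - l + 1 counts the start positions that could
# have produced the fragment. Unpaired fragments carry no insert
# information and use 1 / effective_length. Weights are floored so every
# compatible fragment stays assignable; with sd == 0 the length term is
# dropped.
assignment_weights <- function(fs, transcripts, eff, flm, compat) {
  W <- matrix(0, nrow = nrow(compat), ncol = ncol(compat),
              dimnames = dimnames(compat))
  use_len <- flm$sd > 0
  for (j in seq_along(transcripts)) {
    rows <- which(compat[, j])
    if (!length(rows)) next
    if (use_len) {
      t <- transcripts[[j]]
      L <- tx_length(t)
      a <- genomic_to_tx(t, fs$fragments$span_start[rows])
      b <- genomic_to_tx(t, fs$fragments$span_end[rows])
      l <- b - a
      z <- stats::pnorm(L, flm$mean, flm$sd) - stats::pnorm(0, flm$mean, flm$sd)
      p <- stats::dnorm(l, flm$mean, flm$sd) / max(z, 1e-12) /
        pmax(L - l + 1, 1)
      p[!fs$fragments$paired[rows]] <- 1 / eff[j]  # no insert information
      p[is.na(p)] <- 0
      W[rows, j] <- pmax(p, 1e-15)
    } else {
      W[rows, j] <- 1 / eff[j]
    }
  }
  W
}

#' @export
print.em_fit <- function(x, ...) {
  cat(sprintf("<em_fit> %d transcript(s), %g assignable fragment(s), %d iteration(s)\n",
              length(x$theta), x$n_assignable, x$n_iter))
  invisible(x)
}

# relative FPKM: expected fragments per kb of effective length per million
# LOCAL fragments
relative_fpkm <- function(expected, eff_len, local_total) {
  ifelse(eff_len > 0 & local_total > 0,
         expected / ((eff_len / 1000) * (local_total / 1e6)),
         0)
}

# shared by the local (MSB) and global per-bundle paths so that both are
# the same computation on the same inputs
quantify_bundle <- function(fs, transcripts, index, flm = NULL) {
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  o <- order(ids)
  transcripts <- transcripts[o]
  ids <- ids[o]
  local_total <- nrow(fs$fragments)
  local_bases <- sum(fs$fragments$bases)
  compat <- compatibility_matrix(fs, transcripts)
  if (is.null(flm)) flm <- estimate_frag_len(fs, transcripts, compat = compat)
  fit <- em_quantify(fs, transcripts, flm = flm, compat = compat)
  data.frame(
    transcript_id = ids,
    expected_fragments = as.numeric(fit$expected_fragments),
    effective_length = as.numeric(fit$effective_lengths),
    relative_fpkm = relative_fpkm(as.numeric(fit$expected_fragments),
                                  as.numeric(fit$effective_lengths),
                                  local_total),
    local_fragment_total = local_total,
    global_fragment_total = index$global_fragment_total,
    local_bases = local_bases,
    global_bases = index$global_bases,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Quantify a novel transcript within its MSB
#'
#' Fetches the fragments overlapping the MSB region, runs the EM estimator
#' over the novel transcript together with the MSB's reference transcripts,
#' and computes each transcript's relative FPKM with the within-MSB
#' fragment count as the depth denominator. The sample's global fragment
#' total is attached for the subsequent correction (see [correct_fpkm()]).
#'
#' @param msb An `msb_result` from [infer_msb()].
#' @param alignment_path The sample's BAM file (same one the index was
#'   built from).
#' @param index The sample's `bundle_index`.
#' @param flm Optional [frag_len_model()]; when `NULL` it is estimated from
#'   the MSB's uniquely-assignable paired fragments.
#' @return A `data.frame` of QuantRecords (novel + reference transcripts):
#'   `transcript_id`, `expected_fragments`, `effective_length`,
#'   `relative_fpkm`, `local_fragment_total`, `global_fragment_total`,
#'   `local_bases`, `global_bases`.
#' @export
quantify_in_msb <- function(msb, alignment_path, index, flm = NULL) {
  stopifnot(inherits(msb, "msb_result"), inherits(index, "bundle_index"))
  fs <- fetch_fragments(alignment_path, region = msb$region)
  novel_id <- msb$novel_transcript$transcript_id
  refs <- Filter(function(t) t$transcript_id != novel_id,
                 msb$reference_transcripts)
  transcripts <- c(list(msb$novel_transcript), refs)
  quantify_bundle(fs, transcripts, index, flm = flm)
}

#' Whole-file quantification (the standard, non-local path)
#'
#' Builds bundles over the entire file for the given annotation and runs
#' the same per-bundle estimator in every bundle. This is the conventional
#' whole-transcriptome quantification against which the MSB-local shortcut
#' is validated: for a transcript in the annotation, its corrected FPKM
#' here equals the one obtained from [quantify_in_msb()].
#'
#' @param alignment_path Coordinate-sorted, indexed BAM file.
#' @param ann An [annotation()].
#' @param gap_threshold Bundle gap threshold in bp.
#' @param flm Optional fixed [frag_len_model()]; when `NULL` each bundle
#'   estimates its own, exactly as the local path does.
#' @param fragments Optional prefetched whole-file [fragment_set] for the
#'   same file (avoids re-reading when quantifying repeatedly).
#' @return A `data.frame` of QuantRecords for every transcript, with a
#'   `corrected_fpkm` column appended.
#' @export
quantify_global <- function(alignment_path, ann, gap_threshold = 50,
                            flm = NULL, fragments = NULL) {
  fs <- if (is.null(fragments)) fetch_fragments(alignment_path) else fragments
  index <- build_bundle_index(alignment_path, ann,
                              gap_threshold = gap_threshold,
                              fragments = fs)
  b <- index$bundles
  res <- lapply(seq_len(nrow(b)), function(i) {
    txs <- ann$transcripts[b$members[[i]]]
    if (!length(txs)) return(NULL)
    sub <- subset_fragments(fs, genome_interval(b$chrom[i], b$start[i],
                                                b$end[i]))
    quantify_bundle(sub, unname(txs), index, flm = flm)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(res)
  res$corrected_fpkm <- vapply(seq_len(nrow(res)), function(i) {
    correct_fpkm(res[i, ])
  }, 0)
  rownames(res) <- NULL
  res
}

# restrict a fragment_set to fragments whose span overlaps region
subset_fragments <- function(fs, region) {
  keep <- which(fs$fragments$chrom == region$chrom &
                  fs$fragments$span_start < region$end &
                  fs$fragments$span_end > region$start)
  if (!length(keep)) return(empty_fragment_set())
  key <- integer(nrow(fs$fragments)); key[keep] <- seq_along(keep)
  frag <- NULL
  blocks <- fs$blocks[frag %in% keep][, list(frag = key[frag], start, end)]
  introns <- fs$introns[frag %in% keep][, list(frag = key[frag], start, end)]
  new_fragment_set(fs$fragments[keep], blocks, introns)
}
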