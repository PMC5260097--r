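flm0 <- frag_len_model(200, 0)   # sd 0: pure compatibility weights

test_that("fragment-transcript compatibility follows exon containment and junctions", {
  tx <- make_tx("T1", c(100, 300), c(200, 400))

  # block inside an exon
  f <- frag_set(list(data.frame(start = 100, end = 150)))
  expect_true(is_compatible(f, tx))
  # block dangling outside the exon union
  f <- frag_set(list(data.frame(start = 180, end = 220)))
  expect_false(is_compatible(f, tx))
  # spliced fragment matching the intron exactly
  f <- frag_set(list(data.frame(start = c(150, 300), end = c(200, 350))),
                introns = list(data.frame(start = 200, end = 300)))
  expect_true(is_compatible(f, tx))
  # intron mismatch ([200,310) vs transcript intron [200,300))
  f <- frag_set(list(data.frame(start = c(150, 310), end = c(200, 360))),
                introns = list(data.frame(start = 200, end = 310)))
  expect_false(is_compatible(f, tx))
  # different chromosome is FALSE, not an error
  f <- frag_set(list(data.frame(start = 100, end = 150)), chrom = "chrZ")
  expect_false(is_compatible(f, tx))
  # paired fragment whose inner gap spans the intron needs no junction match
  f <- frag_set(list(data.frame(start = c(120, 320), end = c(170, 370))),
                paired = TRUE)
  expect_true(is_compatible(f, tx))

  # simulated fragments are compatible with their source isoform, always
  sim <- small_sim()
  ann <- read_gtf(sim$paths$gtf)
  fs <- fetch_fragments(sim$paths$bam)
  M <- compatibility_matrix(fs, unname(ann$transcripts))
  src <- utils::read.delim(sim$paths$fragments)
  src_tx <- src$transcript_id[match(fs$fragments$fragment_id,
                                    src$fragment_id)]
  expect_true(all(M[cbind(seq_len(nrow(M)), match(src_tx, colnames(M)))]))

  # and cross-compatibility matches a per-pair brute-force checker
  idx <- sample(nrow(fs$fragments), 60)
  for (i in idx) {
    single <- msbquant:::subset_fragments(
      fs, genome_interval(fs$fragments$chrom[i],
                          fs$fragments$span_start[i],
                          fs$fragments$span_end[i]))
    one <- which(single$fragments$fragment_id == fs$fragments$fragment_id[i])
    for (t in ann$transcripts[sample(names(ann$transcripts), 3)]) {
      expect_equal(
        unname(compatibility_matrix(single, list(t))[one, 1]),
        unname(M[i, t$transcript_id]))
    }
  }
})

test_that("effective length is mature length minus mean fragment length plus one, floored", {
  flm <- frag_len_model(200, 50)
  expect_equal(effective_length(1000, flm), 801)
  expect_equal(effective_length(150, flm), 1)
  expect_equal(effective_length(200, flm), 1)
  tx <- make_tx("T1", c(0, 600), c(500, 1100))
  expect_equal(effective_length(tx, flm), 801)
})

test_that("EM reduces to counting when assignment is unambiguous", {
  tx <- make_tx("T1", 0, 2000)
  f <- frag_set(rep(list(data.frame(start = 10, end = 200)), 10))
  fit <- em_quantify(f, list(tx), flm0)
  expect_equal(unname(fit$expected_fragments), 10)

  # disjoint compatible sets of sizes 6 and 4 -> exactly 6 and 4
  t1 <- make_tx("A", 0, 1000)
  t2 <- make_tx("B", 2000, 3000)
  blocks <- c(rep(list(data.frame(start = 100, end = 200)), 6),
              rep(list(data.frame(start = 2100, end = 2200)), 4))
  f <- frag_set(blocks)
  fit <- em_quantify(f, list(t1, t2), flm0)
  expect_equal(unname(fit$expected_fragments[c("A", "B")]), c(6, 4))

  # zero assignable fragments -> all zero, no error
  f <- frag_set(list(data.frame(start = 5000, end = 5100)))
  fit <- em_quantify(f, list(t1, t2), flm0)
  expect_equal(unname(fit$expected_fragments), c(0, 0))
  expect_equal(fit$n_assignable, 0)
})

test_that("EM matches a dense grid-search MLE on shared-fragment mixtures", {
  grid_mle <- function(w1, w2) {
    th <- seq(1e-4, 1 - 1e-4, by = 1e-4)
    ll <- vapply(th, function(p) sum(log(p * w1 + (1 - p) * w2)), 0)
    th[which.max(ll)]
  }
  # equal effective lengths: unique 6 vs 4 plus 10 shared
  t1 <- make_tx("A", 0, 1200)
  t2 <- make_tx("B", 700, 1900)
  blocks <- c(rep(list(data.frame(start = 100, end = 200)), 6),      # A only
              rep(list(data.frame(start = 1500, end = 1600)), 4),    # B only
              rep(list(data.frame(start = 800, end = 900)), 10))     # shared
  f <- frag_set(blocks)
  fit <- em_quantify(f, list(t1, t2), flm0, tol = 1e-12)
  eff <- unname(fit$effective_lengths)
  w1 <- c(rep(1 / eff[1], 6), rep(0, 4), rep(1 / eff[1], 10))
  w2 <- c(rep(0, 6), rep(1 / eff[2], 4), rep(1 / eff[2], 10))
  expect_lt(abs(unname(fit$theta["A"]) - grid_mle(w1, w2)), 1e-3)

  # unequal effective lengths: the shared term is no longer flat
  t3 <- make_tx("C", 900, 3900)
  blocks <- c(rep(list(data.frame(start = 100, end = 200)), 6),      # A only
              rep(list(data.frame(start = 2500, end = 2600)), 7),    # C only
              rep(list(data.frame(start = 950, end = 1050)), 12))    # shared
  f <- frag_set(blocks)
  fit <- em_quantify(f, list(t1, t3), flm0, tol = 1e-12)
  eff <- unname(fit$effective_lengths)
  w1 <- c(rep(1 / eff[1], 6), rep(0, 7), rep(1 / eff[1], 12))
  w2 <- c(rep(0, 6), rep(1 / eff[2], 7), rep(1 / eff[2], 12))
  expect_lt(abs(unname(fit$theta["A"]) - grid_mle(w1, w2)), 1e-3)
})

test_that("EM conserves assignable fragments and its likelihood never decreases", {
  sim <- small_sim()
  ann <- read_gtf(sim$paths$gtf)
  idx <- build_bundle_index(sim$paths$bam, ann)
  fs <- fetch_fragments(sim$paths$bam)
  for (i in seq_len(nrow(idx$bundles))) {
    b <- idx$bundles[i, ]
    sub <- msbquant:::subset_fragments(
      fs, genome_interval(b$chrom, b$start, b$end))
    txs <- unname(ann$transcripts[b$members[[1]]])
    if (!length(txs)) next
    fit <- em_quantify(sub, txs)
    expect_equal(sum(fit$expected_fragments), fit$n_assignable,
                 tolerance = 1e-6)
    expect_true(all(diff(fit$loglik_trace) > -1e-9))
  }
})

test_that("identical evidence splits equally and duplication scales linearly", {
  # two transcripts with identical compatibility and lengths: equal split
  t1 <- make_tx("A", 0, 1000)
  t2 <- make_tx("B", 0, 1000, gene = "g2")
  f <- frag_set(rep(list(data.frame(start = 100, end = 200)), 8))
  fit <- em_quantify(f, list(t1, t2), flm0)
  expect_equal(unname(fit$expected_fragments), c(4, 4))

  # duplicating every fragment doubles expected counts; relative FPKM is
  # unchanged when the local total doubles with them
  sim <- small_sim()
  ann <- read_gtf(sim$paths$gtf)
  idx <- build_bundle_index(sim$paths$bam, ann)
  b <- idx$bundles[1, ]
  fs <- fetch_fragments(sim$paths$bam, genome_interval(b$chrom, b$start, b$end))
  txs <- unname(ann$transcripts[b$members[[1]]])
  fit1 <- em_quantify(fs, txs)
  dup <- fs
  dup$fragments <- data.table::copy(fs$fragments)[
    , fragment_id := paste0(fragment_id, "_x")]
  both <- msbquant:::new_fragment_set(
    rbind(fs$fragments, dup$fragments),
    rbind(fs$blocks, data.table::copy(fs$blocks)[
      , frag := frag + nrow(fs$fragments)]),
    rbind(fs$introns, data.table::copy(fs$introns)[
      , frag := frag + nrow(fs$fragments)]))
  fit2 <- em_quantify(both, txs)
  expect_equal(unname(fit2$expected_fragments),
               2 * unname(fit1$expected_fragments), tolerance = 1e-6)
  r1 <- msbquant:::relative_fpkm(unname(fit1$expected_fragments),
                                 unname(fit1$effective_lengths),
                                 n_fragments(fs))
  r2 <- msbquant:::relative_fpkm(unname(fit2$expected_fragments),
                                 unname(fit2$effective_lengths),
                                 2 * n_fragments(fs))
  expect_equal(r2, r1, tolerance = 1e-6)
})

test_that("relative FPKM follows its closed form and degenerates to zero", {
  # 10 fragments, 1 kb effective length, local total 1000 -> 10,000
  expect_equal(msbquant:::relative_fpkm(10, 1000, 1000), 10000)
  expect_equal(msbquant:::relative_fpkm(10, 1000, 0), 0)
  expect_equal(msbquant:::relative_fpkm(0, 1000, 1000), 0)
})

test_that("quantifying inside an MSB yields records for novel plus references", {
  sim <- small_sim()
  ann <- read_gtf(sim$paths$gtf)
  ho <- holdout_protocol(ann, 2, seed = 9)
  idx <- build_bundle_index(sim$paths$bam, ho$reduced)
  novel <- ho$held_out[[1]]
  msb <- infer_msb(novel, idx, ho$reduced)
  rec <- quantify_in_msb(msb, sim$paths$bam, idx)
  expect_setequal(
    rec$transcript_id,
    c(novel$transcript_id,
      vapply(msb$reference_transcripts, `[[`, "", "transcript_id")))
  expect_true(all(rec$relative_fpkm >= 0))
  expect_equal(unique(rec$global_fragment_total), idx$global_fragment_total)

  # a novel transcript in an empty region quantifies to zero
  far <- make_tx("N0", 900000, 901000, chrom = sim$config$chrom)
  msb <- infer_msb(far, idx, ho$reduced)
  rec <- quantify_in_msb(msb, sim$paths$bam, idx)
  expect_equal(rec$relative_fpkm, 0)
  expect_equal(rec$local_fragment_total, 0L)
})

test_that("fragment-length estimation recovers the simulated insert size", {
  sim <- small_sim()
  ann <- read_gtf(sim$paths$gtf)
  idx <- build_bundle_index(sim$paths$bam, ann)
  b <- idx$bundles[which.max(idx$bundles$local_fragment_total), ]
  fs <- fetch_fragments(sim$paths$bam, genome_interval(b$chrom, b$start, b$end))
  txs <- unname(ann$transcripts[b$members[[1]]])
  flm <- estimate_frag_len(fs, txs)
  expect_equal(flm$source, "estimated")
  expect_lt(abs(flm$mean - 200), 15)
  expect_lt(abs(flm$sd - 50), 20)

  # too few usable paired fragments -> fixed fallback
  few <- msbquant:::new_fragment_set(fs$fragments[1:10],
                                     fs$blocks[frag <= 10],
                                     fs$introns[frag <= 10])
  flm <- estimate_frag_len(few, txs)
  expect_equal(flm$source, "fixed")
  expect_equal(flm$mean, 200)
})

test_that("local MSB quantification equals the whole-file run", {
  sim <- small_sim()
  ann <- read_gtf(sim$paths$gtf)
  ho <- holdout_protocol(ann, 3, seed = 13)
  fs_all <- fetch_fragments(sim$paths$bam)
  idx <- build_bundle_index(sim$paths$bam, ho$reduced, fragments = fs_all)
  for (novel in ho$held_out) {
    msb <- infer_msb(novel, idx, ho$reduced)
    rec <- quantify_in_msb(msb, sim$paths$bam, idx)
    loc <- rec[rec$transcript_id == novel$transcript_id, ]
    gann <- annotation(c(unname(ho$reduced$transcripts), list(novel)))
    g <- quantify_global(sim$paths$bam, gann, fragments = fs_all)
    glo <- g[g$transcript_id == novel$transcript_id, ]
    expect_equal(correct_fpkm(loc), glo$corrected_fpkm,
                 tolerance = 1e-6)
    expect_equal(loc$expected_fragments, glo$expected_fragments,
                 tolerance = 1e-6)
  }
})
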