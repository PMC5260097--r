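#' Corrected FPKM
#'
#' Rescales a within-MSB relative FPKM to the value a whole-transcriptome
#' quantification would report:
#'
#' \deqn{Corrected\ FPKM = \frac{Relative\ FPKM \times Local\ total}
#'                              {Global\ total}}
#'
#' where the totals are the within-MSB and whole-sample sequencing depth.
#' The depth is counted in fragments by default; `mode = "bases"` uses
#' summed aligned base totals instead (the two differ only by the ratio of
#' local to global mean fragment length).
#'
#' @param record One QuantRecord row (from [quantify_in_msb()]).
#' @param mode `"count"` (fragment counts, default) or `"bases"`.
#' @return Corrected FPKM (numeric scalar); 0 when the local total is 0.
#' @examples
#' r <- data.frame(relative_fpkm = 10000, local_fragment_total = 1000,
#'                 global_fragment_total = 1e6,
#'                 local_bases = 2e5, global_bases = 2e8)
#' correct_fpkm(r) # 10
#' @export
correct_fpkm <- function(record, mode = c("count", "bases")) {
  mode <- match.arg(mode)
  local <- if (mode == "count") record$local_fragment_total else record$local_bases
  global <- if (mode == "count") record$global_fragment_total else record$global_bases
  if (is.null(global) || is.na(global) || global <= 0) {
    stop("undefined sequencing depth: global total is 0")
  }
  if (local <= 0) return(0)
  as.numeric(record$relative_fpkm) * local / global
}

#' Expression matrix of corrected FPKM
#'
#' @param values Numeric matrix, transcripts x samples, of corrected FPKM
#'   (non-negative) with dimnames.
#' @param replicate_groups Named character vector mapping each sample id to
#'   its cell-type / condition label; defaults to every sample in its own
#'   group.
#' @param size_factors Per-sample positive size factors (default 1).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values,
                              replicate_groups = NULL,
                              size_factors = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry transcript (row) and sample (column) names")
  }
  if (any(values < 0)) stop("corrected FPKM must be non-negative")
  samples <- colnames(values)
  if (is.null(replicate_groups)) {
    replicate_groups <- stats::setNames(samples, samples)
  }
  if (!all(samples %in% names(replicate_groups))) {
    stop("replicate_groups must cover all samples")
  }
  replicate_groups <- replicate_groups[samples]
  if (is.null(size_factors)) {
    size_factors <- stats::setNames(rep(1, length(samples)), samples)
  }
  if (any(size_factors <= 0)) stop("size factors must be positive")
  structure(list(values = values,
                 size_factors = size_factors,
                 replicate_groups = replicate_groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d transcript(s) x %d sample(s), %d group(s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$replicate_groups))))
  invisible(x)
}

#' Geometric (median-of-ratios) normalisation across samples
#'
#' Computes per-sample size factors from reference-transcript corrected
#' FPKMs: for each reference transcript that is nonzero in all samples, the
#' geometric mean across samples is taken; a sample's raw factor is the
#' median over those transcripts of (sample value / geometric mean).
#' Factors are rescaled to unit geometric mean (so their product is 1) and
#' each sample's column is divided by its factor.
#'
#' @param em An [expression_matrix()].
#' @param reference_values Matrix of reference-transcript corrected FPKM
#'   (reference transcripts x samples, same sample order); defaults to
#'   `em$values` itself. Size factors should normally be driven by
#'   reference (known) transcripts, not by the novel ones under study.
#' @return A new `expression_matrix` with normalised values and the size
#'   factors recorded. With a single sample, or when no reference
#'   transcript is nonzero in every sample, all factors are 1 (with a
#'   warning in the latter case).
#' @export
geometric_normalize <- function(em, reference_values = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  v <- em$values
  ns <- ncol(v)
  ref <- if (is.null(reference_values)) v else as.matrix(reference_values)
  if (ncol(ref) != ns) stop("reference_values must have one column per sample")
  factors <- rep(1, ns)
  if (ns > 1L) {
    usable <- rowSums(ref > 0) == ns
    if (!any(usable)) {
      warning("no reference transcript is nonzero in all samples; ",
              "size factors default to 1")
    } else {
      u <- ref[usable, , drop = FALSE]
      geo <- exp(rowMeans(log(u)))           # per-transcript geometric means
      raw <- apply(u / geo, 2L, stats::median)
      factors <- raw / exp(mean(log(raw)))   # unit geometric mean
    }
  }
  names(factors) <- colnames(v)
  expression_matrix(sweep(v, 2L, factors, `/`),
                    replicate_groups = em$replicate_groups,
                    size_factors = factors)
}

#' Average replicates per cell type
#'
#' Collapses samples of the same replicate group into one column by
#' arithmetic mean. Intended to be applied after [geometric_normalize()]
#' (averaging unnormalised replicates would defeat the size factors).
#'
#' @param em An [expression_matrix()] whose `replicate_groups` covers all
#'   samples.
#' @return An `expression_matrix` with one column per group (in order of
#'   first appearance), unit size factors and singleton groups.
#' @export
average_replicates <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  groups <- em$replicate_groups
  labels <- unique(unname(groups))
  out <- vapply(labels, function(g) {
    rowMeans(em$values[, names(groups)[groups == g], drop = FALSE])
  }, numeric(nrow(em$values)))
  out <- matrix(out, nrow = nrow(em$values),
                dimnames = list(rownames(em$values), labels))
  expression_matrix(out,
                    replicate_groups = stats::setNames(labels, labels),
                    size_factors = stats::setNames(rep(1, length(labels)),
                                                   labels))
}

#' Write an expression matrix (and its size factors) as TSV
#'
#' Values are printed with 4 decimal places; a companion
#' `<path>.size_factors.tsv` records the per-sample factors.
#'
#' @param em An [expression_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path) {
  v <- em$values
  lines <- c(
    paste(c("transcript_id", colnames(v)), collapse = "\t"),
    vapply(seq_len(nrow(v)), function(i) {
      paste(c(rownames(v)[i], sprintf("%.4f", v[i, ])), collapse = "\t")
    }, "")
  )
  con <- file(path, open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  sf_path <- paste0(path, ".size_factors.tsv")
  con <- file(sf_path, open = "wb")
  writeLines(c("sample_id\tsize_factor",
               sprintf("%s\t%.6f", names(em$size_factors),
                       em$size_factors)), con, sep = "\n")
  close(con)
  invisible(path)
}
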