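#' Relative quantification of RT-qPCR miRNA levels
#'
#' Relative quantity of a target miRNA against the miR-486-5p internal
#' standard: `RQ = N0[target] / N0[reference]`, with N0 the initial
#' concentration per sample in arbitrary fluorescence units (as exported
#' by amplification-curve software). Vectorized over samples.
#'
#' @param n0_target nonnegative N0 values of the target miRNA.
#' @param n0_reference strictly positive N0 values of the reference miRNA.
#' @return numeric RQ values (dimensionless). Zero targets yield RQ = 0,
#'   which [log_transform()] rejects as non-loggable.
#' @export
relative_quantity <- function(n0_target, n0_reference) {
  if (any(!is.finite(n0_reference) | n0_reference <= 0)) {
    stop("normalization error: reference N0 must be strictly positive",
         call. = FALSE)
  }
  if (any(!is.finite(n0_target) | n0_target < 0)) {
    stop("input error: target N0 must be nonnegative", call. = FALSE)
  }
  n0_target / n0_reference
}

#' Natural-log transform of relative expression levels
#'
#' @param rq_values strictly positive relative quantities.
#' @return elementwise natural logarithm.
#' @export
log_transform <- function(rq_values) {
  bad <- which(!is.finite(rq_values) | rq_values <= 0)
  if (length(bad) > 0) {
    stop("non-loggable (nonpositive) values at position(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  log(rq_values)
}

#' Screen transcripts for differential expression between two groups
#'
#' Applies the discovery criteria used for candidate miRNA selection:
#' fold change of at least `fc_threshold` between group means (ratio of
#' larger to smaller mean, with the direction recorded) and a two-sided
#' Wilcoxon rank-sum p-value below `p_threshold`. No multiplicity
#' correction is applied at screening. Fold change is computed on
#' linear-scale values by default; `fc_scale = "log"` exponentiates the
#' difference of log-scale group means instead.
#'
#' @param matrix numeric samples x transcripts matrix, nonnegative.
#' @param group length-`nrow(matrix)` binary labels (case/control; any two
#'   levels).
#' @param fc_threshold minimum fold change (default 1.25).
#' @param p_threshold significance cutoff (default 0.1, strict `<`).
#' @param detected optional logical matrix of the same shape flagging
#'   detected cells; detection fractions default to 1 when absent.
#' @param fc_scale `"linear"` (ratio of arithmetic group means) or
#'   `"log"` (input already log-scale; FC = exp of mean difference).
#' @return data.frame, one row per transcript: `transcript`,
#'   `fold_change` (>= 1), `direction` (`"up"` = higher in the first group
#'   level, `"down"` otherwise), `p_value`, `detection_fraction`, `passes`.
#' @export
screen_candidates <- function(matrix, group, fc_threshold = 1.25,
                              p_threshold = 0.1, detected = NULL,
                              fc_scale = c("linear", "log")) {
  fc_scale <- match.arg(fc_scale)
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- paste0("t", seq_len(ncol(matrix)))
  }
  if (anyDuplicated(colnames(matrix))) {
    stop("transcript names must be unique", call. = FALSE)
  }
  glev <- unique(group)
  if (length(glev) != 2) stop("exactly two groups required", call. = FALSE)
  ia <- which(group == glev[1]); ib <- which(group == glev[2])
  if (length(ia) < 2 || length(ib) < 2) {
    stop("each group needs >= 2 samples", call. = FALSE)
  }
  res <- lapply(colnames(matrix), function(tr) {
    xa <- matrix[ia, tr]; xb <- matrix[ib, tr]
    ma <- mean(xa); mb <- mean(xb)
    fc <- if (fc_scale == "log") exp(abs(ma - mb)) else
      max(ma, mb) / min(ma, mb)
    p <- wilcoxon_rank_sum(xa, xb)
    det <- if (is.null(detected)) 1 else mean(detected[, tr])
    data.frame(transcript = tr, fold_change = fc,
               direction = if (ma >= mb) "up" else "down",
               p_value = p, detection_fraction = det,
               passes = (fc >= fc_threshold) && (p < p_threshold))
  })
  do.call(rbind, res)
}

#' Retain transcripts detected in a minimum fraction of samples
#'
#' @param detected logical samples x transcripts matrix (or a named numeric
#'   vector of detection fractions).
#' @param min_fraction retention threshold; `>=` comparison ("at least").
#' @return character vector of retained transcript names.
#' @export
detection_filter <- function(detected, min_fraction = 0.8) {
  frac <- if (is.matrix(detected)) colMeans(detected) else detected
  if (is.null(names(frac))) names(frac) <- paste0("t", seq_along(frac))
  names(frac)[frac >= min_fraction]
}

#' Split subjects at the sample median of a marker
#'
#' Subjects with value less than or equal to the median (standard sample
#' median, type-7 quantile) are labeled `"low"`; ties at the median all go
#' low.
#'
#' @param values numeric vector, >= 2 finite values, not all identical.
#' @return factor with levels `low`, `high` and the median as attribute
#'   `"median"`.
#' @export
median_split <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2) stop("need >= 2 finite values", call. = FALSE)
  if (length(unique(v)) == 1) {
    stop("degenerate split: all values identical", call. = FALSE)
  }
  m <- stats::median(v)
  out <- factor(ifelse(values <= m, "low", "high"), levels = c("low", "high"))
  attr(out, "median") <- m
  out
}
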