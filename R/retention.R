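# Retention curves: how many probe-pairs and probe-sets survive each
# candidate intensity cut-off.  A probe-pair is retained at cut-off x when
# its PM intensity is strictly greater than x; a probe-set is retained while
# it keeps at least one retained pair.

#' Retention curve container
#'
#' @param thresholds Ascending numeric vector of candidate cut-offs.
#' @param retained_pairs,retained_sets Non-negative integer counts at each
#'   threshold; both must be non-increasing, with pairs >= sets everywhere.
#' @return An object of class `retention_curve` (a data.frame).
#' @export
retention_curve <- function(thresholds, retained_pairs, retained_sets) {
  stopifnot(length(thresholds) == length(retained_pairs),
            length(thresholds) == length(retained_sets),
            !is.unsorted(thresholds))
  if (any(diff(retained_pairs) > 0) || any(diff(retained_sets) > 0))
    stop("retention counts must be non-increasing in the threshold")
  if (any(retained_pairs < retained_sets))
    stop("retained pairs cannot be fewer than retained sets")
  structure(data.frame(threshold = thresholds,
                       retained_pairs = retained_pairs,
                       retained_sets = retained_sets),
            class = c("retention_curve", "data.frame"))
}

#' Pseudo minimum array across chips
#'
#' Elementwise minimum over the chips of a probe matrix.  Used to mask
#' multiple gDNA hybridisations at once: a probe survives a cut-off only if
#' it exceeds it on every chip, which is equivalent to thresholding this
#' single pseudo array.
#'
#' @param pm A [probe_matrix()] (or plain matrix) with >= 1 chip.
#' @return Named numeric vector, one value per probe.
#' @export
pseudo_min_array <- function(pm) {
  if (!ncol(pm)) stop("probe matrix has no chips")
  out <- do.call(pmin, lapply(seq_len(ncol(pm)), function(j) unclass(pm)[, j]))
  names(out) <- rownames(pm)
  out
}

#' Compute the retention curve of a signal vector
#'
#' For every threshold `x` counts the probe-pairs with signal strictly above
#' `x` and the probe-sets with at least one such pair.  The default grid is
#' 0..1000 in steps of 1.
#'
#' @param signal Numeric vector of PM intensities in the canonical probe
#'   order of `layout` (e.g. a chip column or [pseudo_min_array()] output).
#' @param layout A [chip_layout()]; only the probe-set sizes are used.  May
#'   also be a character vector of per-probe set ids.
#' @param thresholds Ascending numeric grid of cut-offs.
#' @return A [retention_curve()].
#' @export
compute_retention <- function(signal, layout, thresholds = 0:1000) {
  sid <- if (inherits(layout, "chip_layout")) {
    rep(names(layout$probe_sets),
        vapply(layout$probe_sets, nrow, integer(1)))
  } else as.character(layout)
  if (length(signal) != length(sid))
    stop(sprintf("signal has %d values but layout has %d PM probes",
                 length(signal), length(sid)))
  thresholds <- sort(thresholds)
  # pairs retained at x: #{signal > x}; counted by sorting once
  s_sorted <- sort(signal)
  n <- length(signal)
  pairs <- n - findInterval(thresholds, s_sorted)
  # a set dies when x reaches its maximum signal
  set_max <- tapply(signal, sid, max)
  m_sorted <- sort(as.numeric(set_max))
  sets <- length(set_max) - findInterval(thresholds, m_sorted)
  retention_curve(thresholds, as.integer(pairs), as.integer(sets))
}

#' Per-pair retention flags at a single cut-off
#'
#' @inheritParams compute_retention
#' @param x Cut-off; a pair is retained iff its signal is strictly greater.
#' @return Logical vector aligned to the canonical pair order, suitable for
#'   [write_masked_cdf()].
#' @export
retention_to_flags <- function(signal, layout, x) {
  np <- if (inherits(layout, "chip_layout")) n_pairs(layout)
        else length(layout)
  if (length(signal) != np)
    stop(sprintf("signal has %d values but layout has %d PM probes",
                 length(signal), np))
  as.vector(signal > x)
}

#' Write a retention curve as TSV
#' @param curve A [retention_curve()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_retention_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a retention curve from TSV
#' @param path TSV with columns `threshold`, `retained_pairs`,
#'   `retained_sets`.
#' @return A [retention_curve()].
#' @export
read_retention_curve <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  retention_curve(df$threshold, df$retained_pairs, df$retained_sets)
}
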