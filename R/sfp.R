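# Single-feature polymorphism screening on the four-chip single-trait
# design: chips B1 (parent 1), B2 (parent 2), B3 (bulk paired with B1),
# B4 (bulk paired with B2).  Group G1 = parents (B1 vs B2), group G2 = F2
# bulks (B3 vs B4); the trait pairing is B1~B3 versus B2~B4.

# ---------------------------------------------------------------------------
# Elementary statistics
# ---------------------------------------------------------------------------

#' Symmetric fold-change of an intensity ratio
#'
#' Maps a positive ratio `q` onto a symmetric scale: `q` when `q >= 1`,
#' `-1/q` otherwise, so two-fold changes in either direction are
#' equidistant from 1 / -1.
#'
#' @param q Positive intensity ratio(s).
#' @return Signed fold-change(s); `|fc| >= 1` always.
#' @export
symmetric_fc <- function(q) {
  if (any(!is.finite(q)) || any(q <= 0)) stop("ratio must be positive")
  ifelse(q >= 1, q, -1 / q)
}

#' MA-value: average within-group log2 ratio
#'
#' `rho = (log2(b1/b2) + log2(b3/b4)) / 2` — the average, over the parent
#' group and the bulk group, of the binary-log intensity ratio taken in the
#' trait orientation (B1~B3 over B2~B4).
#'
#' @param b1,b2,b3,b4 Positive intensities of one probe on the four chips.
#' @return MA-value(s).
#' @export
ma_value <- function(b1, b2, b3, b4) {
  if (any(c(b1, b2, b3, b4) <= 0)) stop("intensities must be positive")
  (log2(b1 / b2) + log2(b3 / b4)) / 2
}

#' D-value: average within-group intensity difference
#'
#' `delta = ((b1 - b2) + (b3 - b4)) / 2`, the difference analogue of the
#' MA-value, more selective against low-intensity probes.
#'
#' @inheritParams ma_value
#' @return D-value(s).
#' @export
d_value <- function(b1, b2, b3, b4) {
  ((b1 - b2) + (b3 - b4)) / 2
}

#' Fold-change difference: signed square root of a D-value
#'
#' `FCD = sign(delta) * sqrt(|delta|)`; symmetric about zero so changes in
#' both directions plot equidistant from the centre.
#'
#' @param delta D-value(s).
#' @return FCD value(s).
#' @export
fcd <- function(delta) sign(delta) * sqrt(abs(delta))

#' Gamma-trimmed mean
#'
#' Drops the `h = floor(gamma * n)` smallest and largest order statistics
#' and averages the remainder.
#'
#' @param x Numeric vector.
#' @param gamma Trimming proportion in \[0, 0.5).
#' @return Trimmed mean.
#' @export
trimmed_mean <- function(x, gamma = 0.1) {
  if (gamma < 0 || gamma >= 0.5) stop("gamma must be in [0, 0.5)")
  n <- length(x)
  h <- floor(gamma * n)
  if (2L * h >= n) stop("trim removes every observation")
  s <- sort(x)
  mean(s[seq.int(h + 1L, n - h)])
}

#' Gamma-Winsorized variance
#'
#' Replaces the `h = floor(gamma * n)` extreme order statistics on each side
#' by the nearest retained order statistic and returns the sample variance
#' (n - 1 denominator) of the Winsorized sample.
#'
#' @inheritParams trimmed_mean
#' @return Winsorized variance (>= 0).
#' @export
winsorized_variance <- function(x, gamma = 0.1) {
  if (gamma < 0 || gamma >= 0.5) stop("gamma must be in [0, 0.5)")
  n <- length(x)
  h <- floor(gamma * n)
  if (2L * h >= n) stop("winsorization removes every observation")
  s <- sort(x)
  if (h > 0L) {
    s[seq_len(h)] <- s[h + 1L]
    s[seq.int(n - h + 1L, n)] <- s[n - h]
  }
  stats::var(s)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-value of the j-th smallest p is
#' `min_{r >= j} (m * p_(r) / r)`, capped at 1; `NA`s propagate.
#'
#' @param p Vector of raw p-values.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (!m) return(out)
  o <- ok[order(p[ok])]
  adj <- rev(cummin(rev(m * p[o] / seq_len(m))))
  out[o] <- pmin(adj, 1)
  out
}

#' Patel small-sample scale factor for the trimmed t statistic
#'
#' `a(n, h) = 1 + 16 * sqrt(h) * exp(2h - n)`, applied when `n < 18`.
#'
#' @param n Sample size.
#' @param h Per-side trim count.
#' @return Scale factor (>= 1).
#' @export
patel_scale <- function(n, h) 1 + 16 * sqrt(h) * exp(2 * h - n)

# ---------------------------------------------------------------------------
# Design container
# ---------------------------------------------------------------------------

#' Assemble a four-chip single-trait design
#'
#' @param pm A [probe_matrix()] with exactly 4 chips ordered B1 (parent 1),
#'   B2 (parent 2), B3 (bulk paired with B1), B4 (bulk paired with B2).
#'   Intensities must be strictly positive (ratios must be defined).
#' @return The matrix, validated, with class `quad_design` prepended.
#' @export
quad_design <- function(pm) {
  if (ncol(pm) != 4L)
    stop(sprintf("a single-trait design needs exactly 4 chips, got %d",
                 ncol(pm)))
  if (any(unclass(pm) <= 0))
    stop("all intensities must be > 0 (preprocess first)")
  class(pm) <- unique(c("quad_design", class(pm)))
  pm
}

# ---------------------------------------------------------------------------
# DFC
# ---------------------------------------------------------------------------

#' Dual fold-change screen
#'
#' A probe is flagged when (i) all four chip intensities exceed the gDNA
#' hybridisation threshold `th`, and (ii) the parental fold-change and the
#' bulk fold-change both exceed their cut-offs in the same direction
#' (`|fc1| >= eps1`, `|fc2| >= eps2`, `sign(fc1) == sign(fc2)`) — the bulk
#' group acting as a cross-check on the parental polymorphism.
#'
#' @param design A [quad_design()] (or 4-column matrix of positive values).
#' @param th gDNA hybridisation intensity threshold (e.g. the ATM cut-off).
#' @param eps1 Parental fold-change cut-off (FCP).
#' @param eps2 Bulk fold-change cut-off (FCF2).
#' @return Logical vector of DFC flags, one per probe.
#' @export
dfc_screen <- function(design, th, eps1 = 2, eps2 = 1.5) {
  b <- unclass(design)
  fc1 <- symmetric_fc(b[, 1] / b[, 2])
  fc2 <- symmetric_fc(b[, 3] / b[, 4])
  above <- rowSums(b > th) == 4L
  above & abs(fc1) >= eps1 & abs(fc2) >= eps2 & sign(fc1) == sign(fc2)
}

# ---------------------------------------------------------------------------
# POST
# ---------------------------------------------------------------------------

#' Probe-wise one-sample test between groups (MA-values)
#'
#' For each probe k of probe-set i, compares its MA-value with the mean and
#' standard deviation of the other `n_i = #(B_i) - 1` MA-values of the set:
#' \deqn{T_{ik} = (\rho_{ik} - \bar\rho_{ik}) / (S_{ik} \sqrt{1 + 1/n_i})}
#' referred to a t distribution with `n_i - 1` degrees of freedom
#' (two-sided).  The `sqrt(1 + 1/n)` prediction factor reflects that probe
#' k is excluded from the sample it is compared against.
#'
#' Probes in sets smaller than 3 are skipped (`NA` statistics).  Degenerate
#' sets with zero spread give p = 1 when the probe matches the rest and the
#' smallest representable p when it does not.
#'
#' @param design A [quad_design()].
#' @return data.frame with columns `t`, `df`, `p` (one row per probe).
#' @export
post_between <- function(design) {
  b <- unclass(design)
  rho <- ma_value(b[, 1], b[, 2], b[, 3], b[, 4])
  post_loo(rho, set_ids(design))
}

#' Probe-wise trimmed one-sample test within a group (D-values)
#'
#' For each probe k of probe-set i, compares its within-group intensity
#' difference (`b1 - b2` for G1, `b3 - b4` for G2) against the
#' gamma-trimmed mean of the other `n_i` differences, studentized by the
#' Winsorized standard deviation:
#' \deqn{t_{ik} = (\delta_{ik} - \bar\delta_{ik}) /
#'   (s_{ik} / ((1 - 2h/n_i)\sqrt{n_i}))}
#' with `n_i - 2h - 1` degrees of freedom (Tukey-McLaughlin) where
#' `h = floor(gamma * n_i)` (so the scale uses the realized trim fraction
#' `h/n_i` and the statistic reduces to the ordinary one-sample t when
#' `h = 0`).  For small samples (`n_i < 18`) the statistic
#' is multiplied by the Patel factor `a(n_i, h)` when
#' `small_sample_scale = TRUE`.
#'
#' @param design A [quad_design()].
#' @param group `"G1"` (parents) or `"G2"` (bulks).
#' @param gamma Trimming proportion in (0, 0.5).
#' @param small_sample_scale Apply Patel's `a(n, h)` scaling for `n < 18`.
#' @return data.frame with columns `t`, `df`, `p` (one row per probe).
#' @export
post_within <- function(design, group = c("G1", "G2"), gamma = 0.1,
                        small_sample_scale = TRUE) {
  group <- match.arg(group)
  b <- unclass(design)
  delta <- if (group == "G1") b[, 1] - b[, 2] else b[, 3] - b[, 4]
  post_loo(delta, set_ids(design), gamma = gamma,
           small_sample_scale = small_sample_scale)
}

# shared leave-one-out engine; gamma = NULL -> plain mean/sd (between-group
# variant), gamma numeric -> trimmed/Winsorized variant
post_loo <- function(values, sid, gamma = NULL, small_sample_scale = TRUE) {
  n_probes <- length(values)
  t_out <- rep(NA_real_, n_probes)
  df_out <- rep(NA_real_, n_probes)
  p_out <- rep(NA_real_, n_probes)
  idx_by_set <- split(seq_len(n_probes), sid)
  for (idx in idx_by_set) {
    if (length(idx) < 3L) next                    # n_i < 2: skipped
    for (k in seq_along(idx)) {
      own <- values[idx[k]]
      rest <- values[idx[-k]]
      n_i <- length(rest)
      if (is.null(gamma)) {
        centre <- mean(rest)
        s <- stats::sd(rest)
        scale <- s * sqrt(1 + 1 / n_i)
        df <- n_i - 1
        tt <- NULL
      } else {
        h <- floor(gamma * n_i)
        df <- n_i - 2 * h - 1
        if (df <= 0) next                         # trim leaves no freedom
        centre <- trimmed_mean(rest, gamma)
        s <- sqrt(winsorized_variance(rest, gamma))
        # effective trim fraction h/n keeps the scale consistent with the
        # realized trim (and reduces to the plain t when h = 0)
        scale <- s / ((1 - 2 * h / n_i) * sqrt(n_i))
      }
      if (scale == 0) {
        if (own == centre) {
          t_out[idx[k]] <- 0; df_out[idx[k]] <- df; p_out[idx[k]] <- 1
        } else {
          t_out[idx[k]] <- sign(own - centre) * Inf
          df_out[idx[k]] <- df
          p_out[idx[k]] <- .Machine$double.xmin   # degenerate: zero spread
        }
        next
      }
      tt <- (own - centre) / scale
      if (!is.null(gamma) && small_sample_scale && n_i < 18)
        tt <- patel_scale(n_i, floor(gamma * n_i)) * tt
      t_out[idx[k]] <- tt
      df_out[idx[k]] <- df
      p_out[idx[k]] <- 2 * stats::pt(-abs(tt), df = df)
    }
  }
  data.frame(t = t_out, df = df_out, p = p_out)
}

# ---------------------------------------------------------------------------
# Record table and filters
# ---------------------------------------------------------------------------

#' Build the full per-probe screening table
#'
#' Computes ratios, fold-changes, MA/D/FCD values, the three POST tests and
#' their BH adjustments (each family adjusted separately), for every PM
#' probe of the design.
#'
#' @param design A [quad_design()].
#' @param gamma Trimming proportion for the within-group tests.
#' @param small_sample_scale Apply Patel scaling (see [post_within()]).
#' @return data.frame of per-probe screening records.
#' @export
sfp_records <- function(design, gamma = 0.1, small_sample_scale = TRUE) {
  b <- unclass(design)
  q1 <- b[, 1] / b[, 2]
  q2 <- b[, 3] / b[, 4]
  between <- post_between(design)
  g1 <- post_within(design, "G1", gamma, small_sample_scale)
  g2 <- post_within(design, "G2", gamma, small_sample_scale)
  data.frame(
    probe_id = rownames(design),
    set_id = set_ids(design),
    b1 = b[, 1], b2 = b[, 2], b3 = b[, 3], b4 = b[, 4],
    q1 = q1, q2 = q2,
    fc1 = symmetric_fc(q1), fc2 = symmetric_fc(q2),
    ma = ma_value(b[, 1], b[, 2], b[, 3], b[, 4]),
    d = d_value(b[, 1], b[, 2], b[, 3], b[, 4]),
    fcd = fcd(d_value(b[, 1], b[, 2], b[, 3], b[, 4])),
    fcd_g1 = fcd(b[, 1] - b[, 2]),
    fcd_g2 = fcd(b[, 3] - b[, 4]),
    t_between = between$t, p_between = between$p,
    padj_between = bh_adjust(between$p),
    t_g1 = g1$t, p_g1 = g1$p, padj_g1 = bh_adjust(g1$p),
    t_g2 = g2$t, p_g2 = g2$p, padj_g2 = bh_adjust(g2$p),
    row.names = NULL)
}

#' Volcano-plot filter (between-group POST)
#'
#' Flags records with `padj_between < alpha` and `|ma| >= ma_cut`,
#' optionally also requiring `|fc2| >= fcf2_cut` (bulk cross-check) and all
#' four intensities above `th` (gDNA hybridisation threshold).
#'
#' @param records Output of [sfp_records()].
#' @param alpha Significance level on the BH-adjusted between-group p.
#' @param ma_cut Minimum absolute MA-value.
#' @param fcf2_cut Optional minimum absolute bulk fold-change (`NULL` skips).
#' @param th Optional intensity threshold (`NULL` skips).
#' @return Logical flag vector.
#' @export
volcano_filter <- function(records, alpha = 0.05, ma_cut = 0.75,
                           fcf2_cut = NULL, th = NULL) {
  flag <- !is.na(records$padj_between) & records$padj_between < alpha &
    abs(records$ma) >= ma_cut
  if (!is.null(fcf2_cut)) flag <- flag & abs(records$fc2) >= fcf2_cut
  if (!is.null(th))
    flag <- flag & records$b1 > th & records$b2 > th &
      records$b3 > th & records$b4 > th
  flag
}

#' Twin-volcano filter (within-group POST)
#'
#' A record is flagged when either group shows a BH-significant within-group
#' test together with a large within-group fold-change difference
#' (`|fcd| >= fcd_cut` in the significant group).  Optional bulk
#' fold-change (`fcf2_cut`) and parental fold-change (`fcp_cut`) cut-offs
#' apply on top.  The group driving the flag is recorded (the colour
#' dimension of the twin plot).
#'
#' @param records Output of [sfp_records()].
#' @param alpha Significance level on the BH-adjusted within-group p.
#' @param fcd_cut Minimum absolute fold-change difference.
#' @param fcf2_cut Optional minimum absolute bulk fold-change.
#' @param fcp_cut Optional minimum absolute parental fold-change.
#' @return data.frame with logical `flag` and `group` ("G1", "G2", "both" or
#'   `NA`).
#' @export
twin_volcano_filter <- function(records, alpha = 0.05, fcd_cut = 8,
                                fcf2_cut = NULL, fcp_cut = NULL) {
  sig1 <- !is.na(records$padj_g1) & records$padj_g1 < alpha &
    abs(records$fcd_g1) >= fcd_cut
  sig2 <- !is.na(records$padj_g2) & records$padj_g2 < alpha &
    abs(records$fcd_g2) >= fcd_cut
  flag <- sig1 | sig2
  if (!is.null(fcf2_cut)) flag <- flag & abs(records$fc2) >= fcf2_cut
  if (!is.null(fcp_cut)) flag <- flag & abs(records$fc1) >= fcp_cut
  group <- rep(NA_character_, nrow(records))
  group[flag & sig1 & !sig2] <- "G1"
  group[flag & sig2 & !sig1] <- "G2"
  group[flag & sig1 & sig2] <- "both"
  data.frame(flag = flag, group = group)
}

# ---------------------------------------------------------------------------
# Euler partition and candidate strategy
# ---------------------------------------------------------------------------

#' Euler-diagram partition of the four screening sets
#'
#' Labels each probe by its region in the four-set Euler diagram built from
#' VP4 (regions a, b, d, e), DFC2 (d, e), TVP2 (b, c, e, f) and TVP4
#' (e, f):
#' \itemize{
#'   \item `e` — in DFC2 and TVP4 (the four-way intersection),
#'   \item `d` — in DFC2 but not TVP4,
#'   \item `f` — in TVP4 but not DFC2,
#'   \item `b` — in VP4 and TVP2, in neither inner set,
#'   \item `a` — in VP4 only,
#'   \item `c` — in TVP2 only,
#'   \item `none` — flagged by no filter.
#' }
#' TVP4 is constructed by tightening TVP2, so a probe in TVP4 but not TVP2
#' is a consistency error.
#'
#' @param vp4,dfc2,tvp2,tvp4 Logical flag vectors of equal length.
#' @return Character vector of labels.
#' @export
euler_partition <- function(vp4, dfc2, tvp2, tvp4) {
  n <- length(vp4)
  stopifnot(length(dfc2) == n, length(tvp2) == n, length(tvp4) == n)
  if (any(tvp4 & !tvp2))
    stop("inconsistent flags: TVP4 must be a subset of TVP2")
  label <- rep("none", n)
  label[vp4 & !tvp2] <- "a"
  label[tvp2 & !vp4 & !tvp4] <- "c"
  label[vp4 & tvp2] <- "b"
  label[tvp2 & tvp4 & !dfc2] <- "f"
  label[dfc2 & !tvp4] <- "d"
  label[dfc2 & tvp4] <- "e"
  label
}

#' Candidate-selection strategy over the Euler partition
#'
#' Encodes the recommended strategy for turning Euler regions into a final
#' candidate list: take the four-way intersection `e` (unless its
#' fold-change difference only barely exceeds the cut-off); inspect the
#' buffers `b` (parental fold-change approaching its cut-off, strong
#' hybridisation) and `f` (intensity just below the hybridisation
#' threshold); check `a` for strong hybridisation with a near-cut-off
#' parental ratio; never take `c` or `d`.
#'
#' @param records Output of [sfp_records()].
#' @param labels Euler labels from [euler_partition()].
#' @param th gDNA hybridisation intensity threshold.
#' @param fcp_cut,fcd_cut Parental fold-change and FCD cut-offs used by the
#'   screens.
#' @param fcp_near Tolerance on `|fc1|` below `fcp_cut` still counted as
#'   "approaching the cut-off" (regions b and a).
#' @param th_near Tolerance on intensity below `th` still counted as
#'   "slightly under the threshold" (region f); default a quarter of `th`.
#' @param fcd_near Margin above `fcd_cut` under which an e-region FCD is
#'   considered to "barely exceed" the cut-off and the probe is dropped.
#' @return Logical candidate flags.
#' @export
candidate_strategy <- function(records, labels, th, fcp_cut = 2,
                               fcd_cut = 8, fcp_near = 0.15,
                               th_near = NULL, fcd_near = 0.5) {
  if (is.null(th_near)) th_near <- 0.25 * th
  bmin <- pmin(records$b1, records$b2, records$b3, records$b4)
  strong <- bmin > th
  fc_near <- abs(records$fc1) >= fcp_cut - fcp_near
  out <- rep(FALSE, nrow(records))
  out[labels == "e"] <-
    abs(records$fcd[labels == "e"]) >= fcd_cut + fcd_near
  out[labels == "b"] <- fc_near[labels == "b"] & strong[labels == "b"]
  out[labels == "f"] <- bmin[labels == "f"] >= th - th_near
  out[labels == "a"] <- strong[labels == "a"] & fc_near[labels == "a"]
  out
}

#' One-call SFP screen
#'
#' Runs [sfp_records()], the DFC screen and the four canonical filter
#' configurations (VP with and without the intensity threshold, TVP with
#' and without the parental fold-change cut), the Euler partition and the
#' candidate strategy.
#'
#' @param design A [quad_design()].
#' @param th gDNA hybridisation intensity threshold (e.g. `run_atm()$x_atm`).
#' @param alpha BH-adjusted significance level.
#' @param ma_cut,fcd_cut,fcp_cut,fcf2_cut Filter cut-offs.
#' @param gamma Trimming proportion.
#' @param small_sample_scale Apply Patel scaling (see [post_within()]).
#' @return The records data.frame extended with columns `dfc`, `vp`, `vp4`,
#'   `tvp`, `tvp4`, `tvp_group`, `euler`, `candidate`.
#' @export
sfp_screen <- function(design, th, alpha = 0.05, ma_cut = 0.75,
                       fcd_cut = 8, fcp_cut = 2, fcf2_cut = 1.5,
                       gamma = 0.1, small_sample_scale = TRUE) {
  rec <- sfp_records(design, gamma = gamma,
                     small_sample_scale = small_sample_scale)
  rec$dfc <- dfc_screen(design, th = th, eps1 = fcp_cut, eps2 = fcf2_cut)
  rec$vp <- volcano_filter(rec, alpha, ma_cut, fcf2_cut = fcf2_cut)
  rec$vp4 <- volcano_filter(rec, alpha, ma_cut, fcf2_cut = fcf2_cut,
                            th = th)
  tvp2 <- twin_volcano_filter(rec, alpha, fcd_cut, fcf2_cut = fcf2_cut)
  tvp4 <- twin_volcano_filter(rec, alpha, fcd_cut, fcf2_cut = fcf2_cut,
                              fcp_cut = fcp_cut)
  rec$tvp <- tvp2$flag
  rec$tvp4 <- tvp4$flag
  rec$tvp_group <- tvp2$group
  rec$euler <- euler_partition(rec$vp4, rec$dfc, rec$tvp, rec$tvp4)
  rec$candidate <- candidate_strategy(rec, rec$euler, th = th,
                                      fcp_cut = fcp_cut, fcd_cut = fcd_cut)
  rec
}
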