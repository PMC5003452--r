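# Synthetic chip layouts and four-chip gDNA hybridisation experiments.
#
# The generator emulates what a cross-species gDNA hybridisation looks like
# at the probe level: a bimodal log-normal intensity mix (cross-species
# background vs conserved, well-hybridising probes, assigned per probe-set
# because sequence conservation is gene-level), small multiplicative
# chip-to-chip noise, and planted single-feature polymorphisms that raise
# one parent's intensity and propagate in the same direction to the paired
# bulk.

#' Generate a synthetic chip layout
#'
#' Lays out `n_sets` probe-sets of `pairs_per_set` PM/MM probe-pairs on a
#' grid, PM and MM on adjacent rows as on real chips.  Cell positions are
#' shuffled deterministically by the seed.
#'
#' @param n_sets Number of probe-sets.
#' @param pairs_per_set Probe-pairs per set.
#' @param grid_cols,grid_rows Grid dimensions; `NULL` picks a compact grid
#'   automatically.  Capacity must cover `2 * n_sets * pairs_per_set` cells.
#' @param seed Integer seed.
#' @param chip_name Chip name written into the layout.
#' @return A [chip_layout()].
#' @export
make_layout <- function(n_sets, pairs_per_set, grid_cols = NULL,
                        grid_rows = NULL, seed = 1L,
                        chip_name = "SYNTH1") {
  n_probes <- n_sets * pairs_per_set
  if (is.null(grid_cols)) grid_cols <- max(8L, ceiling(sqrt(n_probes)))
  if (is.null(grid_rows)) grid_rows <- 2L * ceiling(n_probes / grid_cols)
  if (grid_cols * grid_rows < 2L * n_probes)
    stop(sprintf("grid %dx%d cannot hold %d PM+MM cells",
                 grid_rows, grid_cols, 2L * n_probes))
  set.seed(seed)
  # PM cells live on even rows, their MM partner directly below
  n_slots <- grid_cols * floor(grid_rows / 2)
  slots <- sample.int(n_slots, n_probes)
  pm_x <- (slots - 1L) %% grid_cols
  pm_y <- 2L * ((slots - 1L) %/% grid_cols)
  ids <- sprintf("s%05d_at", seq_len(n_sets))
  probe_sets <- lapply(seq_len(n_sets), function(i) {
    j <- (i - 1L) * pairs_per_set + seq_len(pairs_per_set)
    data.frame(pm_x = as.integer(pm_x[j]), pm_y = as.integer(pm_y[j]),
               mm_x = as.integer(pm_x[j]), mm_y = as.integer(pm_y[j] + 1L),
               expos = seq_len(pairs_per_set) - 1L)
  })
  names(probe_sets) <- ids
  chip_layout(chip_name, grid_rows, grid_cols, probe_sets)
}

#' Simulate a four-chip single-trait gDNA experiment
#'
#' Draws one base intensity per PM probe from a two-component log-normal
#' mix (background vs hybridising), then one observation per chip with
#' multiplicative log-normal chip noise.  `n_sfp` hybridising probes are
#' planted as single-feature polymorphisms: a randomly chosen parent's
#' intensity is multiplied by `sfp_fold` and the same change propagates to
#' the paired bulk (B1 to B3, B2 to B4) with probability
#' `bulk_consistency`.  MM cells receive background-level intensities.
#'
#' Hybridisation is assigned hierarchically: a fraction of probe-sets is
#' "conserved" and most of their probes hybridise, the rest hybridise
#' rarely, so that the marginal probe-level hybridising fraction is about
#' `frac_hyb` while probe-sets die over a narrow threshold band and the
#' retention curve shows a plateau-knee-drop shape.
#'
#' @param layout A [chip_layout()].
#' @param frac_hyb Target marginal fraction of hybridising PM probes.
#' @param mu_bg,mu_hyb Log-scale means of the background and hybridising
#'   intensity components (well separated).
#' @param sigma Log-scale spread of per-probe base intensities.
#' @param chip_sd Log-scale chip-to-chip noise.
#' @param n_sfp Number of planted SFP probes.
#' @param sfp_fold Fold elevation of the affected parent (>= 4 recommended).
#' @param bulk_consistency Probability that the paired bulk inherits the
#'   parental change.
#' @param seed Integer seed.
#' @return List with `arrays` (4 [intensity_array()]s named B1..B4) and
#'   `truth` (data.frame `probe_id`, `chip_affected`, `fold`, `direction`,
#'   `in_bulk`).
#' @export
simulate_quad <- function(layout, frac_hyb = 0.35, mu_bg = log(40),
                          mu_hyb = log(700), sigma = 0.45,
                          chip_sd = 0.1, n_sfp = 10L, sfp_fold = 4,
                          bulk_consistency = 1.0, seed = 1L) {
  set.seed(seed)
  sets <- layout$probe_sets
  nps <- vapply(sets, nrow, integer(1))
  n_probes <- sum(nps)
  n_sets <- length(sets)
  # hierarchical hybridisation: conserved sets hybridise at p_in = 0.9,
  # others at p_out = 0.05; conserved-set fraction solves the marginal rate
  p_in <- 0.9; p_out <- 0.05
  frac_sets <- min(1, max(0, (frac_hyb - p_out) / (p_in - p_out)))
  conserved <- stats::runif(n_sets) < frac_sets
  p_probe <- ifelse(rep(conserved, nps), p_in, p_out)
  hyb <- stats::runif(n_probes) < p_probe
  base <- exp(stats::rnorm(n_probes, ifelse(hyb, mu_hyb, mu_bg), sigma))
  if (n_sfp > sum(hyb))
    stop(sprintf("cannot plant %d SFPs among %d hybridising probes",
                 n_sfp, sum(hyb)))
  fold_mat <- matrix(1, nrow = n_probes, ncol = 4)
  sid <- rep(names(sets), nps)
  pm_x <- unlist(lapply(sets, `[[`, "pm_x"), use.names = FALSE)
  pm_y <- unlist(lapply(sets, `[[`, "pm_y"), use.names = FALSE)
  probe_ids <- sprintf("%s_%d_%d", sid, pm_x, pm_y)
  truth <- data.frame(probe_id = character(0), chip_affected = character(0),
                      fold = numeric(0), direction = character(0),
                      in_bulk = logical(0))
  if (n_sfp > 0L) {
    sfp_idx <- sample(which(hyb), n_sfp)
    parent <- sample(c(1L, 2L), n_sfp, replace = TRUE)
    in_bulk <- stats::runif(n_sfp) < bulk_consistency
    for (s in seq_len(n_sfp)) {
      fold_mat[sfp_idx[s], parent[s]] <- sfp_fold
      if (in_bulk[s]) fold_mat[sfp_idx[s], parent[s] + 2L] <- sfp_fold
    }
    truth <- data.frame(
      probe_id = probe_ids[sfp_idx],
      chip_affected = c("B1", "B2")[parent],
      fold = rep(sfp_fold, n_sfp),
      direction = ifelse(parent == 1L, "up_in_P1", "up_in_P2"),
      in_bulk = in_bulk)
  }
  chip_ids <- c("B1", "B2", "B3", "B4")
  arrays <- vector("list", 4L)
  bg_fill <- function() exp(stats::rnorm(layout$n_rows * layout$n_cols,
                                         mu_bg, sigma))
  for (m in 1:4) {
    vals <- matrix(bg_fill(), nrow = layout$n_rows, ncol = layout$n_cols)
    noise <- exp(stats::rnorm(n_probes, 0, chip_sd))
    vals[cbind(pm_y + 1L, pm_x + 1L)] <- base * fold_mat[, m] * noise
    arrays[[m]] <- intensity_array(chip_ids[m], round(vals, 1))
  }
  names(arrays) <- chip_ids
  list(arrays = arrays, truth = truth)
}

#' Write a complete fixture bundle
#'
#' Writes the layout as a text CDF, each chip as a version 3 text CEL, and
#' the planted truth as TSV, all readable back by the package's readers.
#'
#' @param dir Output directory (created if missing).
#' @param layout A [chip_layout()].
#' @param arrays Named list of [intensity_array()]s.
#' @param truth Optional truth data.frame from [simulate_quad()].
#' @return Invisibly, a named list of the written paths.
#' @export
write_fixture_bundle <- function(dir, layout, arrays, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cdf <- file.path(dir, paste0(layout$chip_name, ".CDF"))
  write_masked_cdf(layout, path = cdf)
  cels <- vapply(arrays, function(a) {
    p <- file.path(dir, paste0(a$chip_id, ".CEL"))
    write_cel_text(a, p)
    p
  }, character(1))
  paths <- list(cdf = cdf, cels = cels)
  if (!is.null(truth)) {
    tp <- file.path(dir, "truth.tsv")
    utils::write.table(truth, tp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$truth <- tp
  }
  invisible(paths)
}

#' Synthetic retention curve with a planted knee
#'
#' Builds a plateau / linear-drop / zero-tail probe-set retention curve with
#' the knee at `knee`, plus a proportional probe-pair component, with
#' optional integer-rounded noise kept monotone.  Used for ATM recovery
#' testing.
#'
#' @param knee Threshold at which the plateau ends.
#' @param drop_end Threshold at which retention reaches zero.
#' @param n_sets Plateau height (probe-set count).
#' @param pairs_per_set Pair multiplier for the pair component.
#' @param thresholds Threshold grid.
#' @param noise_sd Standard deviation of the additive noise (counts).
#' @param seed Integer seed (`NULL` for no noise).
#' @return A [retention_curve()].
#' @export
make_knee_curve <- function(knee, drop_end, n_sets = 100L,
                            pairs_per_set = 10L, thresholds = 0:100,
                            noise_sd = 0, seed = NULL) {
  stopifnot(drop_end > knee)
  x <- sort(thresholds)
  frac <- pmin(1, pmax(0, (drop_end - x) / (drop_end - knee)))
  sets <- n_sets * frac
  pairs <- n_sets * pairs_per_set * frac
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    sets <- sets + stats::rnorm(length(x), 0, noise_sd)
    pairs <- pairs + stats::rnorm(length(x), 0, noise_sd * pairs_per_set)
  }
  sets <- cummin(pmax(0, round(sets)))
  pairs <- cummin(pmax(0, round(pairs)))
  pairs <- pmax(pairs, sets)   # a retained set implies >= 1 retained pair
  retention_curve(x, as.integer(pairs), as.integer(sets))
}
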