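# Shared in-code fixtures: tiny layouts, arrays and malformed files.

# two probe-sets (3 + 2 pairs) on an 8x8 grid, fixed coordinates
tiny_layout <- function() {
  chip_layout("TINY", 8L, 8L, list(
    setA_at = data.frame(pm_x = c(0L, 1L, 2L), pm_y = c(0L, 0L, 0L),
                         mm_x = c(0L, 1L, 2L), mm_y = c(1L, 1L, 1L),
                         expos = 0:2),
    setB_at = data.frame(pm_x = c(3L, 4L), pm_y = c(2L, 2L),
                         mm_x = c(3L, 4L), mm_y = c(3L, 3L),
                         expos = 0:1)))
}

# intensity array with a deterministic value at each cell:
# value = base + x + 10 * y  (distinct everywhere)
tiny_array <- function(chip_id = "chip1", base = 100, n = 8L) {
  vals <- outer(seq_len(n) - 1L, seq_len(n) - 1L,
                function(r, c) base + c + 10 * r)
  intensity_array(chip_id, vals)
}

# literal minimal 2x2 version 3 CEL text
cel2x2_text <- function(means = c(10, 20, 30, 40)) {
  c("[CEL]", "Version=3", "",
    "[HEADER]", "Cols=2", "Rows=2", "",
    "[INTENSITY]", "NumberCells=4", "CellHeader=X\tY\tMEAN\tSTDV\tNPIXELS",
    sprintf("%d\t%d\t%.1f\t0.0\t9", c(0L, 1L, 0L, 1L), c(0L, 0L, 1L, 1L),
            means),
    "")
}

write_lines_tmp <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# a preprocessed quad design of given size (shared by sfp tests)
make_quad <- function(n_sets = 50L, pairs = 11L, n_sfp = 0L, seed = 42L,
                      preprocess_it = FALSE, ...) {
  lay <- make_layout(n_sets, pairs, seed = seed)
  sim <- simulate_quad(lay, n_sfp = n_sfp, seed = seed, ...)
  pm <- extract_pm(lay, sim$arrays)
  if (preprocess_it) pm <- preprocess(pm)
  list(design = quad_design(pm), truth = sim$truth, layout = lay,
       arrays = sim$arrays)
}
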