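# ---------------------------------------------------------------------------
# Domain containers
# ---------------------------------------------------------------------------

#' Chip layout (probe-set to cell map)
#'
#' A `chip_layout` describes which physical cells of an array belong to which
#' probe-set: the universe that probe masking operates on.  It is normally
#' obtained from [read_cdf_text()] or [make_layout()].
#'
#' @param chip_name Chip identifier string.
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param probe_sets Named list; one element per probe-set, each a data.frame
#'   with columns `pm_x`, `pm_y`, `mm_x`, `mm_y` (0-based cell coordinates,
#'   `mm_*` may be `NA`) and `expos` (probe interrogation position, used for
#'   ordering).  Probe-set order and within-set pair order define the
#'   canonical probe order used everywhere else.
#'
#' @return An object of class `chip_layout`.
#' @export
chip_layout <- function(chip_name, n_rows, n_cols, probe_sets) {
  stopifnot(is.character(chip_name), length(chip_name) == 1L,
            n_rows >= 1L, n_cols >= 1L, is.list(probe_sets))
  if (is.null(names(probe_sets)) && length(probe_sets) > 0L)
    stop("probe_sets must be named by probe-set id")
  obj <- structure(list(chip_name = chip_name,
                        n_rows = as.integer(n_rows),
                        n_cols = as.integer(n_cols),
                        probe_sets = probe_sets),
                   class = "chip_layout")
  validate_chip_layout(obj)
  obj
}

validate_chip_layout <- function(x) {
  seen <- character(0)
  for (id in names(x$probe_sets)) {
    ps <- x$probe_sets[[id]]
    if (nrow(ps) < 1L)
      stop(sprintf("probe-set '%s' has no probe-pairs", id))
    if (any(ps$pm_x < 0L | ps$pm_x >= x$n_cols | ps$pm_y < 0L |
            ps$pm_y >= x$n_rows))
      stop(sprintf("probe-set '%s' has PM coordinates outside the grid", id))
    key <- paste(ps$pm_x, ps$pm_y)
    if (any(key %in% seen) || anyDuplicated(key))
      stop(sprintf("duplicate PM cell coordinate in probe-set '%s'", id))
    seen <- c(seen, key)
  }
  invisible(x)
}

#' @export
print.chip_layout <- function(x, ...) {
  cat(sprintf("chip_layout '%s': %d x %d grid, %d probe-sets, %d probe-pairs\n",
              x$chip_name, x$n_rows, x$n_cols, length(x$probe_sets),
              n_pairs(x)))
  invisible(x)
}

#' Number of probe-pairs in a layout
#' @param layout A [chip_layout()].
#' @return Integer count of probe-pairs.
#' @export
n_pairs <- function(layout) {
  sum(vapply(layout$probe_sets, nrow, integer(1)))
}

#' Per-chip cell intensities
#'
#' @param chip_id Chip identifier.
#' @param values Numeric matrix of non-negative intensities, `n_rows` x
#'   `n_cols`; `values[r + 1, c + 1]` is the intensity of cell `(x = c,
#'   y = r)` in 0-based CEL coordinates.
#' @return An object of class `intensity_array`.
#' @export
intensity_array <- function(chip_id, values) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(!is.finite(values)) || any(values < 0))
    stop("intensities must be finite and >= 0")
  structure(list(chip_id = chip_id,
                 n_rows = nrow(values), n_cols = ncol(values),
                 values = values),
            class = "intensity_array")
}

#' @export
print.intensity_array <- function(x, ...) {
  cat(sprintf("intensity_array '%s': %d x %d cells, median %.1f\n",
              x$chip_id, x$n_rows, x$n_cols, stats::median(x$values)))
  invisible(x)
}

#' Probes-by-chips intensity matrix
#'
#' Thin S3 wrapper around a numeric matrix.  Rows follow the canonical probe
#' order of a [chip_layout()] (probe-set order, then pair order); row names
#' are probe ids of the form `"<setid>_<x>_<y>"` using the raw 0-based PM
#' cell coordinates.  A `set_id` attribute maps each row to its probe-set.
#'
#' @param values Numeric matrix, probes x chips.
#' @param probe_ids Character row names.
#' @param chip_ids Character column names.
#' @param set_ids Character vector, one probe-set id per row.
#' @return An object of class `probe_matrix` (also a plain matrix).
#' @export
probe_matrix <- function(values, probe_ids, chip_ids, set_ids) {
  stopifnot(is.matrix(values), length(probe_ids) == nrow(values),
            length(chip_ids) == ncol(values),
            length(set_ids) == nrow(values))
  dimnames(values) <- list(probe_ids, chip_ids)
  structure(values, set_id = set_ids, class = c("probe_matrix", "matrix"))
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe_matrix: %d probes x %d chips (%d probe-sets)\n",
              nrow(x), ncol(x), length(unique(attr(x, "set_id")))))
  invisible(x)
}

#' Probe-set ids aligned to the rows of a probe matrix
#' @param pm A [probe_matrix()].
#' @return Character vector of probe-set ids, one per row.
#' @export
set_ids <- function(pm) attr(pm, "set_id")

# keep attributes through subsetting of rows
#' @export
`[.probe_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    sid <- attr(x, "set_id")
    if (!missing(i)) sid <- sid[i]
    attr(out, "set_id") <- sid
    class(out) <- c("probe_matrix", "matrix")
  }
  out
}

# ---------------------------------------------------------------------------
# CEL version 3 (text)
# ---------------------------------------------------------------------------

cel_format_error <- function(path, line, msg) {
  stop(sprintf("CEL format error in '%s' (line %d): %s", path, line, msg),
       call. = FALSE)
}

#' Read a text (version 3) CEL file
#'
#' Parses the `[CEL]` / `[HEADER]` / `[INTENSITY]` sections of an Affymetrix
#' text CEL file.  The MEAN column becomes the cell value; STDV and NPIXELS
#' are parsed but discarded.
#'
#' @param path Path to a version 3 CEL file.
#' @param chip_id Chip identifier; defaults to the file name without
#'   extension.
#' @return An [intensity_array()].
#' @export
read_cel_text <- function(path, chip_id = NULL) {
  if (is.null(chip_id))
    chip_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  sec <- grep("^\\[CEL\\]", lines)
  if (length(sec) == 0L) cel_format_error(path, 1L, "missing [CEL] section")
  ver <- grep("^Version=", lines, value = TRUE)
  if (length(ver) == 0L) cel_format_error(path, 1L, "missing Version")
  if (trimws(sub("^Version=", "", ver[1])) != "3")
    cel_format_error(path, grep("^Version=", lines)[1],
                     sprintf("unsupported CEL version '%s' (need 3)",
                             sub("^Version=", "", ver[1])))
  hdr <- grep("^\\[HEADER\\]", lines)
  if (length(hdr) == 0L) cel_format_error(path, 1L, "missing [HEADER] section")
  getnum <- function(key) {
    i <- grep(sprintf("^%s=", key), lines)
    if (length(i) == 0L) cel_format_error(path, hdr[1],
                                          sprintf("missing %s", key))
    as.integer(sub(sprintf("^%s=", key), "", lines[i[1]]))
  }
  n_cols <- getnum("Cols")
  n_rows <- getnum("Rows")
  int_at <- grep("^\\[INTENSITY\\]", lines)
  if (length(int_at) == 0L)
    cel_format_error(path, 1L, "missing [INTENSITY] section")
  int_at <- int_at[1]
  nc_line <- grep("^NumberCells=", lines)
  nc_line <- nc_line[nc_line > int_at][1]
  if (is.na(nc_line))
    cel_format_error(path, int_at, "missing NumberCells")
  n_cells <- as.integer(sub("^NumberCells=", "", lines[nc_line]))
  ch_line <- grep("^CellHeader=", lines)
  ch_line <- ch_line[ch_line > int_at][1]
  if (is.na(ch_line))
    cel_format_error(path, int_at, "missing CellHeader")
  if (n_cells != n_rows * n_cols)
    cel_format_error(path, nc_line, sprintf(
      "NumberCells=%d does not match %d x %d grid", n_cells, n_rows, n_cols))
  body <- lines[seq.int(ch_line + 1L, length.out = length(lines) - ch_line)]
  # data rows end at the next section or blank tail
  stop_at <- which(grepl("^\\[", body) | !nzchar(trimws(body)))
  if (length(stop_at)) body <- body[seq_len(min(stop_at) - 1L)]
  if (length(body) < n_cells)
    cel_format_error(path, ch_line + length(body) + 1L, sprintf(
      "expected %d cell rows, found %d (file truncated?)",
      n_cells, length(body)))
  body <- body[seq_len(n_cells)]
  fields <- utils::read.table(text = body, header = FALSE,
                              col.names = c("x", "y", "mean", "stdv", "npix"),
                              colClasses = c("integer", "integer", "numeric",
                                             "numeric", "integer"))
  if (any(fields$x < 0L | fields$y < 0L))
    cel_format_error(path, ch_line + which(fields$x < 0L | fields$y < 0L)[1],
                     "negative cell coordinate")
  if (any(fields$x >= n_cols | fields$y >= n_rows))
    cel_format_error(path,
                     ch_line + which(fields$x >= n_cols | fields$y >= n_rows)[1],
                     "cell coordinate outside declared grid")
  idx <- fields$y * n_cols + fields$x + 1L
  if (anyDuplicated(idx))
    cel_format_error(path, ch_line, "duplicate cell coordinate")
  vals <- matrix(NA_real_, nrow = n_rows, ncol = n_cols)
  vals[cbind(fields$y + 1L, fields$x + 1L)] <- fields$mean
  if (anyNA(vals))
    cel_format_error(path, ch_line, "not every cell present exactly once")
  intensity_array(chip_id, vals)
}

#' Write a text (version 3) CEL file
#'
#' Counterpart of [read_cel_text()]; used by the synthetic-data generator to
#' build fixtures.  STDV is written as 0 and NPIXELS as 9.
#'
#' @param array An [intensity_array()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cel_text <- function(array, path) {
  n_rows <- array$n_rows; n_cols <- array$n_cols
  xy <- expand.grid(x = seq_len(n_cols) - 1L, y = seq_len(n_rows) - 1L)
  means <- array$values[cbind(xy$y + 1L, xy$x + 1L)]
  con <- file(path, "wb")  # binary mode => deterministic LF line endings
  on.exit(close(con))
  writeLines(c("[CEL]", "Version=3", "",
               "[HEADER]",
               sprintf("Cols=%d", n_cols),
               sprintf("Rows=%d", n_rows),
               "TotalX=0", "TotalY=0", "OffsetX=0", "OffsetY=0",
               sprintf("Algorithm=%s", "Percentile"),
               "AlgorithmParameters=", "",
               "[INTENSITY]",
               sprintf("NumberCells=%d", n_rows * n_cols),
               "CellHeader=X\tY\tMEAN\tSTDV\tNPIXELS"),
             con)
  writeLines(sprintf("%3d\t%3d\t%.1f\t%.1f\t%3d",
                     xy$x, xy$y, means, 0, 9L), con)
  writeLines(c("", "[MASKS]", "NumberCells=0", "CellHeader=X\tY", "",
               "[OUTLIERS]", "NumberCells=0", "CellHeader=X\tY", "",
               "[MODIFIED]", "NumberCells=0", "CellHeader=X\tY\tORIGMEAN"),
             con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# CEL version 4 (binary, little-endian) — optional extension
# ---------------------------------------------------------------------------

#' Read a binary (version 4) CEL file
#'
#' Little-endian v4 layout: int32 magic 64, int32 version 4, then grid
#' dimensions, cell count, three length-prefixed strings (header, algorithm,
#' parameters), cell margin, outlier/masked/subgrid counts, and per cell
#' (float mean, float stdv, int16 npixels).
#'
#' @inheritParams read_cel_text
#' @return An [intensity_array()].
#' @export
read_cel_binary <- function(path, chip_id = NULL) {
  if (is.null(chip_id))
    chip_id <- sub("\\.[^.]*$", "", basename(path))
  if (file.size(path) < 24)
    stop(sprintf("CEL format error in '%s': file too short for v4 header",
                 path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  i32 <- function(n = 1L) readBin(con, "integer", n = n, size = 4L,
                                  endian = "little")
  magic <- i32(); version <- i32()
  if (!identical(magic, 64L) || !identical(version, 4L))
    stop(sprintf("CEL format error in '%s': bad magic/version (%d/%d)",
                 path, magic, version), call. = FALSE)
  n_cols <- i32(); n_rows <- i32(); n_cells <- i32()
  if (n_cells != n_cols * n_rows)
    stop(sprintf("CEL format error in '%s': cell count mismatch", path),
         call. = FALSE)
  for (k in 1:3) {                      # header, algorithm, parameters
    len <- i32()
    if (len > 0) readBin(con, "raw", n = len)
  }
  i32()                                 # cell margin
  readBin(con, "integer", n = 2L, size = 4L, endian = "little") # outliers, masked
  i32()                                 # subgrids
  rec <- readBin(con, "raw", n = 10L * n_cells)
  if (length(rec) < 10L * n_cells)
    stop(sprintf("CEL format error in '%s': truncated cell block", path),
         call. = FALSE)
  m <- matrix(rec, nrow = 10L)
  means <- readBin(as.vector(m[1:4, ]), "double", n = n_cells, size = 4L,
                   endian = "little")
  # v4 cells are stored row-major by (y, x)
  vals <- matrix(means, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  intensity_array(chip_id, vals)
}

#' Write a binary (version 4) CEL file
#' @inheritParams write_cel_text
#' @return Invisibly, `path`.
#' @export
write_cel_binary <- function(array, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L,
                              endian = "little")
  w32(64L); w32(4L)
  w32(array$n_cols); w32(array$n_rows); w32(array$n_rows * array$n_cols)
  for (s in c("", "Percentile", "")) {
    raw <- charToRaw(s)
    w32(length(raw))
    if (length(raw)) writeBin(raw, con)
  }
  w32(0L)           # cell margin
  w32(0L); w32(0L)  # outliers, masked
  w32(0L)           # subgrids
  means <- as.vector(t(array$values))  # row-major (y, x)
  for (i in seq_along(means)) {
    writeBin(means[i], con, size = 4L, endian = "little")
    writeBin(0, con, size = 4L, endian = "little")
    writeBin(9L, con, size = 2L, endian = "little")
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# CDF (text)
# ---------------------------------------------------------------------------

cdf_format_error <- function(path, msg) {
  stop(sprintf("CDF format error in '%s': %s", path, msg), call. = FALSE)
}

#' Read an Affymetrix text CDF file
#'
#' Parses the `[Chip]` header and every `[UnitN_BlockM]` section.  A cell is
#' taken as perfect-match when its PBASE differs from its TBASE, mismatch
#' otherwise; PM/MM cells are paired by their EXPOS value and pairs are
#' ordered by EXPOS.
#'
#' @param path Path to a text CDF file.
#' @return A [chip_layout()].
#' @export
read_cdf_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(grep("^\\[CDF\\]", lines)))
    cdf_format_error(path, "missing [CDF] section")
  getval <- function(key, after = 0L) {
    i <- grep(sprintf("^%s=", key), lines)
    i <- i[i > after]
    if (!length(i)) cdf_format_error(path, sprintf("missing %s", key))
    sub(sprintf("^%s=", key), "", lines[i[1]])
  }
  chip_at <- grep("^\\[Chip\\]", lines)
  if (!length(chip_at)) cdf_format_error(path, "missing [Chip] section")
  chip_name <- getval("Name", chip_at[1])
  n_rows <- as.integer(getval("Rows", chip_at[1]))
  n_cols <- as.integer(getval("Cols", chip_at[1]))
  n_units <- as.integer(getval("NumberOfUnits", chip_at[1]))
  block_at <- grep("^\\[Unit[0-9]+_Block[0-9]+\\]", lines)
  if (length(block_at) != n_units)
    cdf_format_error(path, sprintf(
      "NumberOfUnits=%d but found %d unit blocks", n_units, length(block_at)))
  probe_sets <- vector("list", length(block_at))
  ids <- character(length(block_at))
  bounds <- c(block_at, length(lines) + 1L)
  for (b in seq_along(block_at)) {
    chunk <- lines[seq.int(block_at[b], bounds[b + 1L] - 1L)]
    name <- sub("^Name=", "", grep("^Name=", chunk, value = TRUE)[1])
    ncells <- as.integer(sub("^NumCells=", "",
                             grep("^NumCells=", chunk, value = TRUE)[1]))
    cell_rows <- grep("^Cell[0-9]+=", chunk, value = TRUE)
    if (!length(cell_rows) || is.na(ncells) || ncells == 0L)
      cdf_format_error(path, sprintf("unit '%s' has zero cells", name))
    if (length(cell_rows) != ncells)
      cdf_format_error(path, sprintf(
        "unit '%s' declares NumCells=%d but lists %d", name, ncells,
        length(cell_rows)))
    tab <- utils::read.table(text = sub("^Cell[0-9]+=", "", cell_rows),
                             header = FALSE, stringsAsFactors = FALSE)
    # CellHeader=X Y PROBE FEAT QUAL EXPOS POS CBASE PBASE TBASE ATOM INDEX
    colnames(tab)[c(1, 2, 6, 8, 9, 10)] <-
      c("x", "y", "expos", "cbase", "pbase", "tbase")
    if (any(tab$x < 0L | tab$x >= n_cols | tab$y < 0L | tab$y >= n_rows))
      cdf_format_error(path, sprintf(
        "unit '%s' has a cell coordinate outside the %dx%d grid",
        name, n_rows, n_cols))
    is_pm <- toupper(tab$pbase) != toupper(tab$tbase)
    pm <- tab[is_pm, , drop = FALSE]
    mm <- tab[!is_pm, , drop = FALSE]
    pm <- pm[order(pm$expos), , drop = FALSE]
    mm_x <- rep(NA_integer_, nrow(pm)); mm_y <- rep(NA_integer_, nrow(pm))
    if (nrow(mm)) {
      match_idx <- match(pm$expos, mm$expos)
      mm_x <- mm$x[match_idx]; mm_y <- mm$y[match_idx]
    }
    probe_sets[[b]] <- data.frame(pm_x = as.integer(pm$x),
                                  pm_y = as.integer(pm$y),
                                  mm_x = as.integer(mm_x),
                                  mm_y = as.integer(mm_y),
                                  expos = as.integer(pm$expos))
    ids[b] <- name
  }
  names(probe_sets) <- ids
  chip_layout(chip_name, n_rows, n_cols, probe_sets)
}

#' Write a (possibly masked) text CDF file
#'
#' Writes `layout` as an Affymetrix text CDF, keeping only probe-pairs whose
#' `retained` flag is `TRUE`.  Probe-sets left with zero retained pairs are
#' dropped entirely, so the unit count of the output equals the number of
#' probe-sets with at least one retained pair.  Header counts
#' (NumberOfUnits, NumAtoms, NumCells) are updated consistently and the
#' output is re-readable by [read_cdf_text()].
#'
#' @param layout A [chip_layout()].
#' @param retained Logical vector, one flag per probe-pair in canonical
#'   order (defaults to all `TRUE`, i.e. a plain CDF dump).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_masked_cdf <- function(layout, retained = NULL, path) {
  np <- n_pairs(layout)
  if (is.null(retained)) retained <- rep(TRUE, np)
  if (length(retained) != np)
    stop(sprintf("retained has length %d but layout has %d probe-pairs",
                 length(retained), np))
  masked <- mask_layout(layout, retained)
  con <- file(path, "wb")
  on.exit(close(con))
  out <- c("[CDF]", "Version=GC3.0", "",
           "[Chip]",
           sprintf("Name=%s", masked$chip_name),
           sprintf("Rows=%d", masked$n_rows),
           sprintf("Cols=%d", masked$n_cols),
           sprintf("NumberOfUnits=%d", length(masked$probe_sets)),
           sprintf("MaxUnit=%d", length(masked$probe_sets)),
           "NumQCUnits=0",
           "ChipReference=", "")
  writeLines(out, con)
  unit <- 0L
  for (id in names(masked$probe_sets)) {
    unit <- unit + 1L
    ps <- masked$probe_sets[[id]]
    has_mm <- !is.na(ps$mm_x)
    ncells <- nrow(ps) + sum(has_mm)
    writeLines(c(sprintf("[Unit%d]", unit),
                 sprintf("Name=NONE"),
                 "Direction=1",
                 sprintf("NumAtoms=%d", nrow(ps)),
                 sprintf("NumCells=%d", ncells),
                 sprintf("UnitNumber=%d", unit),
                 "UnitType=3",
                 "NumberBlocks=1", "",
                 sprintf("[Unit%d_Block1]", unit),
                 sprintf("Name=%s", id),
                 "BlockNumber=1",
                 sprintf("NumAtoms=%d", nrow(ps)),
                 sprintf("NumCells=%d", ncells),
                 "StartPosition=0",
                 sprintf("StopPosition=%d", nrow(ps) - 1L),
                 paste0("CellHeader=X\tY\tPROBE\tFEAT\tQUAL\tEXPOS\tPOS\t",
                        "CBASE\tPBASE\tTBASE\tATOM\tINDEX")),
               con)
    cell <- 0L
    for (j in seq_len(nrow(ps))) {
      cell <- cell + 1L
      writeLines(sprintf(
        "Cell%d=%d\t%d\tN\tcontrol\t%s\t%d\t13\tC\tC\tG\t%d\t%d",
        cell, ps$pm_x[j], ps$pm_y[j], id, ps$expos[j], j - 1L,
        ps$pm_y[j] * masked$n_cols + ps$pm_x[j]), con)
      if (has_mm[j]) {
        cell <- cell + 1L
        writeLines(sprintf(
          "Cell%d=%d\t%d\tN\tcontrol\t%s\t%d\t13\tC\tG\tG\t%d\t%d",
          cell, ps$mm_x[j], ps$mm_y[j], id, ps$expos[j], j - 1L,
          ps$mm_y[j] * masked$n_cols + ps$mm_x[j]), con)
      }
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Apply per-pair retention flags to a layout in memory
#'
#' @inheritParams write_masked_cdf
#' @return A [chip_layout()] containing only retained pairs; probe-sets with
#'   no retained pair are dropped.
#' @export
mask_layout <- function(layout, retained) {
  np <- n_pairs(layout)
  if (length(retained) != np)
    stop(sprintf("retained has length %d but layout has %d probe-pairs",
                 length(retained), np))
  offset <- 0L
  keep_sets <- list()
  for (id in names(layout$probe_sets)) {
    ps <- layout$probe_sets[[id]]
    flags <- retained[offset + seq_len(nrow(ps))]
    offset <- offset + nrow(ps)
    if (any(flags))
      keep_sets[[id]] <- ps[flags, , drop = FALSE]
  }
  structure(list(chip_name = layout$chip_name, n_rows = layout$n_rows,
                 n_cols = layout$n_cols, probe_sets = keep_sets),
            class = "chip_layout")
}

# ---------------------------------------------------------------------------
# PM extraction
# ---------------------------------------------------------------------------

#' Extract perfect-match intensities into a probe matrix
#'
#' Pulls the PM cell of every probe-pair, in canonical order, from each chip.
#' Downstream analysis is PM-only by default; set `include_mm = TRUE` to
#' append MM rows (probe ids suffixed by the MM coordinates).
#'
#' @param layout A [chip_layout()].
#' @param arrays List of [intensity_array()] objects sharing the layout's
#'   grid dimensions.
#' @param include_mm Append mismatch rows as well (default `FALSE`).
#' @return A [probe_matrix()], one row per PM probe and one column per chip.
#' @export
extract_pm <- function(layout, arrays, include_mm = FALSE) {
  if (!length(arrays)) stop("no intensity arrays supplied")
  if (inherits(arrays, "intensity_array")) arrays <- list(arrays)
  for (a in arrays) {
    if (a$n_rows != layout$n_rows || a$n_cols != layout$n_cols)
      stop(sprintf("chip '%s' is %dx%d but layout '%s' is %dx%d",
                   a$chip_id, a$n_rows, a$n_cols, layout$chip_name,
                   layout$n_rows, layout$n_cols))
  }
  sets <- layout$probe_sets
  nps <- vapply(sets, nrow, integer(1))
  sid <- rep(names(sets), nps)
  pm_x <- unlist(lapply(sets, `[[`, "pm_x"), use.names = FALSE)
  pm_y <- unlist(lapply(sets, `[[`, "pm_y"), use.names = FALSE)
  probe_ids <- sprintf("%s_%d_%d", sid, pm_x, pm_y)
  idx <- cbind(pm_y + 1L, pm_x + 1L)
  vals <- vapply(arrays, function(a) a$values[idx],
                 numeric(length(probe_ids)))
  vals <- matrix(vals, ncol = length(arrays))
  chip_ids <- vapply(arrays, `[[`, character(1), "chip_id")
  if (include_mm) {
    mm_x <- unlist(lapply(sets, `[[`, "mm_x"), use.names = FALSE)
    mm_y <- unlist(lapply(sets, `[[`, "mm_y"), use.names = FALSE)
    keep <- !is.na(mm_x)
    if (any(keep)) {
      midx <- cbind(mm_y[keep] + 1L, mm_x[keep] + 1L)
      mvals <- vapply(arrays, function(a) a$values[midx],
                      numeric(sum(keep)))
      mvals <- matrix(mvals, ncol = length(arrays))
      vals <- rbind(vals, mvals)
      probe_ids <- c(probe_ids,
                     sprintf("%s_mm_%d_%d", sid[keep], mm_x[keep], mm_y[keep]))
      sid <- c(sid, sid[keep])
    }
  }
  probe_matrix(vals, probe_ids, chip_ids, sid)
}

#' Write a probe matrix as TSV
#' @param pm A [probe_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_probe_matrix <- function(pm, path) {
  df <- data.frame(probe_id = rownames(pm), set_id = set_ids(pm),
                   as.data.frame(unclass(pm)[, , drop = FALSE]),
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe matrix from TSV
#' @param path TSV written by [write_probe_matrix()] (columns `probe_id`,
#'   `set_id`, then one column per chip).
#' @return A [probe_matrix()].
#' @export
read_probe_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "set_id") %in% colnames(df)))
    stop("expected columns probe_id and set_id")
  chips <- setdiff(colnames(df), c("probe_id", "set_id"))
  probe_matrix(as.matrix(df[, chips, drop = FALSE]), df$probe_id, chips,
               df$set_id)
}
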