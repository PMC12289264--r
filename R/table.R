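# Construct a size_table, checking shape and basic sanity.
new_size_table <- function(k_values, trephine_values, cells,
                           kindex = KINDEX_DEFAULT) {
  stopifnot(is.numeric(k_values), is.numeric(trephine_values),
            is.matrix(cells),
            nrow(cells) == length(k_values),
            ncol(cells) == length(trephine_values))
  dimnames(cells) <- list(format(k_values, trim = TRUE),
                          sprintf("%.2f", trephine_values))
  structure(
    list(k_values = as.numeric(k_values),
         trephine_values = as.numeric(trephine_values),
         cells = cells, kindex = kindex),
    class = "size_table"
  )
}

#' Generate the punch-size recommendation grid
#'
#' Builds the curvature-by-trephine table of recommended donor punch sizes:
#' each cell is the Descemet's membrane arc length for that keratometry and
#' trephine, rounded to 2 decimals. The defaults regenerate the published
#' clinical envelope (45--70 D in 1-D steps, 6.00--8.00 mm trephines in
#' 0.25-mm steps; 26 x 9 = 234 cells).
#'
#' @param k_values Recipient curvatures in diopters (default `45:70`).
#' @param trephine_values Trephine diameters in mm
#'   (default `seq(6, 8, by = 0.25)`).
#' @inheritParams diopters_to_radius
#' @return An object of class `size_table`: fields `k_values`,
#'   `trephine_values`, `cells` (matrix, mm, 2-decimal) and `kindex`.
#'   Rows and columns increase monotonically: steeper corneas and wider
#'   trephines both lengthen the membrane arc.
#' @examples
#' tab <- generate_size_table()
#' dim(tab$cells)                 # 26 x 9
#' tab$cells["45", "6.00"]        # 6.17
#' @export
generate_size_table <- function(k_values = 45:70,
                                trephine_values = seq(6, 8, by = 0.25),
                                kindex = KINDEX_DEFAULT) {
  if (length(k_values) == 0 || length(trephine_values) == 0) {
    stop("`k_values` and `trephine_values` must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(k_values) || anyDuplicated(trephine_values) ||
      is.unsorted(k_values) || is.unsorted(trephine_values)) {
    stop("`k_values` and `trephine_values` must be strictly increasing",
         call. = FALSE)
  }
  cells <- matrix(NA_real_, length(k_values), length(trephine_values))
  for (i in seq_along(k_values)) {
    for (j in seq_along(trephine_values)) {
      arc <- tryCatch(
        dm_arc_length(k_values[i], trephine_values[j], kindex, warn = FALSE),
        error = function(e) stop(sprintf(
          "cell (K = %g D, trephine = %g mm): %s",
          k_values[i], trephine_values[j], conditionMessage(e)),
          call. = FALSE)
      )
      cells[i, j] <- round_half_up(arc, 2)
    }
  }
  new_size_table(k_values, trephine_values, cells, kindex)
}

#' @export
print.size_table <- function(x, ...) {
  cat(sprintf(
    "Donor punch size table: %d curvatures x %d trephines (kindex = %g)\n",
    length(x$k_values), length(x$trephine_values), x$kindex))
  cat("Curvature (D) rows, trephine (mm) columns, punch sizes in mm:\n")
  print(x$cells)
  invisible(x)
}

#' Write a size table to delimited text or markdown
#'
#' Writes the grid with a header row of trephine sizes and a first column
#' (`K_D`) of curvatures; cells are fixed 2-decimal. The `csv`/`tsv`
#' dialects round-trip losslessly through [read_size_table()]; `markdown`
#' is export-only, for documentation.
#'
#' @param table A `size_table`.
#' @param path Output file path.
#' @param format One of `"csv"`, `"tsv"`, `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_size_table <- function(table, path, format = c("csv", "tsv", "markdown")) {
  stopifnot(inherits(table, "size_table"))
  format <- match.arg(format)
  trephs <- sprintf("%.2f", table$trephine_values)
  ks <- format(table$k_values, trim = TRUE)
  body <- matrix(sprintf("%.2f", table$cells), nrow = nrow(table$cells))
  lines <- switch(format,
    csv = ,
    tsv = {
      sep <- if (format == "csv") "," else "\t"
      c(paste(c("K_D", trephs), collapse = sep),
        vapply(seq_along(ks), function(i)
          paste(c(ks[i], body[i, ]), collapse = sep), character(1)))
    },
    markdown = {
      c(paste0("| K (D) | ", paste(trephs, collapse = " | "), " |"),
        paste0("|", paste(rep("---:", length(trephs) + 1), collapse = "|"), "|"),
        vapply(seq_along(ks), function(i)
          paste0("| ", ks[i], " | ", paste(body[i, ], collapse = " | "), " |"),
          character(1)))
    }
  )
  status <- tryCatch(writeLines(lines, path),
                     error = function(e) stop(sprintf(
                       "cannot write size table to '%s': %s",
                       path, conditionMessage(e)), call. = FALSE))
  invisible(path)
}

#' Read a size table from delimited text
#'
#' Parses the [write_size_table()] csv/tsv dialect: header `K_D` followed
#' by trephine sizes, one row per curvature. Ragged or non-numeric rows
#' are reported with their line number.
#'
#' @param path Input file path.
#' @param kindex Conversion constant to record on the result (metadata
#'   only; the cells are read, not recomputed).
#' @return A `size_table`.
#' @examples
#' ref <- read_size_table(system.file("extdata", "table1_reference.csv",
#'                                    package = "dalksizer"))
#' @export
read_size_table <- function(path, kindex = KINDEX_DEFAULT) {
  if (!file.exists(path)) {
    stop(sprintf("size table file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) {
    stop(sprintf("'%s': need a header and at least one data row", path),
         call. = FALSE)
  }
  sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  header <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  if (trimws(header[1]) != "K_D" || length(header) < 2) {
    stop(sprintf("'%s' line 1: header must start with 'K_D' followed by trephine sizes",
                 path), call. = FALSE)
  }
  trephs <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(trephs)) {
    stop(sprintf("'%s' line 1: non-numeric trephine size in header", path),
         call. = FALSE)
  }
  n_col <- length(header)
  ks <- numeric(length(lines) - 1)
  cells <- matrix(NA_real_, length(lines) - 1, length(trephs))
  for (i in seq_along(ks)) {
    fields <- strsplit(lines[i + 1], sep, fixed = TRUE)[[1]]
    if (length(fields) != n_col) {
      stop(sprintf("'%s' line %d: expected %d fields, found %d",
                   path, i + 1, n_col, length(fields)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop(sprintf("'%s' line %d: non-numeric cell", path, i + 1),
           call. = FALSE)
    }
    ks[i] <- vals[1]
    cells[i, ] <- round_half_up(vals[-1], 2)  # normalize 1-decimal entries
  }
  new_size_table(ks, trephs, cells, kindex)
}

#' Packaged reference transcription of the published table
#'
#' Loads the transcription of the printed recommendation table shipped
#' with the package (26 curvatures x 9 trephines). Cells printed at one
#' decimal in the source are normalized to 2 decimals on load.
#'
#' @return A `size_table`.
#' @export
reference_size_table <- function() {
  read_size_table(system.file("extdata", "table1_reference.csv",
                              package = "dalksizer", mustWork = TRUE))
}

#' Validate a generated table against a reference
#'
#' Cell-by-cell comparison of two tables over identical grids. The strict
#' default tolerance (0.005 mm) demands agreement at 2 printed decimals;
#' the relaxed tier (0.01 mm) tolerates cells that sit on a rounding
#' boundary, where half-up and half-even conventions differ by one unit
#' of the second decimal.
#'
#' @param generated,reference `size_table` objects on the same grid.
#' @param tolerance Maximum absolute deviation (mm) counted as a match;
#'   default 0.005 (strict), 0.01 is the documented relaxed tier.
#' @return An object of class `validation_report`: `n_cells`,
#'   `n_mismatched`, `max_abs_dev` (mm), `worst_cell` (named vector:
#'   curvature and trephine of the largest deviation) and `tolerance`.
#' @examples
#' rep <- validate_size_table(generate_size_table(), reference_size_table())
#' rep$n_mismatched   # 0
#' @export
validate_size_table <- function(generated, reference, tolerance = 0.005) {
  stopifnot(inherits(generated, "size_table"),
            inherits(reference, "size_table"))
  if (!isTRUE(all.equal(generated$k_values, reference$k_values)) ||
      !isTRUE(all.equal(generated$trephine_values, reference$trephine_values))) {
    stop("generated and reference tables are on different grids",
         call. = FALSE)
  }
  dev <- abs(generated$cells - reference$cells)
  worst <- which(dev == max(dev), arr.ind = TRUE)[1, ]
  structure(
    list(n_cells = length(dev),
         n_mismatched = sum(dev > tolerance),
         max_abs_dev = max(dev),
         worst_cell = c(K = generated$k_values[worst[1]],
                        trephine = generated$trephine_values[worst[2]]),
         tolerance = tolerance),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Table validation: %d/%d cells within %.3g mm\n",
              x$n_cells - x$n_mismatched, x$n_cells, x$tolerance))
  cat(sprintf("  max |deviation| = %.4f mm at (K = %g D, trephine = %.2f mm)\n",
              x$max_abs_dev, x$worst_cell["K"], x$worst_cell["trephine"]))
  invisible(x)
}
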