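#' Read a per-replicate SHAPE reactivity table
#'
#' Reads a tab-separated table with header columns `position`, `base`, then
#' one column per replicate (any names, typically `rep1`..`repN`). `NA` marks
#' an undetermined measurement; a position whose replicates are all `NA` is
#' undetermined. Reactivities are normalized SHAPE units and may be negative.
#'
#' @param path Path to the TSV file.
#' @param condition Optional one-row tibble from [shape_condition()]; its
#'   columns are attached to every row of the result.
#'
#' @return A long tibble with columns `position`, `base`, `replicate`,
#'   `reactivity` (NA where undetermined), one row per position x replicate,
#'   plus any condition columns. Positions are 1-based, unique and increasing.
#' @seealso [write_reactivity_table()], [aggregate_replicates()]
#' @export
read_reactivity_table <- function(path, condition = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Reactivity table not found: '%s'", path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) abort(sprintf("'%s' is empty.", path))
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 3L || header[1L] != "position" || header[2L] != "base") {
    abort(sprintf(
      "'%s': header must be 'position<TAB>base<TAB><replicate columns>'.", path
    ))
  }
  rep_names <- header[-(1:2)]
  n_col <- length(header)
  rows <- vector("list", length(lines) - 1L)
  for (i in seq_along(rows)) {
    lineno <- i + 1L
    fields <- strsplit(lines[[lineno]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != n_col) {
      abort(sprintf("'%s' line %d: expected %d fields, got %d.",
                    path, lineno, n_col, length(fields)))
    }
    pos <- suppressWarnings(as.integer(fields[1L]))
    if (is.na(pos) || pos < 1L) {
      abort(sprintf("'%s' line %d: malformed position '%s'.",
                    path, lineno, fields[1L]))
    }
    base <- toupper(trimws(fields[2L]))
    if (!base %in% c("A", "C", "G", "U")) {
      abort(sprintf("'%s' line %d: base must be one of A/C/G/U, got '%s'.",
                    path, lineno, fields[2L]))
    }
    vals <- fields[-(1:2)]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(num) & toupper(trimws(vals)) != "NA")
    if (length(bad)) {
      abort(sprintf("'%s' line %d: malformed reactivity '%s'.",
                    path, lineno, vals[bad[1L]]))
    }
    rows[[i]] <- list(position = pos, base = base, values = num,
                      lineno = lineno)
  }
  positions <- vapply(rows, `[[`, integer(1), "position")
  dup <- which(duplicated(positions))
  if (length(dup)) {
    abort(sprintf("'%s' line %d: duplicate position %d.",
                  path, rows[[dup[1L]]]$lineno, positions[dup[1L]]))
  }
  out <- tibble(
    position = rep(positions, each = length(rep_names)),
    base = rep(vapply(rows, `[[`, character(1), "base"),
               each = length(rep_names)),
    replicate = rep(rep_names, times = length(rows)),
    reactivity = unlist(lapply(rows, `[[`, "values"))
  )
  out <- dplyr::arrange(out, .data$position)
  if (!is.null(condition)) {
    out <- dplyr::bind_cols(out, condition[rep(1L, nrow(out)), , drop = FALSE])
  }
  out
}

#' Write a per-replicate reactivity table
#'
#' Inverse of [read_reactivity_table()]: writes the wide
#' `position base rep...` TSV, with `NA` for undetermined entries. Values are
#' written with full precision so a write/read round-trip is exact.
#'
#' @param reps Long replicate tibble (`position`, `base`, `replicate`,
#'   `reactivity`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reactivity_table <- function(reps, path) {
  check_replicate_tbl(reps)
  wide <- tidyr::pivot_wider(
    dplyr::select(reps, "position", "base", "replicate", "reactivity"),
    names_from = "replicate", values_from = "reactivity"
  )
  wide <- dplyr::arrange(wide, .data$position)
  readr::write_tsv(wide, path, na = "NA")
  invisible(path)
}

#' Export a SHAPE constraint/reactivity file
#'
#' Writes the two-column whitespace-separated `index reactivity` format read
#' by secondary-structure prediction software (the RNAstructure `.shape`
#' dialect). Undetermined positions are written as the sentinel `-999`.
#' Values are printed with 6 significant digits.
#'
#' @param x A tibble with a `position` column and a value column (`value` or
#'   `reactivity`), e.g. a constraint set from [make_pk_mask()] or an
#'   aggregated profile from [aggregate_replicates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_shape()]
#' @export
export_shape <- function(x, path) {
  if (!"position" %in% names(x)) abort("`x` must have a `position` column.")
  val_col <- intersect(c("value", "reactivity"), names(x))[1]
  if (is.na(val_col)) abort("`x` must have a `value` or `reactivity` column.")
  v <- x[[val_col]]
  if ("undetermined" %in% names(x)) v[x$undetermined] <- NA_real_
  txt <- ifelse(is.na(v), "-999", formatC(v, digits = 6, format = "g"))
  writeLines(sprintf("%d %s", as.integer(x$position), txt), path)
  invisible(path)
}

#' Read a SHAPE constraint/reactivity file
#'
#' @param path Path to a two-column `index value` file; `-999` is read as
#'   undetermined (`NA`).
#' @return A tibble with columns `position`, `value` (NA where `-999`).
#' @export
read_shape <- function(path) {
  if (!file.exists(path)) abort(sprintf("SHAPE file not found: '%s'", path))
  df <- utils::read.table(path, col.names = c("position", "value"))
  tibble(
    position = as.integer(df$position),
    value = ifelse(df$value == -999, NA_real_, df$value)
  )
}

check_replicate_tbl <- function(reps, arg = "reps") {
  need <- c("position", "base", "replicate", "reactivity")
  miss <- setdiff(need, names(reps))
  if (length(miss)) {
    abort(sprintf("`%s` lacks column(s): %s.", arg,
                  paste(miss, collapse = ", ")))
  }
  invisible(reps)
}
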