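#' Describe an experimental probing condition
#'
#' A condition is the combination of SHAPE reagent, magnesium concentration
#' and probing temperature under which a reactivity table was acquired. It is
#' returned as a one-row tibble so it can be joined onto, or bound into,
#' replicate tables and carried through the pipeline as ordinary columns.
#'
#' @param probe SHAPE reagent, one of `"1M7"`, `"NMIA"`, `"BzCN"`.
#' @param mg_mM MgCl2 concentration in mM (non-negative).
#' @param temperature_C Probing temperature in degrees Celsius, in `[0, 100]`.
#' @param label Optional free-text label for the condition.
#'
#' @return A one-row tibble with columns `probe`, `mg_mM`, `temperature_C`,
#'   `label`.
#' @examples
#' shape_condition("1M7", mg_mM = 5, temperature_C = 37)
#' @export
shape_condition <- function(probe = c("1M7", "NMIA", "BzCN"), mg_mM = 5,
                            temperature_C = 37, label = NULL) {
  probe <- match.arg(probe)
  if (!is.numeric(mg_mM) || length(mg_mM) != 1L || is.na(mg_mM) || mg_mM < 0) {
    abort("`mg_mM` must be a single non-negative number.")
  }
  if (!is.numeric(temperature_C) || length(temperature_C) != 1L ||
      is.na(temperature_C) || temperature_C < 0 || temperature_C > 100) {
    abort("`temperature_C` must be a single number in [0, 100].")
  }
  label <- label %||% sprintf("%s_%gmM_%gC", probe, mg_mM, temperature_C)
  tibble(probe = probe, mg_mM = mg_mM, temperature_C = temperature_C,
         label = label)
}

# Columns that identify a condition when present in a table.
condition_cols <- function(df) {
  intersect(c("probe", "mg_mM", "temperature_C", "label"), names(df))
}
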