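#' qPCR relative expression by the delta-CT method
#'
#' `2^(CT_housekeeping - CT_target) * 1e4`, with Gapdh as the conventional
#' housekeeping gene. Equal CTs return exactly 1e4.
#'
#' @param ct_target,ct_housekeeping Threshold-cycle values (finite, > 0);
#'   vectors are recycled element-wise.
#' @return Relative expression value(s).
#' @export
relative_expression <- function(ct_target, ct_housekeeping) {
  if (!is.numeric(ct_target) || !is.numeric(ct_housekeeping) ||
      !all(is.finite(ct_target)) || !all(is.finite(ct_housekeeping)) ||
      any(ct_target <= 0) || any(ct_housekeeping <= 0)) {
    stop("CT values must be finite and > 0", call. = FALSE)
  }
  2^(ct_housekeeping - ct_target) * 1e4
}

#' Fold increase of a case group over a control group
#'
#' Ratio of unpaired arithmetic group means, as used to report
#' commensal-associated relative to unassociated animals.
#'
#' @param values_case,values_control Numeric vectors of per-sample relative
#'   expression values.
#' @return `mean(values_case) / mean(values_control)`.
#' @export
fold_increase <- function(values_case, values_control) {
  stopifnot(is.numeric(values_case), is.numeric(values_control),
            length(values_control) >= 1L, length(values_case) >= 1L)
  mc <- mean(values_control)
  if (!is.finite(mc) || mc <= 0) stop("control mean must be > 0",
                                      call. = FALSE)
  mean(values_case) / mc
}

#' Integrated mean fluorescence intensity
#'
#' `iMFI = frequency * MFI`, reflecting the total response of a population.
#' The frequency is on the percent-of-parent-gate scale (0-100); this scale
#' choice matters, since the product is 100-fold smaller on the fraction
#' scale.
#'
#' @param frequency_percent Population frequency, percent of parent (0-100).
#' @param mfi Median/mean fluorescence intensity (arbitrary units, >= 0).
#' @return iMFI value(s).
#' @export
imfi <- function(frequency_percent, mfi) {
  stopifnot(is.numeric(frequency_percent), is.numeric(mfi),
            all(frequency_percent >= 0), all(frequency_percent <= 100),
            all(mfi >= 0))
  frequency_percent * mfi
}

#' Read a CT table
#'
#' Tab-separated with columns `sample`, `group`, `target`, `ct_target`,
#' `ct_housekeeping`.
#'
#' @param text Table text, lines, or a file path.
#' @return Data frame.
#' @export
read_ct_table <- function(text) {
  df <- utils::read.delim(text = paste(read_text_lines(text), collapse = "\n"),
                          stringsAsFactors = FALSE)
  required <- c("sample", "group", "target", "ct_target", "ct_housekeeping")
  if (!all(required %in% names(df))) {
    stop("CT table needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Per-sample relative expression and per-target fold increase
#'
#' Applies [relative_expression()] row-wise, then [fold_increase()] per
#' target between a case and a control group.
#'
#' @param ct_table Data frame from [read_ct_table()].
#' @param case_group,control_group Group labels to contrast.
#' @return List with `values` (the input plus a `value` column) and
#'   `fold_increase` (data frame `target`, `fold_increase`).
#' @export
summarize_ct_table <- function(ct_table, case_group, control_group) {
  ct_table$value <- relative_expression(ct_table$ct_target,
                                        ct_table$ct_housekeeping)
  targets <- unique(ct_table$target)
  fi <- vapply(targets, function(tg) {
    sel <- ct_table$target == tg
    fold_increase(ct_table$value[sel & ct_table$group == case_group],
                  ct_table$value[sel & ct_table$group == control_group])
  }, numeric(1))
  list(values = ct_table,
       fold_increase = data.frame(target = targets, fold_increase = fi,
                                  row.names = NULL,
                                  stringsAsFactors = FALSE))
}

#' Read a flow-cytometry frequency/MFI table
#'
#' Tab-separated with columns `population`, `frequency` (percent of parent,
#' 0-100) and `mfi`.
#'
#' @param text Table text, lines, or a file path.
#' @return Data frame.
#' @export
read_flow_table <- function(text) {
  df <- utils::read.delim(text = paste(read_text_lines(text), collapse = "\n"),
                          stringsAsFactors = FALSE)
  required <- c("population", "frequency", "mfi")
  if (!all(required %in% names(df))) {
    stop("flow table needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Append the iMFI column to a flow table
#'
#' @param flow_table Data frame from [read_flow_table()].
#' @return The table with an `imfi` column.
#' @export
add_imfi <- function(flow_table) {
  flow_table$imfi <- imfi(flow_table$frequency, flow_table$mfi)
  flow_table
}
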