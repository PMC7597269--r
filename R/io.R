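#' Read a wide-format time-series table
#'
#' Reads a CSV or TSV file (extension-detected; header row required) with
#' one column per series and optional date column. Row order is preserved;
#' missing or non-numeric cells are rejected with a row-indexed error — no
#' imputation is ever performed.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @param columns Optional character vector of series columns to keep
#'   (default: all columns except `date_column`).
#' @param date_column Optional name of a date/index column, carried through
#'   untouched as the first output column.
#' @return A tibble.
#' @export
read_series <- function(path, columns = NULL, date_column = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "fbsts_invalid_input")
  }
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) < 3L) {
    abort("Need at least 3 data rows.", class = "fbsts_invalid_input")
  }
  keep <- columns %||% setdiff(names(df), date_column)
  missing_cols <- setdiff(c(keep, date_column), names(df))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Column(s) %s not found; available: %s.",
                  paste(missing_cols, collapse = ", "),
                  paste(names(df), collapse = ", ")),
          class = "fbsts_invalid_input")
  }
  for (cn in keep) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "NA")
      if (length(bad) > 0L) {
        abort(sprintf("Non-numeric cell in column '%s' at row %d.",
                      cn, bad[[1L]]),
              class = "fbsts_invalid_input")
      }
      v <- vn
    }
    nas <- which(is.na(v))
    if (length(nas) > 0L) {
      abort(sprintf("Missing value in column '%s' at row %d.", cn, nas[[1L]]),
            class = "fbsts_invalid_input")
    }
    df[[cn]] <- v
  }
  as_tibble(df[, c(date_column, keep), drop = FALSE])
}

#' Serialize a fitted FBST test to a structured report
#'
#' `as_report()` turns a fitted [fbst_unit_root()] or [fbst_coint()] object
#' into a plain list ready for JSON serialization; `write_report()` writes
#' it to disk with full floating-point precision. The report embeds the
#' resolved configuration (including the seed) so any run can be reproduced
#' from its output alone.
#'
#' @param x A fitted `fbst_ur` or `fbst_coint` object.
#' @param path Output path for the JSON file.
#' @return `as_report()`: a named list. `write_report()`: `path`, invisibly.
#' @export
as_report <- function(x) {
  UseMethod("as_report")
}

#' @export
as_report.fbst_ur <- function(x) {
  ev <- x$evidence
  list(
    version = as.character(utils::packageVersion("fbsts")),
    test = "unit_root",
    config = x$settings,
    estimates = list(
      psi_hat = as.list(x$psi_hat),
      psi_hat_restricted = as.list(x$psi_hat_restricted),
      sigma2_hat_restricted = x$sigma2_hat_restricted,
      adf_tstat = x$adf_tstat
    ),
    evidence = list(
      hypothesis = ev$hypothesis,
      log_s_star = ev$log_s_star,
      ev_bar = ev$ev_bar,
      ev = ev$ev,
      mc_se = ev$mc_se,
      n_draws = ev$n_draws,
      seed = x$settings$seed
    ),
    prob_nonstationary = x$prob_nonstationary
  )
}

#' @export
as_report.fbst_coint <- function(x) {
  pr <- x$per_rank
  list(
    version = as.character(utils::packageVersion("fbsts")),
    test = "cointegration_rank",
    config = x$settings,
    eigenvalues = x$eigenvalues,
    per_rank = lapply(seq_len(nrow(pr)), function(i) as.list(pr[i, ])),
    dimension_counts = lapply(seq_len(nrow(pr)), function(i) {
      list(rank = pr$rank[[i]], m = pr$m[[i]], h = pr$h[[i]])
    })
  )
}

#' @rdname as_report
#' @export
write_report <- function(x, path) {
  report <- as_report(x)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Calibrate an e-value threshold from a p-value (and back)
#'
#' Tidy wrapper over [ev_from_pvalue()] / [pvalue_from_ev()]: supply either
#' `p` or `ev` together with the parameter-space dimensions and get the full
#' correspondence as a tibble.
#'
#' @param m,h Parameter-space dimensions (see [coint_dims()]).
#' @param p,ev Exactly one of these; vectorized.
#' @return Tibble with columns `m`, `h`, `p`, `ev`.
#' @examples
#' fbst_calibrate(m = 58, h = 42, p = 0.01)
#' @export
fbst_calibrate <- function(m, h, p = NULL, ev = NULL) {
  if (is.null(p) == is.null(ev)) {
    abort("Supply exactly one of `p` or `ev`.", class = "fbsts_invalid_input")
  }
  if (is.null(ev)) {
    ev <- ev_from_pvalue(p, m, h)
  } else {
    p <- pvalue_from_ev(ev, m, h)
  }
  tibble(m = m, h = h, p = p, ev = ev)
}
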