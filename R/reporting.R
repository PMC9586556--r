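REPORT_SCHEMA_VERSION <- "1.0"

#' Structured analysis record
#'
#' Flattens an [eoi()] fit into a plain nested list suitable for lossless
#' JSON serialisation: inputs, significance, conic coefficients, nearest
#' point, intercepts, tolerance metrics, optional miscoding verdict, flags
#' and provenance (schema and package version).
#'
#' @param fit An `eoi` fit.
#' @return A named list (schema version `"1.0"`).
#' @export
eoi_record <- function(fit) {
  stopifnot(inherits(fit, "eoi"))
  tab <- fit$table
  rec <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("eoi")),
    input = list(a = tab$a, b = tab$b, c = tab$c, d = tab$d, n = tab$n,
                 alpha = fit$alpha, inverted = fit$inverted),
    significance = list(chi_squared = fit$statistic, nu_c = fit$nu_c,
                        significant = fit$significant),
    coefficients = as.list(fit$coefficients$coef),
    feckup = list(x_e = fit$feckup$x_e, y_e = fit$feckup$y_e,
                  f_min = fit$feckup$f_min, d_min = fit$feckup$d_min,
                  residual = fit$feckup$residual,
                  feasible = fit$feckup$feasible,
                  degenerate = fit$feckup$degenerate),
    intercepts = list(x_i = fit$intercepts$x_i, y_i = fit$intercepts$y_i),
    epsilon = list(E = fit$epsilon$epsilon_E, C = fit$epsilon$epsilon_C,
                   A = fit$epsilon$epsilon_A,
                   E_int = fit$epsilon$epsilon_E_int,
                   C_int = fit$epsilon$epsilon_C_int),
    flags = as.list(fit$flags)
  )
  if (!is.null(fit$miscoding)) {
    rec$miscoding <- list(x_m = fit$miscoding$x_m, y_m = fit$miscoding$y_m,
                          sens_exp = fit$miscoding$sens_exp,
                          spec_exp = fit$miscoding$spec_exp,
                          sens_ctl = fit$miscoding$sens_ctl,
                          spec_ctl = fit$miscoding$spec_ctl,
                          verdict = fit$verdict)
  }
  rec
}

#' Write / read analysis records as JSON
#'
#' Full double precision is retained (`digits = NA`), so a written record
#' reads back with every numeric field identical to within 1e-12.
#'
#' @param record A record from [eoi_record()] (or a list of them).
#' @param path File path.
#' @return `eoi_write_json` returns `path` invisibly; `eoi_read_json`
#'   returns the parsed record list.
#' @export
eoi_write_json <- function(record, path) {
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname eoi_write_json
#' @export
eoi_read_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}

# header-based dialect sniffing: tab wins if the header contains one
detect_sep <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) return(",")
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Batch analysis of delimited tables
#'
#' Reads a comma- or tab-delimited file (dialect auto-detected from the
#' header) with required columns `a,b,c,d` and optional per-row `alpha`,
#' `sens_exp`, `spec_exp`, `sens_ctl`, `spec_ctl` (aliases `sn_e`, `sp_e`,
#' `sn_c`, `sp_c` accepted), runs the full analysis on each row and returns
#' the fits with a one-row-per-table summary. Malformed rows (missing or
#' negative counts, empty margins, invalid alpha) are skipped with a
#' diagnostic naming the file line, or abort the run in strict mode. A
#' data frame can be passed directly in place of a path.
#'
#' @param path File path, or a data frame with the same columns.
#' @param alpha Default significance level for rows without their own.
#' @param strict Abort on the first malformed row instead of skipping it.
#' @return List with `records` (list of `eoi` fits, named by input line) and
#'   `summary` (data frame, one row per analysed table).
#' @export
eoi_batch <- function(path, alpha = 0.05, strict = FALSE) {
  if (is.data.frame(path)) {
    df <- path
    lines <- seq_len(nrow(df)) + 1L  # as if under a header
  } else {
    if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
    sep <- detect_sep(path)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    lines <- seq_len(nrow(df)) + 1L
  }
  alias <- c(sn_e = "sens_exp", sp_e = "spec_exp",
             sn_c = "sens_ctl", sp_c = "spec_ctl")
  for (nm in names(alias))
    if (nm %in% names(df) && !(alias[[nm]] %in% names(df)))
      names(df)[names(df) == nm] <- alias[[nm]]
  required <- c("a", "b", "c", "d")
  if (!all(required %in% names(df)))
    stop("missing required column(s): ",
         paste(setdiff(required, names(df)), collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) {
    warning("no data rows in input")
    return(list(records = list(), summary = data.frame()))
  }
  records <- list()
  rows <- list()
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    res <- tryCatch({
      al <- if ("alpha" %in% names(row) && !is.na(row$alpha)) row$alpha else alpha
      has_test <- "sens_exp" %in% names(row) && !is.na(row$sens_exp) &&
        "spec_exp" %in% names(row) && !is.na(row$spec_exp)
      if (has_test) {
        ctl <- "sens_ctl" %in% names(row) && !is.na(row$sens_ctl) &&
          "spec_ctl" %in% names(row) && !is.na(row$spec_ctl)
        eoi(row$a, row$b, row$c, row$d, alpha = al,
            sens_exp = row$sens_exp, spec_exp = row$spec_exp,
            sens_ctl = if (ctl) row$sens_ctl else row$sens_exp,
            spec_ctl = if (ctl) row$spec_ctl else row$spec_exp)
      } else {
        eoi(row$a, row$b, row$c, row$d, alpha = al)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msg <- sprintf("line %d skipped: %s", lines[i], conditionMessage(res))
      if (strict) stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
    } else {
      records[[as.character(lines[i])]] <- res
      rows[[length(rows) + 1L]] <- cbind(line = lines[i], as.data.frame(res))
    }
  }
  list(records = records,
       summary = if (length(rows)) do.call(rbind, rows) else data.frame())
}

#' Export plot-ready geometry as delimited text
#'
#' Writes four tab-separated files sharing a path prefix:
#' `<prefix>_boundary.tsv` (parametric ellipse samples), `<prefix>_feckup.tsv`
#' (origin and nearest-point segment endpoints), `<prefix>_intercepts.tsv`
#' (axis crossings) and `<prefix>_polygon.tsv` (outer integer polygon
#' vertices), suitable for external plotting.
#'
#' @param fit An `eoi` fit for a significant table.
#' @param prefix Output path prefix.
#' @param n_points Number of boundary samples (default 360).
#' @return Character vector of the written paths, invisibly.
#' @export
export_geometry <- function(fit, prefix, n_points = 360L) {
  stopifnot(inherits(fit, "eoi"))
  if (!fit$significant)
    stop("table not significant: no ellipse geometry to export", call. = FALSE)
  paths <- paste0(prefix, c("_boundary.tsv", "_feckup.tsv",
                            "_intercepts.tsv", "_polygon.tsv"))
  wt <- function(df, p) utils::write.table(
    df, p, sep = "\t", row.names = FALSE, quote = FALSE)
  wt(as.data.frame(ellipse_boundary(fit$coefficients, n_points)), paths[1])
  wt(data.frame(point = c("origin", "feckup"),
                x = c(0, fit$feckup$x_e), y = c(0, fit$feckup$y_e),
                f_min = c(NA, fit$feckup$f_min)), paths[2])
  wt(data.frame(axis = c("x", "y"),
                value = c(fit$intercepts$x_i, fit$intercepts$y_i)), paths[3])
  wt(as.data.frame(polygon_of_insignificance(fit$table, fit$alpha)), paths[4])
  invisible(paths)
}
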