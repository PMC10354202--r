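#' Write an extension trace as tabular text
#'
#' Plain-text format: leading '#' comment lines carry provenance
#' (key: value), then a header line naming the columns \code{time_s},
#' \code{extension_nm}, \code{force_pN}, then tab-separated rows. Values are
#' written with 15 significant digits so a write/read round trip is lossless
#' at double precision.
#'
#' @param trace An \code{extension_trace}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "extension_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  prov <- trace$provenance
  writeLines(c(sprintf("# rate_hz: %.15g", trace$rate_hz),
               sprintf("# noise_sd: %.15g",
                       if (is.null(prov$noise_sd)) NA else prov$noise_sd),
               sprintf("# seed: %s",
                       if (is.null(prov$seed)) "NA" else prov$seed),
               "time_s\textension_nm\tforce_pN"), con)
  writeLines(sprintf("%.15g\t%.15g\t%.15g",
                     trace$time_s, trace$extension_nm, trace$force_pN), con)
  invisible(path)
}

#' Read an extension trace from tabular text
#'
#' Columns are matched by header name, so column order is free. Malformed
#' rows and non-monotone time raise errors naming the offending line.
#'
#' @param path Input file path.
#' @return An \code{extension_trace}.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  prov <- list()
  for (cl in lines[is_comment]) {
    m <- regmatches(cl, regexec("^#\\s*([^:]+):\\s*(.*)$", cl))[[1L]]
    if (length(m) == 3L) {
      v <- suppressWarnings(as.numeric(m[3L]))
      prov[[trimws(m[2L])]] <- if (is.na(v)) m[3L] else v
    }
  }
  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (length(body_idx) < 2L) stop("no data rows in ", path)
  header <- strsplit(trimws(lines[body_idx[1L]]), "[\t ,]+")[[1L]]
  need <- c("time_s", "extension_nm", "force_pN")
  missing_cols <- setdiff(need, header)
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  data_idx <- body_idx[-1L]
  rows <- strsplit(trimws(lines[data_idx]), "[\t ,]+")
  nfield <- lengths(rows)
  bad <- which(nfield != length(header))
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s (expected %d fields, got %d)",
                 data_idx[bad[1L]], path, length(header), nfield[bad[1L]]))
  mat <- matrix(suppressWarnings(as.numeric(unlist(rows))),
                ncol = length(header), byrow = TRUE)
  nas <- which(rowSums(is.na(mat)) > 0)
  if (length(nas))
    stop(sprintf("non-numeric value at line %d of %s", data_idx[nas[1L]], path))
  colnames(mat) <- header
  t <- mat[, "time_s"]
  nonmono <- which(diff(t) <= 0)
  if (length(nonmono))
    stop(sprintf("non-monotone time at line %d of %s",
                 data_idx[nonmono[1L] + 1L], path))
  rate <- if (!is.null(prov$rate_hz)) prov$rate_hz else 1 / stats::median(diff(t))
  structure(list(time_s = t, extension_nm = mat[, "extension_nm"],
                 force_pN = mat[, "force_pN"], rate_hz = rate,
                 provenance = prov),
            class = "extension_trace")
}

#' Write a dwell/event table as tabular text
#' @param dwells A \code{dwell_table} (data frame).
#' @param path Output file path.
#' @param comments Optional named list written as '# key: value' provenance.
#' @return \code{path}, invisibly.
#' @export
write_dwell_table <- function(dwells, path, comments = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(comments))
    writeLines(sprintf("# %s: %s", k, comments[[k]]), con)
  utils::write.table(dwells, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a dwell/event table from tabular text
#' @param path Input file path.
#' @return A \code{dwell_table} data frame (requires columns \code{state},
#'   \code{dwell_s}, \code{censored}).
#' @export
read_dwell_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("state", "dwell_s", "censored")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  class(df) <- c("dwell_table", "data.frame")
  df
}

#' Read a flat key-value configuration file
#'
#' One scalar per line, \code{key = value}; '#' starts a comment. Units are
#' carried in key names (e.g. \code{k0_per_s}, \code{x_dagger_nm},
#' \code{temperature_K}). Numeric-looking values are converted.
#'
#' @param path Input file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    kv <- strsplit(lines[i], "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", lines[i])
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (is.na(num)) val else num
  }
  out
}

#' Write a flat key-value configuration file
#' @param config Named list of scalars.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(!is.null(names(config)), all(nzchar(names(config))))
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, if (is.numeric(v)) sprintf("%.15g", v) else
      as.character(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Bell-Evans parameters from a flat config
#'
#' Reads keys \code{<prefix>k0_per_s}, \code{<prefix>x_dagger_nm},
#' \code{<prefix>sense} from a config list.
#'
#' @param config Named list (from [read_config()]).
#' @param prefix Key prefix, e.g. \code{"flv_unbind_"}.
#' @return A \code{bell_evans_params}.
#' @export
bell_evans_from_config <- function(config, prefix = "") {
  k <- function(x) paste0(prefix, x)
  need <- c(k("k0_per_s"), k("x_dagger_nm"), k("sense"))
  missing_keys <- setdiff(need, names(config))
  if (length(missing_keys))
    stop("missing config key(s): ", paste(missing_keys, collapse = ", "))
  bell_evans_params(config[[k("k0_per_s")]], config[[k("x_dagger_nm")]],
                    config[[k("sense")]])
}
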