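#' Read spectra from a long-format delimited table
#'
#' The canonical exchange format is a UTF-8 CSV with one row per measured
#' point and columns `condition_kind`, `condition_value`, `spot`,
#' `wavelength_nm`, `intensity` ('.' decimal separator). Rows are grouped
#' into spectra by `(condition_value, spot)` and validated: wavelengths must
#' be strictly increasing within a spectrum, intensities nonnegative, and all
#' spectra must share one wavelength grid.
#'
#' @param path Path to the table.
#' @param dialect `"csv"` (comma separated, default) or `"tsv"` (tab).
#' @return A [spectrum_set].
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_spectra: file not found: ", path, call. = FALSE)
  sep <- if (dialect == "csv") "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   colClasses = NA, encoding = "UTF-8")
  required <- c("condition_kind", "condition_value", "spot", "wavelength_nm",
                "intensity")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("read_spectra: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!nrow(df)) return(spectrum_set(list()))
  neg <- which(df$intensity < 0)
  if (length(neg)) {
    r <- df[neg[1L], ]
    stop(sprintf(
      "read_spectra: negative intensity at condition=%s, spot=%s, wavelength=%g nm",
      format(r$condition_value), r$spot, r$wavelength_nm), call. = FALSE)
  }
  key <- paste(format(df$condition_value, digits = 15), df$spot, sep = "\r")
  groups <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  spectra <- lapply(groups, function(idx) {
    g <- df[idx, ]
    if (any(diff(g$wavelength_nm) <= 0))
      stop(sprintf(
        "read_spectra: wavelengths not strictly increasing for condition=%s, spot=%s",
        format(g$condition_value[1L]), g$spot[1L]), call. = FALSE)
    spectrum(g$wavelength_nm, g$intensity, g$condition_kind[1L],
             g$condition_value[1L], g$spot[1L])
  })
  names(spectra) <- NULL
  spectrum_set(spectra)
}

#' Write a spectrum set to a long-format delimited table
#'
#' Inverse of [read_spectra()]: values round-trip at full double precision.
#'
#' @param set A [spectrum_set] (all spectra on the wavelength axis).
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_spectra <- function(set, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(set, "spectrum_set"))
  if (length(set$spectra) &&
      any(vapply(set$spectra, `[[`, "", "axis") != "wavelength"))
    stop("write_spectra: all spectra must be on the wavelength axis", call. = FALSE)
  sep <- if (dialect == "csv") "," else "\t"
  if (!length(set$spectra)) {
    writeLines(paste(c("condition_kind", "condition_value", "spot",
                       "wavelength_nm", "intensity"), collapse = sep), path)
    return(invisible(path))
  }
  rows <- lapply(set$spectra, function(s) {
    data.frame(condition_kind = s$condition_kind,
               condition_value = s$condition_value,
               spot = s$spot,
               wavelength_nm = s$wavelength,
               intensity = s$intensity,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  # 17 significant digits: lossless double round trip
  df$condition_value <- formatC(df$condition_value, digits = 17, format = "g")
  df$wavelength_nm <- formatC(df$wavelength_nm, digits = 17, format = "g")
  df$intensity <- formatC(df$intensity, digits = 17, format = "g")
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
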