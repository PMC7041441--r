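#' Write a three-channel image stack as multi-page TIFF
#'
#' One 16-bit unsigned page per cube image (`I^DD`, `I^DA`, `I^AA`), with an
#' optional JSON sidecar (`<path>.json`) carrying ground truth and scene
#' parameters.  Counts must not exceed 65535.
#'
#' @param img array `height x width x 3` of counts (e.g.
#'   `synth_image()$counts`).
#' @param path output TIFF path.
#' @param sidecar optional list serialized to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_fret_tiff <- function(img, path, sidecar = NULL) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  if (max(img) > 65535) stop("counts exceed the 16-bit range")
  pages <- lapply(1:3, function(k)
    matrix(img[, , k], dim(img)[1], dim(img)[2]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  if (!is.null(sidecar))
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' Read a three-channel TIFF stack written by [write_fret_tiff()]
#'
#' @param path TIFF path (three 16-bit pages, or one page with three
#'   channels).
#' @return Array `height x width x 3` of counts.
#' @export
read_fret_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) == 1 && length(dim(pages[[1]])) == 3 &&
      dim(pages[[1]])[3] >= 3) {
    x <- pages[[1]]
    pages <- lapply(1:3, function(k) x[, , k])
  }
  if (length(pages) < 3) stop("expected three pages/channels (DD, DA, AA)")
  arr <- array(0, dim = c(dim(pages[[1]]), 3),
               dimnames = list(NULL, NULL, c("i_dd", "i_da", "i_aa")))
  for (k in 1:3) arr[, , k] <- round(pages[[k]] * 65535)
  arr
}

#' Write a curve table with a parameter echo
#'
#' Writes a data frame as CSV and a JSON echo of the full parameter set
#' alongside it (`<path>.json`), so every artifact is reproducible from its
#' sidecar.
#'
#' @param df data frame (e.g. from [sigma_sweep()] or [tcspc_sweep()]).
#' @param path output CSV path.
#' @param params named list echoed to the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(df, path, params = list()) {
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(c(list(file = basename(path)), params),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Flat key-value configuration files
#'
#' Reads/writes `key = value` lines (comments with `#`); values are parsed
#' as numbers where possible.  Every CLI flag has a corresponding config
#' key, and CLI flags override config values.
#'
#' @param path config file path.
#' @return `read_config()`: named list; `write_config()`: `path`,
#'   invisibly.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' @rdname read_config
#' @param config named list of scalar values.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste(k, "=", format(config[[k]], scientific = FALSE)), "")
  writeLines(lines, path)
  invisible(path)
}
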