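#' Read cytometry event data
#'
#' Reads an events-by-channels table from an FCS 3.0/3.1 file or from a
#' delimited text file with a header row. One row per cell (event), one column
#' per channel; values pass through untransformed (no compensation, no
#' logicle), matching the convention that preprocessing is the caller's
#' responsibility. A user-supplied transform can be applied on read.
#'
#' @param path Path to the input file.
#' @param format `"fcs"` or `"csv"` (`"csv"` also accepts tab-delimited files).
#' @param transform Optional function applied to the numeric event matrix
#'   before it is returned (e.g. an asinh or logicle transform).
#' @return A tibble with one row per event and one numeric column per channel.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("c1,c2", "0,0", "3,4"), path)
#' read_events(path, format = "csv")
#' @export
read_events <- function(path, format = c("csv", "fcs"), transform = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("cannot read '%s': no such file", path))
  tbl <- if (format == "fcs") read_fcs(path) else read_events_csv(path)
  if (nrow(tbl) == 0) abort(sprintf("'%s' contains zero events", path))
  if (!is.null(transform)) {
    m <- transform(as_cloud_matrix(tbl))
    tbl <- tibble::as_tibble(as.data.frame(m))
  }
  tbl
}

read_events_csv <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  out <- raw
  for (j in seq_along(raw)) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]))
    if (length(bad) > 0) {
      abort(sprintf(
        "non-numeric value '%s' at row %d, column '%s' of '%s'",
        raw[[j]][bad[1]], bad[1], names(raw)[j], path))
    }
    out[[j]] <- v
  }
  out
}

#' Subsample events without replacement
#'
#' Uniformly selects `n` distinct rows; deterministic for a fixed seed (its
#' own substream of the master seed, so downstream stages are unaffected).
#'
#' @param data Events-by-channels table or matrix.
#' @param n Number of events to keep (`1 <= n <= nrow(data)`).
#' @param seed Master seed.
#' @return A tibble of `n` events.
#' @export
subsample_points <- function(data, n, seed = 1L) {
  m <- as_cloud_matrix(data)
  if (n < 1 || n > nrow(m)) {
    abort(sprintf("`n` must be between 1 and %d, got %s", nrow(m), n))
  }
  idx <- withr::with_seed(substream_seed(seed, "subsample"),
                          sample.int(nrow(m), n, replace = FALSE))
  tibble::as_tibble(as.data.frame(m[idx, , drop = FALSE]))
}

#' Write / read a low-dimensional embedding as CSV
#'
#' The CSV has the coordinate columns (`x`, `y`\[, `z`\]) plus a `role`
#' column tagging each row (e.g. `"placed"`, `"community_centroid"`).
#'
#' @param points A data frame with coordinate columns and optionally a
#'   `role` column (added as `"placed"` when absent).
#' @param path Output path.
#' @return `path`, invisibly (`write_embedding`); a tibble (`read_embedding`).
#' @export
write_embedding <- function(points, path) {
  pts <- tibble::as_tibble(points)
  if (nrow(pts) == 0) abort("embedding table must be non-empty")
  if (!"role" %in% names(pts)) pts$role <- "placed"
  readr::write_csv(pts, path)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    role = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
}

#' Write a run report
#'
#' Serializes run configuration, the grid scale factor, and per-pair plus
#' summary distortions as structured JSON text.
#'
#' @param report A list, typically containing a [distortion_summary()] result
#'   and run metadata.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "distortion_report")) {
    report <- list(pairs = tidy(report), summary = as.list(glance(report)))
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Minimal FCS 3.0 support: primary TEXT + DATA segment, list mode, datatype
# F (float32), D (float64) or I (unsigned integer, 16/32 bit), both byte
# orders. Compensation/spillover and additional data sets are out of scope.

read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58L))
  if (!startsWith(header, "FCS3")) {
    abort(sprintf("'%s' is not an FCS 3.x file (header '%s')",
                  path, substr(header, 1, 6)))
  }
  off <- function(i) {
    as.integer(trimws(substr(header, 11 + (i - 1) * 8, 10 + i * 8)))
  }
  text_beg <- off(1); text_end <- off(2)
  data_beg <- off(3); data_end <- off(4)
  seek(con, text_beg)
  text <- rawToChar(readBin(con, "raw", text_end - text_beg + 1L))
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- setNames(parts[seq(2, length(parts), 2)],
                 toupper(trimws(parts[seq(1, length(parts), 2)])))
  if (is.na(data_beg) || data_beg == 0) data_beg <- as.integer(kw[["$BEGINDATA"]])
  if (is.na(data_end) || data_end == 0) data_end <- as.integer(kw[["$ENDDATA"]])
  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  dtype <- toupper(kw[["$DATATYPE"]])
  mode <- toupper(kw[["$MODE"]])
  if (!identical(mode, "L")) abort("only list-mode ($MODE L) FCS data is supported")
  endian <- if (identical(kw[["$BYTEORD"]], "4,3,2,1")) "big" else "little"
  bits <- vapply(seq_len(n_par), function(p) {
    as.integer(kw[[sprintf("$P%dB", p)]])
  }, integer(1))
  names <- vapply(seq_len(n_par), function(p) {
    key <- sprintf("$P%dN", p)
    if (key %in% names(kw)) kw[[key]] else sprintf("P%d", p)
  }, character(1))
  seek(con, data_beg)
  n_val <- n_par * n_tot
  vals <- switch(dtype,
    F = readBin(con, "numeric", n_val, size = 4L, endian = endian),
    D = readBin(con, "numeric", n_val, size = 8L, endian = endian),
    I = {
      if (length(unique(bits)) != 1 || !bits[1] %in% c(16L, 32L)) {
        abort("integer FCS data requires uniform $PnB of 16 or 32")
      }
      readBin(con, "integer", n_val, size = bits[1] / 8L,
              signed = bits[1] == 32L, endian = endian)
    },
    abort(sprintf("unsupported $DATATYPE '%s'", dtype))
  )
  mat <- matrix(as.numeric(vals), nrow = n_tot, ncol = n_par, byrow = TRUE)
  colnames(mat) <- names
  tibble::as_tibble(as.data.frame(mat))
}

#' Write a minimal FCS 3.0 file
#'
#' Fixture-grade writer: list mode, float32 data, little-endian. Intended for
#' round-trip tests of [read_events()], not for interchange with analyzers.
#'
#' @param data Events-by-channels table or matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(data, path) {
  m <- as_cloud_matrix(data)
  n_tot <- nrow(m); n_par <- ncol(m)
  d <- "/"
  par_kw <- unlist(lapply(seq_len(n_par), function(p) {
    c(sprintf("$P%dN", p), colnames(m)[p],
      sprintf("$P%dB", p), "32",
      sprintf("$P%dE", p), "0,0",
      sprintf("$P%dR", p), format(max(1, ceiling(max(m[, p]) + 1)),
                                  scientific = FALSE))
  }))
  make_text <- function(beg, end) {
    kv <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
            "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
            "$BEGINDATA", sprintf("%010d", beg),
            "$ENDDATA", sprintf("%010d", end),
            "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
            "$NEXTDATA", "0",
            "$PAR", as.character(n_par), "$TOT", as.character(n_tot),
            par_kw)
    paste0(d, paste(kv, collapse = d), d)
  }
  text_beg <- 58L
  text_len <- nchar(make_text(0L, 0L)) # offsets are fixed-width, length stable
  text_end <- text_beg + text_len - 1L
  data_beg <- text_end + 1L
  data_end <- data_beg + 4L * n_tot * n_par - 1L
  text <- make_text(data_beg, data_end)
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_beg, text_end, data_beg, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
  invisible(path)
}
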