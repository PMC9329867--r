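#' Read spectra from a delimited text file
#'
#' Expects comma-delimited text with a header row: the first column is the
#' axis (cm^-1 or nm), each further column one spectrum. An optional sidecar
#' (JSON, or YAML if the yaml package is installed) maps intensity column
#' names to labels (`analyte`, `concentration`, `replicate`) and carries
#' set-level metadata such as `source_wavelength_nm`.
#'
#' Rows are re-ordered so the axis is ascending; duplicate axis values and
#' non-numeric cells are errors naming the offending location.
#'
#' @param path path to the spectral CSV.
#' @param sidecar optional path to a JSON/YAML metadata file.
#' @param axis_kind axis interpretation, default Raman shift in cm^-1.
#' @return A [spectrum_set()].
#' @export
read_spectra <- function(path, sidecar = NULL,
                         axis_kind = c("raman_shift_cm1", "wavelength_nm")) {
  axis_kind <- match.arg(axis_kind)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (ncol(raw) < 2L)
    stop("need an axis column plus at least one intensity column", call. = FALSE)
  num <- vapply(seq_along(raw), function(j) {
    suppressWarnings(as.numeric(raw[[j]]))
  }, numeric(nrow(raw)))
  num <- matrix(num, nrow = nrow(raw))
  bad <- which(is.na(num) & !(raw == "" | toupper(as.matrix(raw)) == "NA"),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell at data row %d, column '%s' (value '%s')",
                 bad[1, 1], names(raw)[bad[1, 2]],
                 raw[[bad[1, 2]]][bad[1, 1]]), call. = FALSE)
  axis <- num[, 1L]
  if (anyDuplicated(axis))
    stop("duplicate axis value ", axis[duplicated(axis)][1L], call. = FALSE)
  ord <- order(axis)
  mat <- t(num[ord, -1L, drop = FALSE])
  rownames(mat) <- names(raw)[-1L]

  meta <- list(); labels <- NULL
  if (!is.null(sidecar)) {
    side <- read_sidecar(sidecar)
    meta <- side$meta %||% side[setdiff(names(side), "columns")]
    if (!is.null(side$columns)) {
      cols <- side$columns
      labels <- data.frame(
        analyte = vapply(rownames(mat), function(nm)
          as.character(cols[[nm]]$analyte %||% NA_character_), character(1)),
        concentration = vapply(rownames(mat), function(nm)
          as.numeric(cols[[nm]]$concentration %||% NA_real_), numeric(1)),
        replicate = vapply(rownames(mat), function(nm)
          as.character(cols[[nm]]$replicate %||% NA_character_), character(1)),
        row.names = NULL)
    }
  }
  spectrum_set(axis[ord], mat, labels = labels, axis_kind = axis_kind, meta = meta)
}

read_sidecar <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML sidecar given but the yaml package is not installed", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
}

#' Write a spectrum set to a spectral CSV plus JSON sidecar
#'
#' Inverse of [read_spectra()]: axis in the first column (`axis`), one column
#' per spectrum. Full double precision is kept so a read/write round trip
#' reproduces the data exactly as printed.
#'
#' @param set a [spectrum_set()].
#' @param path output CSV path.
#' @param sidecar optional output path for the JSON sidecar; `NULL` skips it.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path, sidecar = NULL) {
  stopifnot(inherits(set, "spectrum_set"))
  nm <- rownames(set$matrix) %||% paste0("s", seq_len(nrow(set$matrix)))
  df <- data.frame(axis = set$axis, t(set$matrix), check.names = FALSE)
  names(df) <- c("axis", nm)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(sidecar)) {
    cols <- lapply(seq_len(nrow(set$matrix)), function(i)
      list(analyte = set$labels$analyte[i],
           concentration = set$labels$concentration[i],
           replicate = set$labels$replicate[i]))
    names(cols) <- nm
    jsonlite::write_json(list(meta = set$meta, columns = cols), sidecar,
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
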