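# Reading and writing compression-isotherm records.
#
# Canonical dialect: UTF-8 CSV (comma delimiter, dot decimal separator) with
# header names area_A2_per_molecule, surface_pressure_mN_per_m and optionally
# surface_potential_mV. Metadata travels either in a JSON sidecar
# ("<path>.meta.json") or as "# key: value" comment lines at the top of the
# file. Rows are canonicalized to compression order (decreasing area).

.canonical_cols <- c(
  area = "area_A2_per_molecule",
  pressure = "surface_pressure_mN_per_m",
  potential = "surface_potential_mV"
)

parse_comment_metadata <- function(path) {
  lines <- readLines(path, n = 100L, warn = FALSE)
  cm <- grep("^#", lines, value = TRUE)
  if (length(cm) == 0) {
    return(list())
  }
  kv <- regmatches(cm, regexec("^#\\s*([^:]+):\\s*(.*)$", cm))
  kv <- kv[lengths(kv) == 3L]
  out <- lapply(kv, function(m) {
    v <- m[3]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- vapply(kv, function(m) trimws(m[2]), character(1))
  out
}

canonicalize_isotherm <- function(df, metadata, n_raw) {
  df <- df[stats::complete.cases(df[c("area_A2", "pressure_mN_m")]), ]
  if ("potential_mV" %in% names(df)) {
    df <- df[!is.na(df$potential_mV), ]
  }
  dropped <- n_raw - nrow(df)
  if (dropped > 0) {
    rlang::inform(paste0("Dropped ", dropped, " incomplete row(s)."))
  }
  if (nrow(df) < 20L) {
    abort_mono(
      paste0("Fewer than 20 valid rows (", nrow(df), ")."),
      "insufficient_data"
    )
  }
  n_dup <- sum(duplicated(df$area_A2))
  if (n_dup > 0.01 * nrow(df)) {
    abort_mono(
      paste0(
        "Area grid has ", n_dup, " duplicated values (> 1% of rows); ",
        "cannot canonicalize by sorting."
      ),
      "validation"
    )
  }
  if (n_dup > 0) {
    # barrier pauses: average readings taken at a repeated area
    df <- df |>
      group_by(area_A2) |>
      summarise(dplyr::across(dplyr::everything(), mean), .groups = "drop")
  }
  df <- arrange(df, dplyr::desc(area_A2))
  if (any(df$pressure_mN_m <= -1)) {
    abort_mono(
      "Surface pressure below -1 mN/m; check baseline calibration.",
      "validation"
    )
  }
  new_isotherm(
    df$area_A2, df$pressure_mN_m,
    if ("potential_mV" %in% names(df)) df$potential_mV else NULL,
    metadata
  )
}

#' Read a compression isotherm from a delimited text file
#'
#' @param path Path to the file.
#' @param dialect `"canonical"` (headered CSV, see Details) or
#'   `"two_column"` (headerless area, pressure pairs; any of comma, tab or
#'   whitespace delimited).
#' @details The canonical dialect is comma-separated UTF-8 with header names
#'   `area_A2_per_molecule`, `surface_pressure_mN_per_m` and optionally
#'   `surface_potential_mV`. Metadata is read from a `<path>.meta.json`
#'   sidecar if present, else from `# key: value` comment lines. Incomplete
#'   rows are dropped (with a message); duplicate-area rows are averaged;
#'   rows are returned in compression order regardless of file order.
#' @return An isotherm tibble (see [generate_isotherm()] for the schema).
#' @export
read_isotherm <- function(path, dialect = c("canonical", "two_column")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort_mono(paste0("No such file: ", path), "io")
  }
  sidecar <- paste0(path, ".meta.json")
  metadata <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    parse_comment_metadata(path)
  }
  if (dialect == "canonical") {
    # base strtod parsing: correctly rounded, so written values round-trip
    df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
    if (!all(.canonical_cols[c("area", "pressure")] %in% names(df))) {
      abort_mono(
        paste0(
          "Unknown header names: ", paste(names(df), collapse = ", "),
          ". Expected ", paste(.canonical_cols[1:2], collapse = ", "),
          " (and optionally ", .canonical_cols[["potential"]], ")."
        ),
        "format"
      )
    }
    out <- tibble(
      area_A2 = as.numeric(df[[.canonical_cols[["area"]]]]),
      pressure_mN_m = as.numeric(df[[.canonical_cols[["pressure"]]]])
    )
    if (.canonical_cols[["potential"]] %in% names(df)) {
      out$potential_mV <- as.numeric(df[[.canonical_cols[["potential"]]]])
    }
  } else {
    df <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#")
    if (ncol(df) == 1L) {
      df <- utils::read.table(path, header = FALSE, sep = ",", comment.char = "#")
    }
    if (ncol(df) < 2L) {
      abort_mono("two_column dialect needs two numeric columns.", "format")
    }
    out <- tibble(
      area_A2 = as.numeric(df[[1]]),
      pressure_mN_m = as.numeric(df[[2]])
    )
  }
  canonicalize_isotherm(out, metadata, nrow(out))
}

#' Write a compression isotherm in the canonical dialect
#'
#' Writes the canonical CSV (full double precision, so a read/write round
#' trip reproduces the values exactly) and a JSON metadata sidecar at
#' `<path>.meta.json`.
#'
#' @param iso An isotherm tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_isotherm <- function(iso, path) {
  stopifnot(is.data.frame(iso))
  cols <- list(
    area_A2_per_molecule = iso$area_A2,
    surface_pressure_mN_per_m = iso$pressure_mN_m
  )
  if ("potential_mV" %in% names(iso)) {
    cols$surface_potential_mV <- iso$potential_mV
  }
  # %.17g guarantees a bit-exact double round trip
  body <- do.call(paste, c(lapply(cols, function(x) sprintf("%.17g", x)), sep = ","))
  lines <- c(paste(names(cols), collapse = ","), body)
  tryCatch(
    writeLines(lines, path),
    error = function(e) abort_mono(paste0("Cannot write ", path, ": ", conditionMessage(e)), "io"),
    warning = function(e) abort_mono(paste0("Cannot write ", path, ": ", conditionMessage(e)), "io")
  )
  md <- iso_metadata(iso)
  if (length(md) > 0) {
    jsonlite::write_json(
      md, paste0(path, ".meta.json"),
      auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
    )
  }
  invisible(path)
}
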