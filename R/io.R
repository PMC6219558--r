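#' Read an ImageJ point-tool XY export
#'
#' Parses a two-column numeric text file (whitespace- or comma-delimited,
#' optional header line), one digitized point per line, as produced by the
#' ImageJ point tool. Because plain XY exports carry no role labels, roles
#' are assigned by a documented block convention: the first `n_axis` rows
#' are the midvein axis polyline (first row = `midvein_base`, last row of
#' the block = `midvein_tip`, interior rows = `midvein_node`) and all
#' remaining rows are `vein_origin`. Files with an explicit `role` column
#' (the richer CSV dialect, see [read_points_csv()]) should use that reader
#' instead.
#'
#' @param path file path.
#' @param leaf_id identifier stamped on the points; defaults to the file
#'   name without extension.
#' @param n_axis number of leading rows forming the midvein axis block
#'   (default 2: base and tip; 0 = no axis block, every row a vein
#'   origin).
#' @return tibble with columns `leaf_id`, `x`, `y`, `role`, in file order.
#' @export
read_imagej_xy <- function(path, leaf_id = NULL, n_axis = 2L) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(leaf_id)) leaf_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty point file: ", path)
    return(tibble::tibble(leaf_id = character(), x = numeric(),
                          y = numeric(), role = character()))
  }
  parse_line <- function(ln) {
    fields <- strsplit(ln, "[,\t ]+")[[1]]
    fields <- fields[nzchar(fields)]
    suppressWarnings(as.numeric(fields))
  }
  first <- parse_line(lines[1])
  start <- 1L
  if (any(is.na(first))) { # header line
    start <- 2L
    if (length(lines) < 2) {
      warning("point file contains only a header: ", path)
      return(tibble::tibble(leaf_id = character(), x = numeric(),
                            y = numeric(), role = character()))
    }
  }
  body <- lines[start:length(lines)]
  parsed <- lapply(body, parse_line)
  for (i in seq_along(parsed)) {
    v <- parsed[[i]]
    if (length(v) < 2)
      stop(sprintf("line %d of %s: expected at least 2 columns",
                   i + start - 1L, path))
    if (any(is.na(v[1:2])))
      stop(sprintf("line %d of %s: non-numeric coordinate",
                   i + start - 1L, path))
  }
  x <- vapply(parsed, `[`, numeric(1), 1)
  y <- vapply(parsed, `[`, numeric(1), 2)
  n <- length(x)
  if (n_axis != 0 && (n_axis < 2 || n < n_axis))
    stop(sprintf("%s: need at least n_axis = %d rows for the axis block",
                 path, n_axis))
  role <- rep("vein_origin", n)
  if (n_axis >= 2) {
    role[1] <- "midvein_base"
    role[n_axis] <- "midvein_tip"
    if (n_axis > 2) role[2:(n_axis - 1)] <- "midvein_node"
  }
  tibble::tibble(leaf_id = leaf_id, x = x, y = y, role = role)
}

#' Read the role-annotated points CSV dialect
#'
#' CSV with columns `leaf_id`, `role`, `x`, `y`; `role` is one of
#' `midvein_base`, `midvein_tip`, `midvein_node`, `vein_origin`. This is
#' the preferred richer format; the synthetic generator writes it.
#'
#' @param path file path.
#' @return tibble with columns `leaf_id`, `x`, `y`, `role`.
#' @export
read_points_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("leaf_id", "role", "x", "y")
  if (!all(need %in% names(df)))
    stop("points CSV must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$role),
                 c("midvein_base", "midvein_tip", "midvein_node", "vein_origin"))
  if (length(bad))
    stop("unknown point role(s): ", paste(bad, collapse = ", "))
  tibble::as_tibble(df[, c("leaf_id", "x", "y", "role")])
}

#' Validate a point-annotation table and split it into leaf records
#'
#' Checks the per-leaf invariants (exactly one `midvein_base` and one
#' `midvein_tip`; at least two `vein_origin` rows for a leaf to enter
#' ratio computation) and assembles one leaf record per `leaf_id`, each
#' with a [midvein_axis()] and an origin table.
#'
#' @param points tibble as returned by [read_imagej_xy()] or
#'   [read_points_csv()].
#' @return named list of leaf records (`leaf_id`, `axis`, `origins`).
#' @export
points_to_leaves <- function(points) {
  points <- tibble::as_tibble(points)
  out <- lapply(split(points, points$leaf_id), function(p) {
    base <- p[p$role == "midvein_base", c("x", "y")]
    tip <- p[p$role == "midvein_tip", c("x", "y")]
    if (nrow(base) != 1 || nrow(tip) != 1)
      stop(sprintf("leaf %s: need exactly one midvein_base and one midvein_tip",
                   p$leaf_id[1]))
    nodes <- rbind(as.matrix(base),
                   as.matrix(p[p$role == "midvein_node", c("x", "y")]),
                   as.matrix(tip))
    origins <- p[p$role == "vein_origin", c("x", "y")]
    if (nrow(origins) < 2)
      warning(sprintf("leaf %s: fewer than 2 vein origins; no ratios computable",
                      p$leaf_id[1]))
    list(leaf_id = p$leaf_id[1], axis = midvein_axis(nodes),
         origins = origins)
  })
  out[unique(points$leaf_id)]
}

#' Read a species metadata table
#'
#' CSV with one row per species. Required columns: `code` (unique),
#' `phyllotaxis` (`alternate`/`opposite`) and `life_form`
#' (`woody`/`herbaceous`); the bundled table additionally carries
#' `binomial`, `family`, `leaf_type`, `venation_class` and the published
#' per-species leaf (`n_leaves`) and vein (`n_veins`) counts.
#'
#' @param path CSV path; the default is the metadata table for the 30
#'   study species bundled with the package.
#' @return tibble of species metadata.
#' @export
read_species_metadata <- function(path = system.file("extdata",
                                                     "species_metadata.csv",
                                                     package = "veinr")) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("code", "phyllotaxis", "life_form")
  if (!all(need %in% names(df)))
    stop("species metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$code))
    stop("species codes must be unique")
  bad_ph <- which(!df$phyllotaxis %in% c("alternate", "opposite"))
  bad_lf <- which(!df$life_form %in% c("woody", "herbaceous"))
  if (length(bad_ph))
    stop("invalid phyllotaxis level in row(s): ",
         paste(bad_ph, collapse = ", "))
  if (length(bad_lf))
    stop("invalid life_form level in row(s): ",
         paste(bad_lf, collapse = ", "))
  df
}

#' Write a tidy result table
#'
#' Writes any of the package's result tables to CSV or JSON so that
#' reading the file back reproduces the table field for field (numeric
#' fields to at least 10 significant digits; CSV uses 15).
#'
#' @param records data frame; may be empty only when `allow_empty = TRUE`.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @param allow_empty write a header-only file for an empty table.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("csv", "json"),
                          allow_empty = FALSE) {
  format <- match.arg(format)
  records <- as.data.frame(records)
  if (nrow(records) == 0 && !allow_empty)
    stop("refusing to write an empty table (set allow_empty = TRUE)")
  if (format == "csv") {
    out <- records
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(v)
      ifelse(is.na(v), NA, formatC(v, digits = 15, format = "g")))
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = FALSE)
  }
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`.
#' @return tibble.
#' @export
read_results <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv")
    tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  else
    tibble::as_tibble(jsonlite::fromJSON(path))
}
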