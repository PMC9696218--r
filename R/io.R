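#' Read a persistence-length dataset from delimited text
#'
#' The file is comma- or tab-delimited with a header row containing
#' `concentration_M` and `lp_nm` (or `lp_m`), preceded by an optional
#' metadata block of `#`-prefixed `key: value` lines carrying `T_K`, `Z`,
#' `constraint_class` and `label`.
#'
#' @param path Path to the file.
#' @return An [lp_dataset()].
#' @export
read_lp_dataset <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  meta <- list(T_K = 298, Z = 1L, constraint_class = "suspended", label = "")
  for (ml in meta_lines) {
    kv <- sub("^\\s*#\\s*", "", ml)
    if (!grepl(":", kv)) next
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    if (key %in% names(meta)) meta[[key]] <- val
  }
  body <- lines[!grepl("^\\s*#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L)
    stop(sprintf("malformed dataset file %s: no data rows found.", path),
         call. = FALSE)
  delim <- if (grepl("\t", body[1L])) "\t" else ","
  df <- tryCatch(
    utils::read.table(text = body, sep = delim, header = TRUE,
                      strip.white = TRUE, check.names = TRUE),
    error = function(e)
      stop(sprintf("malformed dataset file %s: %s", path, conditionMessage(e)),
           call. = FALSE))
  lp_dataset(df,
             T = as.numeric(meta$T_K), Z = as.integer(meta$Z),
             constraint_class = meta$constraint_class, label = meta$label)
}

#' Write a persistence-length dataset to delimited text
#'
#' @param ds An [lp_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lp_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "lp_dataset"))
  hdr <- c(sprintf("# T_K: %g", attr(ds, "T")),
           sprintf("# Z: %d", attr(ds, "Z")),
           sprintf("# constraint_class: %s", attr(ds, "constraint_class")),
           sprintf("# label: %s", attr(ds, "label")),
           "concentration_M,lp_nm")
  rows <- sprintf("%.9g,%.9g", ds$concentration_M, ds$lp_nm)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a conformation ensemble as multi-record XYZ text
#'
#' One block per conformation: a count line with the number of axis points,
#' followed by that many `x y z` lines in nanometres at 9 significant digits.
#'
#' @param ens A `chain_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "chain_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  for (m in ens$conformations) {
    writeLines(as.character(nrow(m)), con)
    writeLines(sprintf("%.9g %.9g %.9g",
                       m[, 1L] * 1e9, m[, 2L] * 1e9, m[, 3L] * 1e9), con)
  }
  invisible(path)
}

#' Read a conformation ensemble from multi-record XYZ text
#'
#' @param path Path written by [write_xyz_ensemble()].
#' @return A `chain_ensemble` (coordinates in metres).
#' @export
read_xyz_ensemble <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  conf <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n) || n < 2L || i + n > length(lines))
      stop(sprintf("malformed XYZ file %s at line %d.", path, i), call. = FALSE)
    block <- lines[(i + 1L):(i + n)]
    m <- matrix(suppressWarnings(as.numeric(unlist(strsplit(trimws(block), "\\s+")))),
                ncol = 3L, byrow = TRUE)
    if (any(is.na(m)))
      stop(sprintf("malformed XYZ file %s: non-numeric coordinates near line %d.",
                   path, i + 1L), call. = FALSE)
    conf[[length(conf) + 1L]] <- m * 1e-9
    i <- i + n + 1L
  }
  if (length(conf) == 0L)
    stop(sprintf("malformed XYZ file %s: no conformations.", path), call. = FALSE)
  structure(list(conformations = conf), class = "chain_ensemble")
}
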