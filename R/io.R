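#' Load model parameters from a flat key-value config file
#'
#' Reads a plain-text config with one `key = value` pair per line (`#`
#' starts a comment; blank lines ignored). Valid keys: `N`, `T`, `V`,
#' `lam`, `a`, `f0`, `l0`, `kb`, `kb_ratio`, `m`. Missing keys fall back
#' to the reference defaults of [af_params()]; unknown keys are rejected
#' with a message listing the valid ones. An empty file therefore yields
#' the full default parameter set.
#'
#' @param path Path to the config file.
#' @param base An `"af_params"` object supplying the fallback values.
#' @return A validated `"af_params"` object.
#' @examples
#' cfg <- tempfile()
#' writeLines(c("kb_ratio = 10", "m = 500"), cfg)
#' af_load_config(cfg)
#' @export
af_load_config <- function(path, base = af_params()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  stopifnot(inherits(base, "af_params"))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  valid <- c("N", "T", "V", "lam", "a", "f0", "l0", "kb", "kb_ratio", "m")
  overrides <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("cannot parse config line (expected 'key = value'): ", ln,
           call. = FALSE)
    key <- trimws(parts[1])
    val <- trimws(parts[2])
    if (!key %in% valid)
      stop(sprintf("unknown config key '%s'; valid keys: %s", key,
                   paste(valid, collapse = ", ")), call. = FALSE)
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num))
      stop(sprintf("config value for '%s' is not numeric: '%s'", key, val),
           call. = FALSE)
    overrides[[key]] <- num
  }
  if ("T" %in% names(overrides)) {
    overrides$T_kelvin <- overrides$T
    overrides$T <- NULL
  }
  do.call(af_update, c(list(params = base), overrides))
}

fmt12 <- function(x) {
  # period decimal separator regardless of locale; 12 significant digits
  vapply(x, function(v) sprintf("%.12g", v), character(1))
}

#' Write a length-distribution table (deterministic TSV)
#'
#' Writes the per-class table of [as.data.frame.af_distribution()] as a
#' tab-separated file with header, 12-significant-digit C-locale number
#' formatting and a trailing newline, so identical runs produce
#' byte-identical files suitable for checksum-based regression tests.
#'
#' @param dist An `"af_distribution"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [af_read_distribution_table()]
#' @export
af_write_distribution_table <- function(dist, path) {
  stopifnot(inherits(dist, "af_distribution"))
  tab <- as.data.frame(dist)
  out <- tryCatch(file(path, open = "wb"), error = function(e)
    stop("cannot open output file '", path, "': ", conditionMessage(e),
         call. = FALSE))
  on.exit(close(out))
  writeLines(paste(names(tab), collapse = "\t"), out, sep = "\n")
  num_cols <- names(tab)
  body <- do.call(paste, c(lapply(tab[num_cols], function(col) {
    if (is.numeric(col) && !is.integer(col)) fmt12(col)
    else as.character(col)
  }), sep = "\t"))
  writeLines(body, out, sep = "\n")
  invisible(path)
}

#' Read back a length-distribution table
#'
#' @param path Path written by [af_write_distribution_table()].
#' @return A `data.frame` with the standard columns.
#' @export
af_read_distribution_table <- function(path) {
  if (!file.exists(path)) stop("no such table: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "numeric")
}

#' Write a sweep as per-point TSV files plus a manifest
#'
#' One distribution table per swept value, named
#' `<param>_<index>.tsv`, plus a `manifest.tsv` listing
#' `file`, `param`, `value` and the MD5 `checksum` of each table. Because
#' the tables are byte-stable, re-running the sweep reproduces the
#' manifest exactly.
#'
#' @param sweep An `"af_sweep"` object.
#' @param dir Output directory (created if absent).
#' @param overwrite Refuse to clobber an existing manifest unless `TRUE`.
#' @return Path to the manifest, invisibly.
#' @export
af_write_sweep <- function(sweep, dir, overwrite = FALSE) {
  stopifnot(inherits(sweep, "af_sweep"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest_path <- file.path(dir, "manifest.tsv")
  if (file.exists(manifest_path) && !overwrite)
    stop("manifest already exists in '", dir,
         "'; pass overwrite = TRUE to replace it", call. = FALSE)
  files <- sprintf("%s_%03d.tsv", sweep$param, seq_along(sweep$values))
  for (j in seq_along(sweep$values))
    af_write_distribution_table(sweep$distributions[[j]],
                                file.path(dir, files[j]))
  sums <- unname(tools::md5sum(file.path(dir, files)))
  man <- data.frame(file = files, param = sweep$param,
                    value = fmt12(as.numeric(sweep$values)),
                    checksum = sums)
  out <- file(manifest_path, open = "wb")
  on.exit(close(out))
  writeLines(paste(names(man), collapse = "\t"), out, sep = "\n")
  writeLines(do.call(paste, c(man, sep = "\t")), out, sep = "\n")
  invisible(manifest_path)
}
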