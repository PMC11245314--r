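# Delimited-text serialization. All matrices/vectors travel as header-free
# CSV (row-major, 0-based indices in any serialized index fields); configs
# and manifests are JSON or YAML, auto-detected by extension.

write_matrix_csv <- function(m, path) {
  utils::write.table(as.matrix(m), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

read_matrix_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' Write a polytope as header-free CSV files
#'
#' Writes `<prefix>_A.csv` (constraint matrix) and `<prefix>_b.csv`
#' (bounds, one per line).
#'
#' @param P a [polytope()].
#' @param prefix path prefix for the two files.
#' @return the prefix, invisibly.
#' @export
write_polytope <- function(P, prefix) {
  write_matrix_csv(P$A, paste0(prefix, "_A.csv"))
  write_matrix_csv(matrix(P$b, ncol = 1L), paste0(prefix, "_b.csv"))
  invisible(prefix)
}

#' Read a polytope written by [write_polytope()]
#' @param prefix path prefix used when writing.
#' @param label optional label for the polytope.
#' @return a [polytope()].
#' @export
read_polytope <- function(prefix, label = NULL) {
  A <- read_matrix_csv(paste0(prefix, "_A.csv"))
  b <- as.numeric(read_matrix_csv(paste0(prefix, "_b.csv")))
  polytope(A, b, label = label)
}

#' Write a transform record as CSV files
#' @param record a [transform_record()].
#' @param prefix path prefix (`<prefix>_basis.csv`, `<prefix>_shift.csv`).
#' @return the prefix, invisibly.
#' @export
write_transform <- function(record, prefix) {
  write_matrix_csv(record$basis, paste0(prefix, "_basis.csv"))
  write_matrix_csv(matrix(record$shift, ncol = 1L),
                   paste0(prefix, "_shift.csv"))
  invisible(prefix)
}

#' Read a transform record written by [write_transform()]
#' @param prefix path prefix used when writing.
#' @return a [transform_record()].
#' @export
read_transform <- function(prefix) {
  transform_record(read_matrix_csv(paste0(prefix, "_basis.csv")),
                   as.numeric(read_matrix_csv(paste0(prefix, "_shift.csv"))))
}

#' Read a structured config document (JSON or YAML)
#'
#' Format is chosen by extension (`.json` vs `.yml`/`.yaml`); anything else
#' is tried as JSON first, then YAML. File paths inside a config are
#' interpreted relative to the config's directory by the CLI.
#'
#' @param path config file path.
#' @return a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    cw_stop(sprintf("config file '%s' does not exist", path),
            "cw_config_error")
  }
  ext <- tolower(tools::file_ext(path))
  parse_json <- function() jsonlite::fromJSON(path, simplifyVector = TRUE)
  parse_yaml <- function() yaml::read_yaml(path)
  out <- if (ext == "json") {
    tryCatch(parse_json(), error = function(e) {
      cw_stop(sprintf("malformed JSON config '%s': %s", path,
                      conditionMessage(e)), "cw_config_error")
    })
  } else if (ext %in% c("yml", "yaml")) {
    tryCatch(parse_yaml(), error = function(e) {
      cw_stop(sprintf("malformed YAML config '%s': %s", path,
                      conditionMessage(e)), "cw_config_error")
    })
  } else {
    tryCatch(parse_json(), error = function(e) {
      tryCatch(parse_yaml(), error = function(e2) {
        cw_stop(sprintf("config '%s' is neither valid JSON nor YAML", path),
                "cw_config_error")
      })
    })
  }
  if (!is.list(out)) {
    cw_stop(sprintf("config '%s' must be a mapping at the top level", path),
            "cw_config_error")
  }
  out
}

#' Write sampler draws to disk
#'
#' `format = "csv"` writes one header-free CSV per chain
#' (`chain_1.csv`, ...) plus a `meta.json` sidecar with seeds, proposal,
#' thinning, polytope label and acceptance rates. `format = "bin"` writes a
#' single packed little-endian binary (`draws.bin`) with a JSON index
#' header in `meta.json` describing the (chain, draw, dimension) layout.
#'
#' @param batch a `"sample_batch"`.
#' @param dir output directory (created if missing).
#' @param format `"csv"` or `"bin"`.
#' @return `dir`, invisibly.
#' @export
write_sample_batch <- function(batch, dir, format = c("csv", "bin")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(batch$draws)
  meta <- c(batch$meta,
            list(format = format, n_dim = d[3L],
                 acceptance_rates = batch$acceptance_rates,
                 layout = "chain-major; within a chain, draws are rows"))
  if (format == "csv") {
    for (k in seq_len(d[1L])) {
      write_matrix_csv(batch$draws[k, , , drop = TRUE],
                       file.path(dir, sprintf("chain_%d.csv", k)))
    }
  } else {
    con <- file(file.path(dir, "draws.bin"), "wb")
    on.exit(close(con))
    writeBin(as.integer(d), con, size = 4L, endian = "little")
    writeBin(as.numeric(aperm(batch$draws, c(3L, 2L, 1L))), con,
             size = 8L, endian = "little")
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read draws written by [write_sample_batch()]
#' @param dir directory written by [write_sample_batch()].
#' @return a `"sample_batch"` (without reduced-space draws).
#' @export
read_sample_batch <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"),
                             simplifyVector = TRUE)
  if (identical(meta$format, "csv")) {
    files <- sort(list.files(dir, pattern = "^chain_[0-9]+\\.csv$",
                             full.names = TRUE))
    mats <- lapply(files, read_matrix_csv)
    draws <- array(NA_real_,
                   c(length(mats), nrow(mats[[1L]]), ncol(mats[[1L]])))
    for (k in seq_along(mats)) draws[k, , ] <- mats[[k]]
  } else {
    con <- file(file.path(dir, "draws.bin"), "rb")
    on.exit(close(con))
    d <- readBin(con, "integer", 3L, size = 4L, endian = "little")
    v <- readBin(con, "numeric", prod(d), size = 8L, endian = "little")
    draws <- aperm(array(v, d[c(3L, 2L, 1L)]), c(3L, 2L, 1L))
  }
  structure(list(draws = draws, reduced = NULL,
                 acceptance_rates = meta$acceptance_rates,
                 meta = meta),
            class = "sample_batch")
}
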