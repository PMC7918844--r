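## CSV export with a JSON metadata header line.  Output is deterministic:
## re-running a configuration reproduces files byte for byte.

.write_csv_with_meta <- function(df, path, metadata) {
  meta <- jsonlite::toJSON(c(list(package = "dhcell",
                                  version = as.character(
                                    utils::packageVersion("dhcell"))),
                             metadata),
                           auto_unbox = TRUE, digits = NA)
  con <- file(path, open = "wb")  # binary mode: identical newlines everywhere
  on.exit(close(con))
  writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE,
                     quote = FALSE, eol = "\n")
  invisible(path)
}

.read_meta_header <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# ")) return(NULL)
  jsonlite::fromJSON(sub("^# ", "", first))
}

#' Write a radial profile to CSV
#'
#' Columns `r_over_R`, `value`, `kind_tag`; the first line is a `#`
#' comment holding the full parameter set as JSON.
#'
#' @param profile a [radial_profile()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "radial_profile"))
  df <- data.frame(r_over_R = profile$r_over_R, value = profile$value,
                   kind_tag = attr(profile, "kind"))
  .write_csv_with_meta(df, path,
                       c(list(kind = attr(profile, "kind")),
                         attr(profile, "params")))
}

#' Read a radial profile written by [write_profile_csv()]
#'
#' @param path file path.
#' @return a [radial_profile()] with metadata restored.
#' @export
read_profile_csv <- function(path) {
  meta <- .read_meta_header(path)
  df <- utils::read.csv(path, comment.char = "#")
  params <- meta[setdiff(names(meta), c("package", "version", "kind"))]
  radial_profile(df$r_over_R, df$value, df$kind_tag[1], params = params)
}

#' Write free-energy or sweep records to CSV
#'
#' @param df a data frame of result records (e.g. a `scaled_sweep`).
#' @param path output file path.
#' @param metadata named list stored in the JSON header.
#' @return the path, invisibly.
#' @export
write_sweep_csv <- function(df, path, metadata = list()) {
  .write_csv_with_meta(as.data.frame(df), path, metadata)
}
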