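#' Read and write trial tables
#'
#' Trial tables are stored as tab-separated text with a single header row
#' and the columns documented in [generate_mouse_dataset()].
#'
#' @param trials Trial table.
#' @param path File path.
#' @return `read_trials()` returns the trial table; `write_trials()` its
#'   input, invisibly.
#' @export
write_trials <- function(trials, path) {
  write.table(trials, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(trials)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  d$correct <- as.logical(d$correct)
  d
}

#' Serialize a fit result
#'
#' Writes (or reads) a `ddm_fit` object as JSON: the per-condition table
#' plus the shared scalars.
#'
#' @param fit A `ddm_fit` object.
#' @param path File path.
#' @export
write_fit <- function(fit, path) {
  if (!inherits(fit, "ddm_fit")) {
    stop("'fit' must be a 'ddm_fit' object", call. = FALSE)
  }
  payload <- unclass(fit)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(fit)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$conditions <- as.data.frame(payload$conditions,
                                      stringsAsFactors = FALSE)
  structure(payload, class = "ddm_fit")
}
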