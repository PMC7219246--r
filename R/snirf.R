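#' SNIRF (HDF5) import and export
#'
#' Reads and writes recordings as SNIRF containers -- the shared HDF5
#' format for near-infrared spectroscopy data. Because no HDF5 binding is
#' assumed on the R side, the HDF5 work is delegated to a bundled Python
#' helper (`h5py`), which bridges SNIRF to the package's long-format text
#' representation; `python` with `h5py` must be on the PATH (configurable
#' via `options(fnirslat.python = ...)`).
#'
#' Only processed-concentration SNIRF payloads are handled: one data block
#' whose measurement lists carry `dataTypeLabel` `"HbO"`/`"HbR"` and whose
#' stimulus groups are named `hand:condition`. Malformed containers fail
#' with the offending HDF5 path in the message.
#'
#' @param path SNIRF file path.
#' @param montage montage to attach on read (default inferred as in
#'   [read_recording_text()]).
#' @return `read_snirf()` returns an `fnirs_recording`; `write_snirf()`
#'   invisibly returns `path`.
#' @export
read_snirf <- function(path, montage = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tmp_s <- tempfile(fileext = ".tsv"); tmp_e <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(tmp_s, tmp_e)))
  snirf_helper("export", path, tmp_s, tmp_e)
  read_recording_text(tmp_s, tmp_e, montage = montage)
}

#' @rdname read_snirf
#' @param recording an `fnirs_recording` to write.
#' @export
write_snirf <- function(recording, path) {
  stopifnot(inherits(recording, "fnirs_recording"))
  tmp_s <- tempfile(fileext = ".tsv"); tmp_e <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(tmp_s, tmp_e)))
  write_recording_text(recording, tmp_s, tmp_e)
  snirf_helper("import", tmp_s, tmp_e, path)
  invisible(path)
}

snirf_helper <- function(mode, ...) {
  python <- getOption("fnirslat.python", Sys.which("python"))
  if (!nzchar(python))
    stop("SNIRF support needs `python` with h5py on the PATH ",
         "(set options(fnirslat.python=))")
  script <- system.file("python", "snirf_io.py", package = "fnirslat")
  if (!nzchar(script))   # running from a source checkout
    script <- file.path("inst", "python", "snirf_io.py")
  out <- suppressWarnings(
    system2(python, c(shQuote(script), mode, vapply(list(...), shQuote,
                                                    character(1))),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("SNIRF ", mode, " failed: ", paste(out, collapse = "\n"))
  invisible(NULL)
}
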