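## Optional convenience fetchers for public archives. These are thin,
## untested stubs: every tested code path in the package works from
## local files, and the pipeline never calls these itself.

#' Download a structure or shift file from its public archive
#'
#' Convenience stubs around `utils::download.file()`. They require
#' network access and are not exercised by the test suite; all
#' pipeline functions take local paths.
#'
#' @param id PDB id (`fetchPDBFile`) or shift-archive accession
#'   (`fetchShiftFile`).
#' @param destfile Local destination path.
#' @param baseUrl Archive base URL.
#' @return `destfile`, invisibly.
#' @export
fetchPDBFile <- function(id, destfile,
                         baseUrl = "https://files.rcsb.org/download") {
  utils::download.file(sprintf("%s/%s.pdb", baseUrl, toupper(id)),
                       destfile, quiet = TRUE, mode = "wb")
  invisible(destfile)
}

#' @rdname fetchPDBFile
#' @export
fetchShiftFile <- function(id, destfile,
                           baseUrl = "https://bmrb.io/ftp/pub/bmrb/entry_directories") {
  utils::download.file(
    sprintf("%s/bmr%s/bmr%s_3.str", baseUrl, id, id),
    destfile, quiet = TRUE, mode = "wb")
  invisible(destfile)
}
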