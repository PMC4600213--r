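#' Assemble a run report bundle
#'
#' Writes the pipeline's result tables (ROH summary, shared/consensus
#' intervals, concordance, neutrality windows, contrast variants -- whatever
#' is supplied) as TSV files plus a JSON run manifest recording the settings
#' and seeds needed to reproduce the run.  Components passed as `NULL` are
#' recorded as explicit gaps in the manifest rather than silently omitted.
#'
#' @param out_dir Output directory (created if needed).
#' @param components Named list of tibbles/data frames to write, e.g.
#'   `list(roh_summary = scan$summary, consensus = consensus_tbl)`.  `NULL`
#'   entries are allowed and reported as missing.
#' @param manifest Named list of run metadata (settings, seed, input paths);
#'   stored verbatim in `manifest.json`.
#' @return Invisibly, a tibble of the files written.
#' @export
assemble_report <- function(out_dir, components = list(), manifest = list()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir)
  }
  written <- list()
  missing <- character()
  for (nm in names(components)) {
    x <- components[[nm]]
    if (is.null(x)) {
      missing <- c(missing, nm)
      next
    }
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written[[nm]] <- path
  }
  man <- list(
    package = "rohscape",
    version = as.character(utils::packageVersion("rohscape")),
    settings = manifest,
    tables = lapply(written, basename),
    missing_components = as.list(missing))
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(tibble::tibble(
    component = c(names(written), "manifest"),
    path = c(unlist(written), file.path(out_dir, "manifest.json"))))
}

#' Read back a run manifest
#'
#' @param out_dir Directory written by [assemble_report()].
#' @return The manifest as a list.
#' @export
read_manifest <- function(out_dir) {
  jsonlite::read_json(file.path(out_dir, "manifest.json"),
                      simplifyVector = TRUE)
}
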