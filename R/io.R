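## Delimited-text I/O for the pipeline's table schemas. All files are
## UTF-8, tab-delimited, with '#' comment lines permitted.

.write_tsv <- function(x, path, header_comment = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    encoding = "UTF-8")
}

#' Write / read the peptide evidence and protein tables
#'
#' \code{peptides.tsv} holds one row per peptide with its
#' semicolon-joined protein mapping and per-replicate counts;
#' \code{proteins.tsv} holds \code{protein_id} and \code{length_aa}.
#'
#' @param peptides,proteins tables as produced by
#'   [simulateSpectralCounts()].
#' @param dir directory to write into (created if needed).
#' @return invisibly, the paths written.
#' @export
writeProteomicsTables <- function(peptides, proteins, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- .write_tsv(peptides, file.path(dir, "peptides.tsv"),
                   "peptide-level spectral counts; protein_ids ;-joined")
  p2 <- .write_tsv(proteins, file.path(dir, "proteins.tsv"),
                   "protein lengths in amino acids")
  invisible(c(peptides = p1, proteins = p2))
}

#' @rdname writeProteomicsTables
#' @param path file to read.
#' @export
readPeptides <- function(path) .read_tsv(path)

#' @rdname writeProteomicsTables
#' @export
readProteins <- function(path) .read_tsv(path)

#' Write / read single-molecule trace tables
#'
#' \code{traces.tsv} holds one row per event sample; \code{movies.tsv} is
#' the metadata sidecar (frame interval, frame count, microtubule length,
#' duration per movie).
#'
#' @param traces,movies tables as produced by [simulateTraces()].
#' @param dir directory to write into.
#' @return invisibly, the paths written.
#' @export
writeTraceTables <- function(traces, movies, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- .write_tsv(traces, file.path(dir, "traces.tsv"),
                   "event samples: positions in um along the microtubule")
  p2 <- .write_tsv(movies, file.path(dir, "movies.tsv"),
                   "movie metadata sidecar")
  invisible(c(traces = p1, movies = p2))
}

#' @rdname writeTraceTables
#' @param path file to read.
#' @export
readTraces <- function(path) {
  x <- .read_tsv(path)
  x$channel2_present <- as.logical(x$channel2_present)
  x
}

#' @rdname writeTraceTables
#' @export
readMovies <- function(path) .read_tsv(path)

#' Write / read ROI and tubule-track tables
#'
#' @param rois ROI table as from [simulateRoiMeasurements()].
#' @param tubules track table as from [simulateTubuleTracks()]; optional.
#' @param dir directory to write into.
#' @return invisibly, the paths written.
#' @export
writeImagingTables <- function(rois, tubules = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- c(rois = .write_tsv(rois, file.path(dir, "rois.tsv"),
                             "paired centrosome / whole-cell ROI sums"))
  if (!is.null(tubules))
    out <- c(out, tubules = .write_tsv(tubules,
                                       file.path(dir, "tubules.tsv"),
                                       "per-cell tubule tracks"))
  invisible(out)
}

#' @rdname writeImagingTables
#' @param path file to read.
#' @export
readRois <- function(path) .read_tsv(path)

#' @rdname writeImagingTables
#' @export
readTubules <- function(path) {
  x <- .read_tsv(path)
  x$moved_from_origin <- as.logical(x$moved_from_origin)
  x
}
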