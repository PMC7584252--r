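#' Write / read methylation or coverage tracks as bedGraph
#'
#' Four-column bedGraph (chrom, start, end, value), 0-based half-open on
#' disk; in memory the track is a `GRanges` with a numeric `score`.
#'
#' @param gr `GRanges` with `score`.
#' @param path output file path.
#' @return `write_bedgraph` returns `path` invisibly; `read_bedgraph`
#'   returns a `GRanges` with `score`.
#' @export
write_bedgraph <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  sf_assert(file.exists(path), "file_not_found", "no such file: %s", path)
  rtracklayer::import(path, format = "bedGraph")
}

#' Write a cassette-exon annotation
#'
#' `write_annotation_bed` emits one BED12 line per event (exons as
#' blocks); `write_annotation_tsv` / `read_annotation_tsv` carry the full
#' structure including which exon is the ASE (BED12 cannot).
#'
#' @param events an `ase_annotation` (see [generate_annotation()]).
#' @param path output path.
#' @return path, invisibly (readers return the object).
#' @export
write_annotation_bed <- function(events, path) {
  ev <- data.table::as.data.table(events)
  ev <- ev[order(ev$event_id, ev$start)]
  bed <- ev[, list(
    chrom = chrom[1], chromStart = min(start), chromEnd = max(end),
    name = event_id[1], score = 0L, strand = strand[1],
    thickStart = min(start), thickEnd = max(end), itemRgb = "0",
    blockCount = .N,
    blockSizes = paste0(paste(end - start, collapse = ","), ","),
    blockStarts = paste0(paste(start - min(start), collapse = ","), ",")
  ), by = "event_id"][, -1]
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @export
write_annotation_tsv <- function(events, path) {
  write_tsv(data.table::as.data.table(events), path)
}

#' @rdname write_annotation_bed
#' @export
read_annotation_tsv <- function(path) {
  ann <- read_tsv(path)
  ann$is_ase <- as.logical(ann$is_ase)
  data.table::setattr(ann, "class", c("ase_annotation", class(ann)))
  ann
}

#' Write / read a region-set manifest
#'
#' Long-format TSV with one row per interval: `event_id`, `category`,
#' `chrom`, `start`, `end` (0-based half-open), `strand`.
#'
#' @param region_sets result of [build_region_sets()].
#' @param path file path.
#' @return path invisibly; the reader returns a `region_sets` object.
#' @export
write_region_manifest <- function(region_sets, path) {
  stopifnot(inherits(region_sets, "region_sets"))
  write_tsv(data.table::as.data.table(region_sets), path)
}

#' @rdname write_region_manifest
#' @export
read_region_manifest <- function(path) {
  dt <- read_tsv(path)
  sf_assert(all(c("event_id", "category", "chrom", "start", "end",
                  "strand") %in% names(dt)), "invalid_input",
            "malformed region manifest: %s", path)
  data.table::setattr(dt, "class", c("region_sets", class(dt)))
  dt
}

#' TSV helpers
#'
#' Tab-separated read/write with a header row and `NA` for missing values;
#' all pipeline intermediates use this format.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return path invisibly (reader returns a `data.table`).
#' @export
write_tsv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(x, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  sf_assert(file.exists(path), "file_not_found", "no such file: %s", path)
  data.table::fread(path, sep = "\t", na.strings = "NA", data.table = TRUE)
}
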