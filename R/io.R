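#' File input/output for pipeline artifacts
#'
#' Round-trip helpers for the formats the pipeline consumes and produces:
#' RNA FASTA for UTR sets (DNA-alphabet files are transliterated T to U
#' with a notice), CSV for Ct/DE/cell tables with column checking, and
#' 16-bit grayscale TIFF (plus PNG preview) for section images.
#'
#' @name perimir_io
NULL

#' @rdname perimir_io
#' @param path File path.
#' @return `read_utr_fasta()`: named character vector of RNA sequences.
#' @export
read_utr_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(grepl("T", seqs, fixed = TRUE))) {
    inform("DNA-alphabet FASTA: transliterating T -> U")
    seqs <- chartr("T", "U", seqs)
  }
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    abort(paste0(
      "non-RNA characters in sequence(s): ",
      paste(head(names(seqs)[bad], 5), collapse = ", ")
    ))
  }
  if (any(!nzchar(seqs))) abort("empty sequence(s) in FASTA")
  seqs
}

#' @rdname perimir_io
#' @param utrs Named character vector of RNA sequences.
#' @export
write_utr_fasta <- function(utrs, path) {
  set <- Biostrings::BStringSet(utrs)
  Biostrings::writeXStringSet(set, path, width = 70)
  invisible(path)
}

.read_checked_csv <- function(path, required, what) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    abort(paste0(
      what, " file ", path, " missing column(s): ",
      paste(miss, collapse = ", ")
    ))
  }
  df
}

#' @rdname perimir_io
#' @return `read_ct_csv()`: a Ct table tibble (`sample_id`, `group_label`,
#'   `assay`, `ct`).
#' @export
read_ct_csv <- function(path) {
  .read_checked_csv(path, c("sample_id", "group_label", "assay", "ct"), "Ct")
}

#' @rdname perimir_io
#' @return `read_de_csv()`: a DE tibble (`gene_id`, `log2fc`, `p`).
#' @export
read_de_csv <- function(path) {
  de <- .read_checked_csv(path, c("gene_id", "log2fc", "p"), "DE")
  .check_de(de)
}

#' @rdname perimir_io
#' @param image Numeric matrix in `[0, 1]`.
#' @details Images are stored as 16-bit grayscale TIFF; the round-trip
#'   error is bounded by the 16-bit quantization step (< 2^-15).
#' @export
write_scene_tiff <- function(image, path) {
  tiff::writeTIFF(image, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname perimir_io
#' @export
read_scene_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' @rdname perimir_io
#' @export
write_scene_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' @rdname perimir_io
#' @return `read_layout_yaml()`: a [sector_layout()].
#' @export
read_layout_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(sector_layout, y)
}

#' @rdname perimir_io
#' @param layout A [sector_layout()].
#' @export
write_layout_yaml <- function(layout, path) {
  yaml::write_yaml(unclass(layout), path)
  invisible(path)
}
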