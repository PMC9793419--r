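# Stack, label and table I/O. Multi-channel stacks go to OME-TIFF-style
# multi-page 16-bit TIFF (plane order: for each channel, all z) with the
# OME-XML metadata (dimensions, channel names, physical voxel size) in a
# `<stack>.ome.xml` companion file, since the available TIFF writer cannot
# embed an ImageDescription tag. Intensities are stored as integer counts
# (clipped to 0..65535).

INT_SCALE <- 65535

ome_xml <- function(d, channels, voxel_size) {
  ch <- paste(sprintf('<Channel ID="Channel:0:%d" Name="%s" SamplesPerPixel="1"/>',
                      seq_along(channels) - 1L, channels), collapse = "")
  paste0('<?xml version="1.0" encoding="UTF-8"?>',
         '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
         '<Image ID="Image:0"><Pixels ID="Pixels:0" DimensionOrder="XYZCT" Type="uint16"',
         sprintf(' SizeX="%d" SizeY="%d" SizeZ="%d" SizeC="%d" SizeT="1"',
                 d[3], d[2], d[1], length(channels)),
         sprintf(' PhysicalSizeX="%g" PhysicalSizeY="%g" PhysicalSizeZ="%g">',
                 voxel_size[3], voxel_size[2], voxel_size[1]),
         ch, '</Pixels></Image></OME>')
}

#' Write and read multi-channel image stacks as OME-TIFF
#'
#' `write_stack()` stores an [render_stack()] result (or any named list of 3D
#' arrays sharing a shape) as a multi-page 16-bit TIFF, channel-major plane
#' order, with an OME-XML header recording sizes, channel names and voxel
#' spacing in µm. `read_stack()` restores the `image_stack`.
#'
#' @param stack An `image_stack`, or a named list of 3D arrays (then
#'   `voxel_size` is required).
#' @param path Output `.tif` path.
#' @param voxel_size Voxel spacing override, µm.
#' @return `write_stack()`: the path, invisibly. `read_stack()`: an
#'   `image_stack`.
#' @export
write_stack <- function(stack, path, voxel_size = NULL) {
  if (inherits(stack, "image_stack")) {
    channels <- stack$channels
    voxel_size <- voxel_size %||% stack$voxel_size
  } else {
    channels <- stack
    if (is.null(voxel_size)) stopf("voxel_size required for a plain channel list")
  }
  d <- dim(channels[[1]])
  planes <- list()
  for (ch in channels) {
    stopifnot(all(dim(ch) == d))
    for (z in seq_len(d[1]))
      planes[[length(planes) + 1L]] <-
        pmin(pmax(round(ch[z, , ]), 0), INT_SCALE) / INT_SCALE
  }
  tiff::writeTIFF(planes, path, bits.per.sample = 16L, compression = "deflate",
                  reduce = FALSE)
  writeLines(ome_xml(d, names(channels), voxel_size), paste0(path, ".ome.xml"))
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  meta <- paste0(path, ".ome.xml")
  if (!file.exists(meta)) stopf("%s has no OME-XML companion (%s)", path, meta)
  x <- xml2::read_xml(meta)
  px <- xml2::xml_find_first(x, "//*[local-name()='Pixels']")
  nz <- as.integer(xml2::xml_attr(px, "SizeZ"))
  nc <- as.integer(xml2::xml_attr(px, "SizeC"))
  ny <- as.integer(xml2::xml_attr(px, "SizeY"))
  nx <- as.integer(xml2::xml_attr(px, "SizeX"))
  vs <- c(as.numeric(xml2::xml_attr(px, "PhysicalSizeZ")),
          as.numeric(xml2::xml_attr(px, "PhysicalSizeY")),
          as.numeric(xml2::xml_attr(px, "PhysicalSizeX")))
  chn <- xml2::xml_attr(xml2::xml_find_all(x, "//*[local-name()='Channel']"), "Name")
  if (length(planes) != nz * nc) stopf("plane count mismatch in %s", path)
  channels <- list()
  for (ci in seq_len(nc)) {
    a <- array(0, c(nz, ny, nx))
    for (z in seq_len(nz)) a[z, , ] <- planes[[(ci - 1L) * nz + z]] * INT_SCALE
    channels[[chn[ci]]] <- a
  }
  structure(list(channels = channels, voxel_size = vs), class = "image_stack")
}

#' Write and read a cell label volume as single-channel TIFF
#'
#' @param labels 3D integer label array.
#' @param path `.tif` path.
#' @return `write_labels()`: the path invisibly; `read_labels()`: the integer
#'   array.
#' @export
write_labels <- function(labels, path) {
  d <- dim(labels)
  planes <- lapply(seq_len(d[1]), function(z) labels[z, , ] / INT_SCALE)
  tiff::writeTIFF(planes, path, bits.per.sample = 16L, compression = "deflate",
                  reduce = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  d <- c(length(planes), dim(planes[[1]]))
  a <- array(0L, d)
  for (z in seq_len(d[1])) a[z, , ] <- as.integer(round(planes[[z]] * INT_SCALE))
  a
}

# CSV writers: header row, floats at 6 significant digits
write_table_csv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read ground-truth molecule tables
#'
#' CSV with columns `mol_id, z_um, y_um, x_um, cell_id, norm_dist,
#' cluster_id`; floats carry 6 significant digits.
#'
#' @param truth A `ground_truth` data frame.
#' @param path CSV path.
#' @export
write_ground_truth <- function(truth, path) write_table_csv(truth, path)

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  gt <- read.csv(path)
  class(gt) <- c("ground_truth", "data.frame")
  gt
}

#' Read or write coding sequences as FASTA
#'
#' Thin wrappers over Biostrings FASTA I/O returning plain character vectors.
#'
#' @param path FASTA path.
#' @return `read_cds_fasta()`: named character vector of sequences.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_cds_fasta
#' @param seqs Named character vector of nucleotide sequences.
#' @export
write_cds_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(seqs)), path)
  invisible(path)
}
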