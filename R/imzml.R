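# Minimal continuous-mode imzML I/O.  No installed R package reads imzML, so
# the package carries its own writer/reader for the continuous dialect it
# produces: a shared m/z axis stored once in the .ibd binary, followed by one
# 64-bit float intensity array per pixel, with CSV sidecars for core and
# pixel metadata.

IMZML_HEADER <- '<?xml version="1.0" encoding="UTF-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">
  <cvList count="2">
    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology"/>
    <cv id="IMS" fullName="Imaging MS Ontology"/>
  </cvList>
  <fileDescription>
    <fileContent>
      <cvParam cvRef="IMS" accession="IMS:1000030" name="continuous"/>
      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="%s"/>
    </fileContent>
  </fileDescription>
  <referenceableParamGroupList count="2">
    <referenceableParamGroup id="mzArray">
      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>
      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>
      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
    </referenceableParamGroup>
    <referenceableParamGroup id="intensityArray">
      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>
      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>
      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
    </referenceableParamGroup>
  </referenceableParamGroupList>
  <run id="run0">
    <spectrumList count="%d">'

IMZML_SPECTRUM <- '      <spectrum id="spectrum=%d" index="%d">
        <scanList count="1">
          <scan>
            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>
          </scan>
        </scanList>
        <binaryDataArrayList count="2">
          <binaryDataArray encodedLength="0">
            <referenceableParamGroupRef ref="mzArray"/>
            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>
            <binary/>
          </binaryDataArray>
          <binaryDataArray encodedLength="0">
            <referenceableParamGroupRef ref="intensityArray"/>
            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>
            <binary/>
          </binaryDataArray>
        </binaryDataArrayList>
      </spectrum>'

IMZML_FOOTER <- '    </spectrumList>
  </run>
</mzML>'

# Global pixel coordinates: cores are laid out side by side with a 2-pixel
# gutter, as on a physical TMA slide.
global_coords <- function(pixels, cores) {
  core_idx <- match(pixels$core_id, cores$core_id)
  width <- max(pixels$x) + 2L
  data.frame(x = pixels$x + (core_idx - 1L) * width, y = pixels$y)
}

#' Write a dataset as continuous-mode imzML with CSV sidecars
#'
#' Produces `<name>.imzML`, `<name>.ibd`, `<name>_cores.csv` (core_id,
#' patient_id, subtype) and `<name>_pixels.csv` (global x/y, core_id,
#' compartment).
#'
#' @param dataset An `ims_dataset`.
#' @param dir Output directory (created if needed).
#' @param name File stem (default "dataset").
#' @return Invisibly, the paths written.
#' @export
write_ims <- function(dataset, dir, name = "dataset") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(dataset$intensities)
  nmz <- length(dataset$mz)
  uuid <- substr(object_hash(list(dataset$mz, dim(dataset$intensities))), 1, 32)

  ibd_path <- file.path(dir, paste0(name, ".ibd"))
  con <- file(ibd_path, "wb")
  writeBin(as.raw(strtoi(substring(uuid, seq(1, 31, 2), seq(2, 32, 2)), 16L)), con)
  writeBin(as.numeric(dataset$mz), con, size = 8, endian = "little")
  for (i in seq_len(n))
    writeBin(as.numeric(dataset$intensities[i, ]), con, size = 8,
             endian = "little")
  close(con)

  gc_xy <- global_coords(dataset$pixels, dataset$cores)
  int_offsets <- 16 + 8 * nmz + (seq_len(n) - 1) * 8 * nmz
  xml_path <- file.path(dir, paste0(name, ".imzML"))
  body <- sprintf(IMZML_SPECTRUM, seq_len(n), seq_len(n) - 1L,
                  gc_xy$x, gc_xy$y, nmz, 16L, nmz, int_offsets)
  writeLines(c(sprintf(IMZML_HEADER, uuid, n), body, IMZML_FOOTER), xml_path)

  cores_path <- file.path(dir, paste0(name, "_cores.csv"))
  write.csv(dataset$cores, cores_path, row.names = FALSE)
  pixels_path <- file.path(dir, paste0(name, "_pixels.csv"))
  write.csv(data.frame(x = gc_xy$x, y = gc_xy$y,
                       core_id = dataset$pixels$core_id,
                       compartment = dataset$pixels$compartment),
            pixels_path, row.names = FALSE)
  invisible(c(imzml = xml_path, ibd = ibd_path, cores = cores_path,
              pixels = pixels_path))
}

xml_cv_value <- function(node, accession) {
  cv <- xml2::xml_find_first(node, sprintf(
    ".//*[local-name()='cvParam'][@accession='%s']", accession))
  if (inherits(cv, "xml_missing")) NA_character_ else xml2::xml_attr(cv, "value")
}

#' Read a continuous-mode imzML dataset with CSV sidecars
#'
#' Only the continuous imzML dialect is supported; processed-mode files are
#' rejected with an explicit error.  Pixels present in the imzML but absent
#' from the pixel sidecar are excluded with a warning.
#'
#' @param imzml_path Path to the `.imzML` file (the `.ibd` is expected
#'   alongside it).
#' @param cores_path,pixels_path Paths to the CSV sidecars.
#' @return An `ims_dataset`.
#' @export
read_ims <- function(imzml_path, cores_path, pixels_path) {
  for (p in c(imzml_path, cores_path, pixels_path))
    if (!file.exists(p)) stopf("missing input file: %s", p)
  doc <- xml2::read_xml(imzml_path)
  fc <- xml2::xml_find_first(doc, "//*[local-name()='fileContent']")
  if (!inherits(xml2::xml_find_first(fc, ".//*[local-name()='cvParam'][@accession='IMS:1000031']"),
                "xml_missing"))
    stopf("unsupported-dialect error: processed-mode imzML is not supported; only continuous mode")
  if (inherits(xml2::xml_find_first(fc, ".//*[local-name()='cvParam'][@accession='IMS:1000030']"),
               "xml_missing"))
    stopf("unsupported-dialect error: file does not declare continuous mode")

  spectra <- xml2::xml_find_all(doc, "//*[local-name()='spectrum']")
  xs <- as.integer(vapply(spectra, xml_cv_value, "", "IMS:1000050"))
  ys <- as.integer(vapply(spectra, xml_cv_value, "", "IMS:1000051"))
  get_array_info <- function(node, ref) {
    bda <- xml2::xml_find_first(node, sprintf(
      ".//*[local-name()='binaryDataArray'][*[local-name()='referenceableParamGroupRef'][@ref='%s']]",
      ref))
    c(length = as.numeric(xml_cv_value(bda, "IMS:1000103")),
      offset = as.numeric(xml_cv_value(bda, "IMS:1000102")))
  }
  mz_info <- get_array_info(spectra[[1L]], "mzArray")
  int_info <- t(vapply(spectra, get_array_info, c(length = 0, offset = 0),
                       ref = "intensityArray"))

  ibd_path <- sub("\\.imzML$", ".ibd", imzml_path)
  con <- file(ibd_path, "rb")
  on.exit(close(con))
  seek(con, mz_info[["offset"]])
  mz <- readBin(con, "double", n = mz_info[["length"]], size = 8,
                endian = "little")
  intensities <- matrix(0, length(spectra), length(mz))
  for (i in seq_along(spectra)) {
    seek(con, int_info[i, "offset"])
    intensities[i, ] <- readBin(con, "double", n = int_info[i, "length"],
                                size = 8, endian = "little")
  }

  cores <- read.csv(cores_path, stringsAsFactors = FALSE)
  pixel_tab <- read.csv(pixels_path, stringsAsFactors = FALSE)
  key <- paste(xs, ys); tab_key <- paste(pixel_tab$x, pixel_tab$y)
  hit <- match(key, tab_key)
  if (anyNA(hit)) {
    warnf("%d pixel(s) present in imzML but absent from the pixel table; excluded",
          sum(is.na(hit)))
    keep <- !is.na(hit)
    intensities <- intensities[keep, , drop = FALSE]
    xs <- xs[keep]; ys <- ys[keep]; hit <- hit[keep]
  }
  pixels <- data.frame(spectrum = seq_along(xs), x = xs, y = ys,
                       core_id = pixel_tab$core_id[hit],
                       patient_id = cores$patient_id[
                         match(pixel_tab$core_id[hit], cores$core_id)],
                       compartment = pixel_tab$compartment[hit],
                       stringsAsFactors = FALSE)
  structure(list(mz = mz, intensities = intensities, pixels = pixels,
                 cores = cores,
                 compartment_labeled = !anyNA(pixels$compartment),
                 preprocessed = character(0)),
            class = "ims_dataset")
}
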