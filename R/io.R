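# Standard-format I/O: headered TSV tables, GMT gene sets, BED gene
# intervals, NIfTI volumes, and the text truth bundle.

#' Write a headered TSV (missing values as empty fields)
#' @param x data.frame or matrix.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  df <- as.data.frame(x)
  df <- df[, !vapply(df, is.list, TRUE), drop = FALSE]  # drop list-columns
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a headered TSV written by [write_tsv()]
#' @param path Input path.
#' @export
read_tsv <- function(path) {
  read.delim(path, check.names = FALSE, na.strings = "")
}

#' Read pathway gene sets from a GMT file
#' @param path GMT path (one set per line: name, description, genes...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write pathway gene sets as GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene intervals from a BED file into a gene model
#'
#' BED is 0-based half-open on disk; the returned model is 1-based
#' inclusive (the conversion is handled by the importer).
#'
#' @param path BED path with a name column.
#' @return data.frame(symbol, chrom, start, end), class `gene_model`.
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(symbol = gr$name,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr))
  class(out) <- c("gene_model", class(out))
  out
}

#' Write a gene model as BED
#' @param gene_model data.frame(symbol, chrom, start, end), 1-based.
#' @param path Output path.
#' @export
write_gene_bed <- function(gene_model, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(gene_model$chrom),
    ranges = IRanges::IRanges(start = gene_model$start,
                              end = gene_model$end),
    name = gene_model$symbol)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write per-subject volumes and the mask as NIfTI-1
#'
#' @param volumes 4D array (x, y, z, subject) or list of 3D arrays.
#' @param mask Logical 3D array.
#' @param dir Output directory.
#' @param voxel_size_mm Voxel edge lengths (mm), carried in the header.
#' @param ids Subject ids for file naming.
#' @return Character vector of volume paths.
#' @export
write_nifti_volumes <- function(volumes, mask, dir,
                                voxel_size_mm = c(1, 1, 1), ids = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.array(volumes) && length(dim(volumes)) == 4L) {
    volumes <- lapply(seq_len(dim(volumes)[4]), function(s) volumes[, , , s])
  }
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(volumes))
  paths <- character(length(volumes))
  as_img <- function(a) {
    img <- RNifti::asNifti(a)
    RNifti::pixdim(img) <- voxel_size_mm
    img
  }
  for (s in seq_along(volumes)) {
    paths[s] <- file.path(dir, paste0(ids[s], "_gm.nii.gz"))
    RNifti::writeNifti(as_img(volumes[[s]]), paths[s])
  }
  RNifti::writeNifti(as_img(array(as.numeric(mask), dim(mask))),
                     file.path(dir, "mask.nii.gz"))
  invisible(paths)
}

#' Read per-subject NIfTI volumes and a mask from a directory
#'
#' @param dir Directory written by [write_nifti_volumes()].
#' @return list(volumes = list of 3D arrays, mask = logical array,
#'   voxel_size_mm, ids).
#' @export
read_nifti_volumes <- function(dir) {
  mask_path <- file.path(dir, "mask.nii.gz")
  if (!file.exists(mask_path)) stop_pf("no mask.nii.gz in %s", dir)
  mask_img <- RNifti::readNifti(mask_path)
  files <- sort(setdiff(list.files(dir, pattern = "\\.nii(\\.gz)?$",
                                   full.names = TRUE),
                        mask_path))
  vols <- lapply(files, function(f) {
    v <- RNifti::readNifti(f)
    array(as.numeric(v), dim(v))
  })
  list(volumes = vols, mask = array(as.numeric(mask_img) > 0.5, dim(mask_img)),
       voxel_size_mm = RNifti::pixdim(mask_img)[1:3],
       ids = sub("_gm\\.nii(\\.gz)?$", "", basename(files)))
}

#' Write a component z-map as NIfTI
#' @param source_row Source vector over in-mask voxels.
#' @param mask Logical 3D array.
#' @param path Output path.
#' @param voxel_size_mm Voxel sizes.
#' @export
write_component_map <- function(source_row, mask, path,
                                voxel_size_mm = c(1, 1, 1)) {
  z <- (source_row - mean(source_row)) / sd(source_row)
  img <- RNifti::asNifti(unflatten_map(z, mask))
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write the synthetic truth bundle as TSV matrices + JSON manifest
#' @param truth `synthetic_truth` object.
#' @param dir Output directory.
#' @export
write_truth_bundle <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("gene_sources", "brain_sources", "gene_loadings",
               "brain_loadings")) {
    write.table(truth[[nm]], file.path(dir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  manifest <- list(
    group_labels = truth$group_labels,
    subpop_labels = truth$subpop_labels,
    linked_pairs = lapply(truth$linked_pairs, as.numeric),
    realized_link_correlations = truth$realized_link_correlations,
    target_maf = truth$target_maf)
  jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
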