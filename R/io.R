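# NIfTI-1 volume I/O (via RNifti) and provenance-stamped TSV tables.

#' Read a 3-D NIfTI volume
#'
#' @param path Path to a `.nii` / `.nii.gz` file holding 3-D data.
#' @return Numeric 3-D array with a `voxel_size_mm` attribute taken from the
#'   NIfTI header.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4 && d[4] == 1) {
    img <- img[, , , 1]
  } else if (length(d) != 3) {
    stop(sprintf("'%s' is %d-D; select a single 3-D frame before loading",
                 path, length(d)), call. = FALSE)
  }
  vs <- RNifti::pixdim(img)[1:3]
  if (any(vs <= 0)) stop("non-positive voxel sizes in NIfTI header",
                         call. = FALSE)
  out <- array(as.numeric(img), dim(img)[1:3])
  set_voxel_size(out, vs)
}

#' Write a volume as NIfTI-1
#'
#' Doubles are stored as float32, integer data (e.g. atlas labels) exactly
#' as int32; voxel size goes into the header.
#'
#' @param volume 3-D numeric or integer array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Voxel edge lengths in mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, voxel_size_mm = voxel_size(volume)) {
  check_volume(volume)
  dtype <- if (is.integer(volume) ||
               all(volume == round(volume))) "int32" else "float"
  img <- RNifti::asNifti(array(volume, dim(volume)))
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

# Fowler-Noll-Vo 32-bit hash, used for provenance stamps and stage seeds
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keep h a double mod 2^32
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

#' Derive a per-stage seed from a master seed
#'
#' Stable hash of the stage name folded into the master seed, kept inside
#' the 32-bit signed integer range, so every pipeline stage draws from its
#' own reproducible stream without seed bookkeeping.
#'
#' @param master_seed Integer master seed.
#' @param stage Stage name (character).
#' @return Integer seed.
#' @export
derive_seed <- function(master_seed, stage) {
  as.integer((fnv1a(stage) + as.numeric(master_seed) * 2654435761) %%
               2147483647)
}

#' Write a data frame as TSV with provenance headers
#'
#' Prepends `#`-prefixed provenance lines (config hash, master seed, package
#' version) so outputs are self-describing and byte-reproducible for a fixed
#' seed.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param provenance Named character vector of provenance fields.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(provenance))
    writeLines(sprintf("# %s: %s", nm, provenance[[nm]]), con)
  utils::write.table(format(df, digits = 8, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
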