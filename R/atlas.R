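#' Build the default synthetic 673-parcel atlas
#'
#' Constructs a random Voronoi tessellation of a 3D grid into exactly 673
#' contiguous, non-overlapping parcels, partitioned into 600 cortical, 36
#' subcortical and 37 cerebellar labels -- the label counts of the combined
#' cortical/subcortical/cerebellar parcellation used for parcel-based
#' morphometry.  The tessellation is a synthetic stand-in: it reproduces the
#' label structure (counts, compartments, contiguity), not any anatomy.
#' Deterministic given `seed`.
#'
#' @param grid_shape Integer length-3 grid extent (voxels per axis).
#' @param seed Integer seed for the tessellation.
#' @param n_cortical,n_subcortical,n_cerebellar Compartment label counts.
#' @param voxel_volume Volume of one voxel in mm^3.
#' @return A `parcel_atlas`: list with `labels` (3D integer array, 0 =
#'   background-free here; every voxel is labelled), `label_table` (tibble:
#'   `label`, `parcel_id`, `compartment`) and `voxel_volume`.
#' @export
#' @examples
#' atlas <- build_default_atlas(grid_shape = c(16, 16, 16), seed = 1)
#' nrow(atlas$label_table)
build_default_atlas <- function(grid_shape = c(24, 24, 24), seed = 1,
                                n_cortical = 600, n_subcortical = 36,
                                n_cerebellar = 37, voxel_volume = 1) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  grid_shape <- as.integer(grid_shape)
  n_labels <- n_cortical + n_subcortical + n_cerebellar
  n_vox <- prod(grid_shape)
  if (n_vox < n_labels) {
    abort(sprintf(
      "grid of %d voxels cannot host %d labels; need at least %d voxels.",
      n_vox, n_labels, n_labels
    ))
  }
  set.seed(seed)
  coords <- as.matrix(expand.grid(
    x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
    z = seq_len(grid_shape[3])
  ))
  centers <- coords[sample.int(n_vox, n_labels), , drop = FALSE]

  # nearest-center assignment; each center voxel maps to itself, so every
  # label gets >= 1 voxel; Voronoi cells on a convex grid are contiguous
  labels <- integer(n_vox)
  c2 <- rowSums(centers^2)
  chunk <- 4096L
  for (start in seq(1L, n_vox, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_vox)
    d2 <- outer(rowSums(coords[idx, , drop = FALSE]^2), c2, "+") -
      2 * coords[idx, , drop = FALSE] %*% t(centers)
    labels[idx] <- max.col(-d2, ties.method = "first")
  }
  dim(labels) <- grid_shape

  label_table <- tibble(
    label = seq_len(n_labels),
    parcel_id = sprintf("p%04d", seq_len(n_labels)),
    compartment = rep(c("cortical", "subcortical", "cerebellar"),
                      times = c(n_cortical, n_subcortical, n_cerebellar))
  )
  structure(
    list(labels = labels, label_table = label_table,
         voxel_volume = as.numeric(voxel_volume)),
    class = "parcel_atlas"
  )
}

#' @export
print.parcel_atlas <- function(x, ...) {
  cat("<parcel_atlas>\n")
  cat(sprintf("  grid: %s voxels (voxel volume %g mm^3)\n",
              paste(dim(x$labels), collapse = " x "), x$voxel_volume))
  comp <- table(x$label_table$compartment)
  cat(sprintf("  labels: %d (%s)\n", nrow(x$label_table),
              paste(sprintf("%s %d", names(comp), comp), collapse = ", ")))
  invisible(x)
}

#' Aggregate a voxel map into parcel values
#'
#' Compresses a voxel-wise gray-matter map to one value per atlas label.
#' With `reduction = "sum"` the voxel values are summed and scaled by the
#' voxel volume, so modulated gray-matter maps yield parcel volumes in mm^3;
#' `"mean"` averages the voxel values instead.
#'
#' @param voxel_map 3D numeric array with the atlas grid dimensions.
#' @param atlas A `parcel_atlas`.
#' @param reduction `"sum"` (default; volume-preserving) or `"mean"`.
#' @return Tibble with one row per label, in label-table order:
#'   `label`, `parcel_id`, `compartment`, `value`.
#' @export
aggregate_voxels_to_parcels <- function(voxel_map, atlas,
                                        reduction = c("sum", "mean")) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  reduction <- match.arg(reduction)
  if (!is.numeric(voxel_map) || !identical(dim(voxel_map), dim(atlas$labels))) {
    abort(sprintf(
      "voxel map dimensions (%s) do not match the atlas grid (%s).",
      paste(dim(voxel_map) %||% length(voxel_map), collapse = " x "),
      paste(dim(atlas$labels), collapse = " x ")
    ))
  }
  labs <- atlas$label_table$label
  inside <- atlas$labels > 0
  lab_in <- atlas$labels[inside]
  counts <- tabulate(lab_in, nbins = max(labs))
  if (any(counts[labs] == 0)) {
    abort(sprintf("atlas label(s) with zero voxels: %s.",
                  paste(labs[counts[labs] == 0], collapse = ", ")))
  }
  sums <- rowsum(as.numeric(voxel_map[inside]), group = lab_in)
  sums <- sums[match(labs, as.integer(rownames(sums))), 1]
  value <- switch(reduction,
    sum = sums * atlas$voxel_volume,
    mean = sums / counts[labs]
  )
  mutate(atlas$label_table, value = unname(value))
}

#' Compress a cohort of voxel maps into a parcel table
#'
#' Applies [aggregate_voxels_to_parcels()] to each subject's map and stacks
#' the results into the wide subjects-by-parcels table used by all downstream
#' statistics.  Row order follows the input list order.
#'
#' @param voxel_maps Named list of 3D arrays; names are subject ids.
#' @param atlas A `parcel_atlas`.
#' @inheritParams aggregate_voxels_to_parcels
#' @return Tibble: `subject_id` plus one column per parcel.
#' @export
compress_cohort <- function(voxel_maps, atlas, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (!is.list(voxel_maps) || is.null(names(voxel_maps)) ||
      any(names(voxel_maps) == "")) {
    abort("`voxel_maps` must be a named list (names = subject ids).")
  }
  rows <- purrr::imap(voxel_maps, function(map, id) {
    agg <- tryCatch(
      aggregate_voxels_to_parcels(map, atlas, reduction),
      error = function(e) {
        abort(sprintf("aggregation failed for subject '%s': %s", id,
                      conditionMessage(e)))
      }
    )
    setNames(agg$value, agg$parcel_id)
  })
  bind_cols(
    tibble(subject_id = names(voxel_maps)),
    as_tibble(do.call(rbind, rows))
  )
}

#' Write / read an atlas as a NIfTI label image plus a label-table TSV
#'
#' @param atlas A `parcel_atlas`.
#' @param nifti_path Path for the NIfTI-1 label image.
#' @param table_path Path for the TSV with columns label, parcel_id,
#'   compartment.
#' @return `write_atlas()` returns the paths invisibly; `read_atlas()`
#'   returns a `parcel_atlas`.
#' @export
write_atlas <- function(atlas, nifti_path, table_path) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  vdim <- atlas$voxel_volume^(1 / 3)
  arr <- atlas$labels
  attr(arr, "pixdim") <- c(vdim, vdim, vdim)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int32"), nifti_path)
  readr::write_tsv(atlas$label_table, table_path)
  invisible(c(nifti_path, table_path))
}

#' @param check_labels Validate that grid labels and table labels agree.
#' @rdname write_atlas
#' @export
read_atlas <- function(nifti_path, table_path, check_labels = TRUE) {
  img <- RNifti::readNifti(nifti_path)
  label_table <- readr::read_tsv(table_path, show_col_types = FALSE)
  need <- c("label", "parcel_id", "compartment")
  if (!all(need %in% names(label_table))) {
    abort("label table must have columns label, parcel_id, compartment.")
  }
  labels <- array(as.integer(round(as.array(img))), dim = dim(img))
  if (check_labels) {
    in_grid <- sort(unique(labels[labels > 0]))
    if (!setequal(in_grid, label_table$label)) {
      abort("labels in the image and in the label table do not agree.")
    }
  }
  vox <- prod(RNifti::pixdim(img)[1:3])
  structure(
    list(labels = labels,
         label_table = as_tibble(label_table[, need]),
         voxel_volume = vox),
    class = "parcel_atlas"
  )
}
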