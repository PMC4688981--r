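#' Read and write binary masks as NIfTI
#'
#' Masks are stored as NIfTI-1 (`.nii` / `.nii.gz`) with the grid geometry
#' in the header: spacing in `pixdim`, origin in the affine translation.
#' Reading coerces any non-binary labels to 0/1 with a warning. Writing then
#' reading reproduces voxels, spacing and origin exactly.
#'
#' @param path File path.
#' @param volume A [label_volume()].
#' @param frame Frame tag attached to the volume on read. Default `"LPS"`.
#' @return `read_mask()` returns a [label_volume()]; `write_mask()` returns
#'   `path` invisibly.
#' @name mask-io
NULL

#' @rdname mask-io
#' @export
read_mask <- function(path, frame = "LPS") {
  if (!file.exists(path)) {
    stop(sprintf("mask file not found: %s", path), call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop(sprintf("expected a 3D mask, got %d dimension(s): %s",
                 length(dim(arr)), path), call. = FALSE)
  }
  vals <- unique(as.vector(arr))
  if (!all(vals %in% c(0, 1))) {
    warning(sprintf("mask %s contains labels other than {0,1}; coercing nonzero to 1",
                    basename(path)), call. = FALSE)
  }
  xf <- RNifti::xform(img)
  label_volume(arr != 0, spacing = RNifti::pixdim(img)[1:3],
               origin = as.numeric(xf[1:3, 4]), frame = frame)
}

#' @rdname mask-io
#' @export
write_mask <- function(volume, path) {
  stopifnot(is_label_volume(volume))
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing_mm
  m <- rbind(cbind(diag(volume$spacing_mm), volume$origin_mm), c(0, 0, 0, 1))
  m <- structure(m, code = 2L)
  RNifti::qform(img) <- m
  RNifti::sform(img) <- m
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write landmark files
#'
#' JSON dialect:
#' `{"c5_anterior_tubercle": [x, y, z], "infraglenoid_tubercle": [x, y, z],
#' "frame": "LPS"}` with coordinates in mm. Unknown keys are ignored; a
#' missing landmark key is an error. A missing `frame` defaults to `"LPS"`.
#'
#' @param path File path.
#' @param landmarks A [landmark_set()].
#' @return `read_landmarks()` returns a [landmark_set()];
#'   `write_landmarks()` returns `path` invisibly.
#' @name landmark-io
NULL

#' @rdname landmark-io
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("landmark file not found: %s", path), call. = FALSE)
  }
  obj <- jsonlite::fromJSON(path)
  for (key in c("c5_anterior_tubercle", "infraglenoid_tubercle")) {
    if (is.null(obj[[key]])) {
      stop(sprintf("landmark file %s is missing key \"%s\"",
                   basename(path), key), call. = FALSE)
    }
  }
  landmark_set(obj$c5_anterior_tubercle, obj$infraglenoid_tubercle,
               frame = if (is.null(obj$frame)) "LPS" else obj$frame)
}

#' @rdname landmark-io
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  jsonlite::write_json(
    list(c5_anterior_tubercle = landmarks$c5_anterior_tubercle,
         infraglenoid_tubercle = landmarks$infraglenoid_tubercle,
         frame = landmarks$frame),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Sections `synthetic`, `fusion` and `experiment` (all optional) override
#' the package defaults; unknown keys raise an error so typos do not pass
#' silently. See [synthetic_config()], [staple()] and
#' [run_loo_experiment()] for the meaning of each field.
#'
#' @param path YAML file.
#' @return List with elements `synthetic` (a [synthetic_config()]), `fusion`
#'   (named list of [staple()] arguments) and `experiment` (named list:
#'   `k_values`, `random_limit`, `margin_mode`, `margin_value`,
#'   `confidence`, `seed`).
#' @export
read_pipeline_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- c("synthetic", "fusion", "experiment")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown config section(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  syn_args <- raw$synthetic %||% list()
  bad <- setdiff(names(syn_args), names(formals(synthetic_config)))
  if (length(bad)) {
    stop("unknown synthetic config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(syn_args$grid_shape)) {
    syn_args$grid_shape <- as.integer(unlist(syn_args$grid_shape))
  }
  synthetic <- do.call(synthetic_config, syn_args)

  fusion <- raw$fusion %||% list()
  bad <- setdiff(names(fusion),
                 c("prior", "tol", "max_iter", "init_performance", "threshold"))
  if (length(bad)) {
    stop("unknown fusion config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  exp_defaults <- list(k_values = 2:8, random_limit = 7L,
                       margin_mode = "relative", margin_value = 0.10,
                       confidence = 0.90, seed = 1L)
  exp_raw <- raw$experiment %||% list()
  bad <- setdiff(names(exp_raw), names(exp_defaults))
  if (length(bad)) {
    stop("unknown experiment config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  experiment <- utils::modifyList(exp_defaults, exp_raw)
  experiment$k_values <- as.integer(unlist(experiment$k_values))
  if (any(experiment$k_values < 1L) ||
      any(experiment$k_values > synthetic$n_atlases - 1L)) {
    stop("experiment k_values must lie in [1, n_atlases - 1]", call. = FALSE)
  }
  list(synthetic = synthetic, fusion = fusion, experiment = experiment)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
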