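# On-disk formats: PNG for images and masks (lossless, single channel),
# JSON for boxes and reports, CSV for manifests and grids, YAML for run
# configuration. No bespoke binary formats.

#' Write a dataset to disk
#'
#' Per sample: an 8-bit grayscale PNG image, one 0/255 PNG per instance
#' mask, and a record in `boxes.json`
#' (`{image_id, instance_id, xmin, ymin, xmax, ymax}`). A `manifest.csv`
#' lists every sample id with its split and budget flags when a split is
#' supplied. Writing is deterministic: the same dataset yields
#' byte-identical manifests and box files.
#'
#' @param samples List of `seg_sample` objects.
#' @param dir Output directory (created if absent).
#' @param split Optional [split_dataset()] result used to tag the
#'   manifest.
#' @param budgets Optional budget fractions to flag nested subsets in the
#'   manifest.
#' @param force Overwrite an existing non-empty directory (default
#'   `FALSE`).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(samples, dir, split = NULL, budgets = NULL,
                          force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force) {
    abort("output directory exists and is not empty; use `force = TRUE`")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  box_records <- list()
  for (s in samples) {
    png::writePNG(t_img(s$image), file.path(dir, paste0(s$id, ".png")))
    for (j in seq_along(s$masks)) {
      png::writePNG(t_img(s$masks[[j]]),
                    file.path(dir, sprintf("%s_mask%02d.png", s$id, j)))
    }
    for (j in seq_len(nrow(s$boxes))) {
      b <- s$boxes[j, ]
      box_records[[length(box_records) + 1L]] <- list(
        image_id = s$id, instance_id = b$instance,
        xmin = b$xmin, ymin = b$ymin, xmax = b$xmax, ymax = b$ymax)
    }
  }
  jsonlite::write_json(box_records, file.path(dir, "boxes.json"),
                       auto_unbox = TRUE, digits = NA)
  ids <- vapply(samples, function(s) s$id, character(1))
  man <- tibble(id = ids, n_instances = vapply(samples, function(s)
    length(s$masks), numeric(1)))
  if (!is.null(split)) {
    split_of <- function(id) {
      for (nm in names(split)) {
        if (id %in% vapply(split[[nm]], function(s) s$id, character(1))) {
          return(nm)
        }
      }
      NA_character_
    }
    man$split <- vapply(man$id, split_of, character(1))
    if (!is.null(budgets)) {
      for (f in budgets) {
        sub_ids <- vapply(budget_subset(split$train, f), function(s) s$id,
                          character(1))
        man[[sprintf("budget_%03d", round(100 * f))]] <- man$id %in% sub_ids
      }
    }
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

# R image matrices are row=y; PNG wants the same orientation via writePNG
# on a matrix whose rows are image rows. Round-trip is tested.
t_img <- function(m) {
  m[m > 1] <- 1
  m[m < 0] <- 0
  m
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A list of `seg_sample` objects (with boxes re-read from
#'   `boxes.json`).
#' @export
read_dataset <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  recs <- jsonlite::read_json(file.path(dir, "boxes.json"),
                              simplifyVector = TRUE)
  lapply(man$id, function(id) {
    img <- png::readPNG(file.path(dir, paste0(id, ".png")))
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    mask_files <- sort(list.files(dir, sprintf("^%s_mask[0-9]+\\.png$", id),
                                  full.names = TRUE))
    masks <- lapply(mask_files, function(f) {
      m <- png::readPNG(f)
      if (length(dim(m)) == 3L) m <- m[, , 1L]
      matrix(as.integer(m > 0.5), nrow(m), ncol(m))
    })
    bx <- recs[recs$image_id == id, , drop = FALSE]
    union_mask <- Reduce(pmax, masks)
    structure(
      list(id = id, image = img, masks = masks, union_mask = union_mask,
           boxes = tibble(instance = bx$instance_id, xmin = bx$xmin,
                          ymin = bx$ymin, xmax = bx$xmax, ymax = bx$ymax)),
      class = "seg_sample"
    )
  })
}

config_schema <- list(
  scene = c("image_size", "n_instances", "shape_families", "fg_mean",
            "bg_mean", "noise_sd", "blur_sigma", "seed"),
  run = c("prompt_mode", "distill_mode", "phase1_epochs", "phase2_epochs",
          "teacher_epochs", "lr", "phase1_lr", "cosine", "batch_size"),
  distill = c("temperature", "lambda_main", "lambda_vlr", "alpha_pos",
              "gamma", "tau_square_rescale"),
  spec = c("image_size", "embed_dim", "fused_channels", "n_sparse", "bins",
           "student_width", "teacher_width", "encoder_width", "adapter_dim",
           "decoder_rounds", "heads"),
  dataset = c("n_samples", "test_frac", "val_frac", "split_seed")
)

#' Read and validate a YAML run configuration
#'
#' The file may contain any of the sections `scene`, `run`, `distill`,
#' `spec`, `dataset`. Validation is strict: unknown sections or keys are
#' rejected, so experiment definitions cannot silently drift. Each
#' present section is passed through its constructor
#' ([scene_config()], [run_config()], [distill_config()],
#' [model_spec()]).
#'
#' @param path Path to a YAML file.
#' @return A named list with the constructed configuration objects.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), names(config_schema))
  if (length(bad)) abort(paste0("unknown config section(s): ",
                                paste(bad, collapse = ", ")))
  for (sec in names(raw)) {
    unknown <- setdiff(names(raw[[sec]]), config_schema[[sec]])
    if (length(unknown)) {
      abort(paste0("unknown key(s) in [", sec, "]: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  out <- list()
  if (!is.null(raw$scene)) out$scene <- do.call(scene_config, raw$scene)
  if (!is.null(raw$run)) out$run <- do.call(run_config, raw$run)
  if (!is.null(raw$distill)) out$distill <- do.call(distill_config, raw$distill)
  if (!is.null(raw$spec)) out$spec <- do.call(model_spec, raw$spec)
  if (!is.null(raw$dataset)) out$dataset <- raw$dataset
  out
}

#' Write a configuration list back to YAML
#'
#' Round-trips the sections accepted by [read_config()].
#'
#' @param cfg A named list of configuration objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  plain <- lapply(cfg, function(x) {
    x <- unclass(x)
    x[!vapply(x, is.null, logical(1))]
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' A single-file archive holding the object plus a JSON manifest
#' (configuration hash, phase, seed) used to verify prerequisites when
#' reloading.
#'
#' @param object A `detector` or `ldseg_model`.
#' @param path Output file.
#' @param phase Training phase that produced the object.
#' @param seed Seed that produced the object.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(object, path, phase, seed) {
  manifest <- list(
    package = "ldseg",
    class = class(object)[1L],
    phase = phase,
    seed = seed,
    spec_hash = rlang::hash(object$spec)
  )
  saveRDS(list(manifest = manifest, object = object), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expect_class Required class of the archived object (optional).
#' @return `load_checkpoint()`: the archived object, with the manifest in
#'   attribute `"manifest"`.
#' @export
load_checkpoint <- function(path, expect_class = NULL) {
  if (!file.exists(path)) {
    abort(paste0("missing checkpoint: ", path))
  }
  arc <- readRDS(path)
  if (!is.list(arc) || is.null(arc$manifest)) {
    abort("not an ldseg checkpoint archive")
  }
  if (!is.null(expect_class) && arc$manifest$class != expect_class) {
    abort(paste0("checkpoint holds a '", arc$manifest$class,
                 "', expected '", expect_class, "'"))
  }
  structure(arc$object, manifest = arc$manifest)
}
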