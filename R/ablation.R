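#' Run a prompt-mode / distillation / budget ablation grid
#'
#' Trains and evaluates the full two-phase pipeline for every requested
#' combination of prompt mode, distillation mode, annotation budget, and
#' seed, reusing shared stages within a call: the teacher is fitted once
#' per (budget, seed) and each distilled student once per
#' (distill mode, budget, seed), since phase-2 arms differing only in
#' prompt mode share them. At every budget the identical nested subset
#' supplies both the phase-1 boxes and the phase-2 masks (supervision
#' parity).
#'
#' With `out_dir` set, each finished cell is written to
#' `<out_dir>/cell-<prompt>-<distill>-<budget>-<seed>.json` and a rerun
#' resumes by skipping cells whose file exists. A failing cell is
#' recorded (`status = "error"`) and the grid continues.
#'
#' @param data A [split_dataset()] result (`train`/`val`/`test`).
#' @param base_cfg A [run_config()]; its prompt/distill modes are
#'   overridden per cell.
#' @param prompt_modes,distill_modes,budgets,seeds Grid axes.
#' @param spec A [model_spec()].
#' @param dcfg A [distill_config()].
#' @param out_dir Optional directory for per-cell results (resumability).
#' @param boot_B Bootstrap resamples per cell (default 200).
#' @return A tibble of class `ablation_grid`, one row per cell, with the
#'   evaluation means, Dice CI bounds, and a `cases` list-column of
#'   per-case scores.
#' @export
run_ablation_grid <- function(data, base_cfg = run_config(),
                              prompt_modes = c("box", "dense", "sparse",
                                               "dense+sparse"),
                              distill_modes = "ld_main_vlr",
                              budgets = 1, seeds = c(10L, 42L, 123L),
                              spec = model_spec(), dcfg = distill_config(),
                              out_dir = NULL, boot_B = 200L) {
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  grid <- expand.grid(prompt_mode = prompt_modes, distill_mode = distill_modes,
                      budget = budgets, seed = seeds,
                      stringsAsFactors = FALSE)
  teachers <- new.env(parent = emptyenv())
  students <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    cell <- grid[r, ]
    key <- sprintf("cell-%s-%s-%s-%s", cell$prompt_mode, cell$distill_mode,
                   format(cell$budget), cell$seed)
    cell_file <- if (!is.null(out_dir)) file.path(out_dir, paste0(key, ".json"))
    if (!is.null(out_dir) && file.exists(cell_file)) {
      rows[[r]] <- cell_from_json(cell_file)
      next
    }
    rows[[r]] <- tryCatch({
      row <- run_ablation_cell(data, base_cfg, cell, spec, dcfg,
                               teachers, students, boot_B)
      if (!is.null(out_dir)) cell_to_json(row, cell_file)
      row
    }, error = function(e) {
      tibble(prompt_mode = cell$prompt_mode, distill_mode = cell$distill_mode,
             budget = cell$budget, seed = cell$seed,
             dice = NA_real_, iou = NA_real_, acc = NA_real_,
             hd = NA_real_, assd = NA_real_,
             dice_lower = NA_real_, dice_upper = NA_real_,
             n_test = length(data$test), status = "error",
             message = conditionMessage(e), cases = list(tibble()))
    })
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ablation_grid", class(out))
  out
}

run_ablation_cell <- function(data, base_cfg, cell, spec, dcfg,
                              teachers, students, boot_B) {
  cfg <- base_cfg
  cfg$prompt_mode <- cell$prompt_mode
  cfg$distill_mode <- cell$distill_mode
  train <- budget_subset(data$train, cell$budget)
  train_ids <- vapply(train, function(s) s$id, character(1))

  needs_student <- cell$prompt_mode %in% c("dense", "sparse", "dense+sparse")
  student <- NULL
  if (needs_student) {
    skey <- sprintf("%s-%s-%s", cell$distill_mode, format(cell$budget),
                    cell$seed)
    student <- get0(skey, envir = students)
    if (is.null(student)) {
      teacher <- NULL
      if (cell$distill_mode != "none") {
        tkey <- sprintf("%s-%s", format(cell$budget), cell$seed)
        teacher <- get0(tkey, envir = teachers)
        if (is.null(teacher)) {
          teacher <- pretrain_teacher(train, spec, cfg, seed = cell$seed)
          assign(tkey, teacher, envir = teachers)
        }
      }
      student <- phase1_distill(teacher, train, cfg, dcfg, spec,
                                seed = cell$seed)
      # supervision parity: the ids feeding phase-1 boxes must be the ids
      # feeding phase-2 masks
      student$train_ids <- train_ids
      assign(skey, student, envir = students)
    }
    stopifnot(identical(sort(student$train_ids), sort(train_ids)))
  }
  model <- phase2_segment(train, cfg, student, spec, seed = cell$seed)
  report <- evaluate_model(model, data$test, boot_B = boot_B,
                           boot_seed = cell$seed)
  sm <- report$summary
  tibble(prompt_mode = cell$prompt_mode, distill_mode = cell$distill_mode,
         budget = cell$budget, seed = cell$seed,
         dice = sm$mean[sm$metric == "dice"],
         iou = sm$mean[sm$metric == "iou"],
         acc = sm$mean[sm$metric == "acc"],
         hd = sm$mean[sm$metric == "hd"],
         assd = sm$mean[sm$metric == "assd"],
         dice_lower = sm$ci_lower[sm$metric == "dice"],
         dice_upper = sm$ci_upper[sm$metric == "dice"],
         n_test = length(data$test), status = "ok", message = "",
         cases = list(report$cases))
}

cell_to_json <- function(row, path) {
  obj <- as.list(row[setdiff(names(row), "cases")])
  obj$cases <- row$cases[[1L]]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

cell_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cases <- tibble::as_tibble(obj$cases)
  obj$cases <- NULL
  row <- tibble::as_tibble(obj)
  row$cases <- list(cases)
  row
}
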