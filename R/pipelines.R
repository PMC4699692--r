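# Replayable multi-step segmentation workflows.  A PipelineRecipe is an
# ordered list of parameterized steps over a registered op vocabulary; every
# executed step appends to the dataset's action log, and replay on identical
# input is deterministic.  The 13-step mitotic-cell organelle workflow and
# the ER global-threshold workflow are shipped as builders.

#' One step of a pipeline recipe
#' @param op registered operation name (see [recipe_ops()])
#' @param params parameter record (plain values only, so recipes serialize)
#' @export
recipe_step <- function(op, params = list()) {
  structure(list(op = op, params = params), class = "RecipeStep")
}

#' An ordered, parameterized, replayable workflow
#' @param name recipe name
#' @param steps list of [recipe_step()]
#' @param description free-text description
#' @param seed RNG seed set before execution (replays bit-identically)
#' @export
pipeline_recipe <- function(name, steps = list(), description = "",
                            seed = 1) {
  ops <- vapply(steps, `[[`, "", "op")
  unknown <- setdiff(ops, names(recipe_ops()))
  if (length(unknown))
    stop("unknown recipe op(s): ", paste(unknown, collapse = ", "))
  structure(list(name = name, description = description, seed = seed,
                 steps = steps), class = "PipelineRecipe")
}

#' @export
print.PipelineRecipe <- function(x, ...) {
  cat(sprintf("<PipelineRecipe> %s: %d step(s), seed %d\n", x$name,
              length(x$steps), x$seed))
  for (i in seq_along(x$steps))
    cat(sprintf("  %2d. %s\n", i, x$steps[[i]]$op))
  invisible(x)
}

#' Serialize / restore a recipe as YAML
#' @param recipe a `PipelineRecipe`
#' @param path file path
#' @export
save_recipe <- function(recipe, path) {
  yaml::write_yaml(list(name = recipe$name, description = recipe$description,
                        seed = recipe$seed,
                        steps = lapply(recipe$steps, function(s)
                          list(op = s$op, params = s$params))), path)
  invisible(path)
}

#' @rdname save_recipe
#' @export
load_recipe <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_recipe(y$name,
                  lapply(y$steps, function(s)
                    recipe_step(s$op, s$params %||% list())),
                  description = y$description %||% "", seed = y$seed %||% 1)
}

# ---------------------------------------------------------------------------
# op registry: each op is function(state, p) -> state, where state holds
# `ds` (LayeredDataset) and `aux` (named list of auxiliary volumes).

get_binding <- function(state, name) {
  if (name == "image") return(img3d(state$ds))
  if (name %in% c("selection", "mask", "model"))
    return(get_layer(state$ds, name))
  if (startsWith(name, "aux:")) {
    v <- state$aux[[substring(name, 5)]]
    if (is.null(v)) stop("missing auxiliary volume: ", name)
    return(v)
  }
  stop("unknown binding: ", name)
}

set_binding <- function(state, name, vol) {
  if (name == "image") {
    state$ds$image[, , 1, ] <- clip_dtype(vol, state$ds)
  } else if (name %in% c("selection", "mask")) {
    state$ds[[name]] <- array(as.integer(vol != 0), ds_dim(state$ds))
  } else if (startsWith(name, "aux:")) {
    state$aux[[substring(name, 5)]] <- vol
  } else stop("unknown binding: ", name)
  state
}

model_material_id <- function(state, name) {
  hit <- match(name, state$ds$materials$name)
  if (is.na(hit)) {
    state$ds <- add_material(state$ds, name)
    hit <- nrow(state$ds$materials)
  }
  list(state = state, id = hit)
}

assign_selection_to_model <- function(state, material) {
  mi <- model_material_id(state, material)
  state <- mi$state
  model <- get_layer(state$ds, "model")
  sel <- get_layer(state$ds, "selection")
  model[sel != 0] <- mi$id
  state$ds$model <- model
  state$ds$selection <- NULL
  state
}

background_level <- function(state) {
  v <- img3d(state$ds)
  model <- get_layer(state$ds, "model")
  stats::median(v[model == 0])
}

.ops <- new.env()

.ops$diffusion <- function(state, p) {
  state$ds <- anisotropic_diffusion(state$ds,
    iterations = p$iterations %||% 8, kappa = p$kappa %||% 25,
    lambda = p$lambda %||% 0.25, dims = p$dims %||% "2d")
  state
}

.ops$bottomhat <- function(state, p) {
  vol <- img3d(state$ds)
  out <- morph_vol(vol, "bottom-hat",
                   element_offsets(p$shape %||% "disk", p$radius %||% 5))
  state <- set_binding(state, p$output %||% "aux:bh", out)
  state$ds <- log_action(state$ds, "bottomhat", p)
  state
}

.ops$invert_to_aux <- function(state, p) {
  vol <- img3d(state$ds)
  state <- set_binding(state, p$output %||% "aux:bh",
                       dtype_max(state$ds) - vol)
  state$ds <- log_action(state$ds, "invert_to_aux", p)
  state
}

.ops$frangi_model <- function(state, p) {
  vol <- get_binding(state, p$input %||% "aux:bh")
  tmp <- state$ds
  tmp$image[, , 1, ] <- vol * (dtype_max(tmp) / max(max(vol), 1e-9))
  vess <- frangi_filter(tmp, scales = p$scales %||% c(1.5, 2.5),
                        polarity = p$polarity %||% "bright",
                        planes = p$planes %||% "sequential-planes")
  sel <- vess >= (p$threshold %||% 0.15)
  if (!is.null(p$intensity_window)) {
    v0 <- img3d(state$ds)
    sel <- sel & v0 >= p$intensity_window[1] & v0 <= p$intensity_window[2]
  }
  state$ds$selection <- array(as.integer(sel), ds_dim(state$ds))
  state <- assign_selection_to_model(state, p$material %||% "ER")
  state$ds <- log_action(state$ds, "frangi_model", p)
  state
}

.ops$replace_background <- function(state, p) {
  bg <- background_level(state)
  v <- img3d(state$ds)
  model <- get_layer(state$ds, "model")
  ids <- match(p$materials, state$ds$materials$name)
  if (anyNA(ids)) stop("replace_background: unknown material(s): ",
                       paste(p$materials[is.na(ids)], collapse = ", "))
  grow <- p$grow %||% 2
  zone <- array(as.integer(model %in% ids), dim(model))
  if (grow > 0)
    zone <- morph_vol(zone, "dilation", element_offsets("ball", grow))
  repl <- zone >= 0.5
  if (!is.null(p$intensity_window))
    repl <- repl & v >= p$intensity_window[1] & v <= p$intensity_window[2]
  v[repl] <- bg
  state$ds$image[, , 1, ] <- v
  state$ds <- log_action(state$ds, "replace_background",
                         list(materials = p$materials, level = bg))
  state
}

.ops$threshold <- function(state, p) {
  state$ds <- threshold_bw(state$ds, p$window, scope = p$scope %||% "whole")
  state
}

.ops$set_central_mask <- function(state, p) {
  m <- state$aux$central_mask
  if (is.null(m))
    stop("step requires a central-area mask: supply aux = list(central_mask = ...)",
         " to run_recipe()")
  state$ds <- set_layer(state$ds, "mask", m, op = "set_central_mask")
  state$ds <- threshold_bw(state$ds, p$window, scope = "masked")
  state
}

.ops$smooth_to_model <- function(state, p) {
  sel <- get_layer(state$ds, "selection")
  off <- element_offsets(p$shape %||% "ball", p$radius %||% 2)
  sm <- morph_vol(morph_vol(sel + 0, "erosion", off), "dilation", off)
  state$ds$selection <- array(as.integer(sm >= 0.5), ds_dim(state$ds))
  if (!is.null(p$min_voxels)) {
    lo <- label_objects(state$ds$selection, "3d")
    fo <- filter_objects(lo$labels, lo$table,
                         n_voxels = c(p$min_voxels, Inf))
    state$ds$selection <- array(as.integer(fo$labels > 0), ds_dim(state$ds))
  }
  if (!is.null(p$material))
    state <- assign_selection_to_model(state, p$material)
  state$ds <- log_action(state$ds, "smooth_to_model", p)
  state
}

.ops$classify_by_size <- function(state, p) {
  # smooth (erosion-dilation), then assign selection objects to materials
  # by voxel-count ranges
  sel <- get_layer(state$ds, "selection")
  if (!is.null(p$radius)) {
    off <- element_offsets("ball", p$radius)
    sel <- array(as.integer(
      morph_vol(morph_vol(sel + 0, "erosion", off), "dilation", off) >= 0.5),
      dim(sel))
  }
  lo <- label_objects(sel, "3d")
  model <- get_layer(state$ds, "model")
  for (cls in names(p$classes)) {
    rng <- p$classes[[cls]]
    ids <- lo$table$id[lo$table$n_voxels >= rng[1] &
                       lo$table$n_voxels <= rng[2]]
    if (!length(ids)) next
    mi <- model_material_id(state, cls)
    state <- mi$state
    model[array(lo$labels, dim(model)) %in% ids] <- mi$id
  }
  state$ds$model <- model
  state$ds$selection <- NULL
  state$ds <- log_action(state$ds, "classify_by_size", p)
  state
}

.ops$opening_threshold <- function(state, p) {
  v <- img3d(state$ds)
  op <- morph_vol(v, "opening",
                  element_offsets(p$shape %||% "disk", p$radius %||% 3))
  state$ds$image[, , 1, ] <- clip_dtype(op, state$ds)
  state$ds <- log_action(state$ds, "opening", p["radius"])
  state$ds <- threshold_bw(state$ds, p$window)
  state
}

.ops$combine_models <- function(state, p) {
  state$ds <- log_action(state$ds, "combine_models",
                         list(materials = state$ds$materials$name))
  state
}

.ops$noop <- function(state, p) {
  state$ds <- log_action(state$ds, "noop", p)
  state
}

#' The registered pipeline operation vocabulary
#' @return named list of op functions
#' @export
recipe_ops <- function() as.list(.ops)

#' Execute a pipeline recipe
#'
#' Runs the steps in order on the dataset.  A step failure halts execution
#' with the step index and cause, preserving the partial state for
#' inspection.  The report lists per-step timings and selection/model
#' object counts.
#'
#' @param ds a `LayeredDataset`
#' @param recipe a `PipelineRecipe`
#' @param aux named list of auxiliary volumes available to steps (e.g.
#'   `central_mask`)
#' @param keep_snapshots retain a copy of the layers after every step
#' @return list with `ds`, `report` (data.frame), optionally `snapshots`
#' @export
run_recipe <- function(ds, recipe, aux = list(), keep_snapshots = FALSE) {
  state <- list(ds = ds, aux = aux)
  set.seed(recipe$seed)
  rows <- list()
  snaps <- list()
  ops <- recipe_ops()
  for (i in seq_along(recipe$steps)) {
    st <- recipe$steps[[i]]
    t0 <- proc.time()[3]
    state <- tryCatch(ops[[st$op]](state, st$params),
      error = function(e)
        stop("recipe halted at step ", i, " (", st$op, "): ",
             conditionMessage(e), call. = FALSE))
    el <- proc.time()[3] - t0
    rows[[i]] <- data.frame(step = i, op = st$op, seconds = round(el, 3),
      n_selected = sum(get_layer(state$ds, "selection") != 0),
      n_materials = nrow(state$ds$materials))
    if (keep_snapshots) snaps[[i]] <- snapshot_layers(state$ds)
  }
  out <- list(ds = state$ds,
              report = if (length(rows)) do.call(rbind, rows) else
                data.frame(step = integer(), op = character(),
                           seconds = numeric(), n_selected = integer(),
                           n_materials = integer()))
  if (keep_snapshots) out$snapshots <- snaps
  out
}

#' Build the 13-step mitotic-cell organelle segmentation recipe
#'
#' The sequence segments a densely packed, low-contrast mitotic cell by
#' peeling off organelle classes one at a time: (1) edge-preserving
#' anisotropic diffusion; (2) bottom-hat filtering to temporarily suppress
#' all large objects; (3) tubular (vesselness) enhancement sequentially in
#' the XY and ZX planes, thresholded into the ER model; (4) ER areas
#' replaced by the background level ("degraded" image); (5) thresholding of
#' the dark singular organelles; (6) 3-D erosion-dilation smoothing and
#' size-based assignment of lysosome/peroxisome/lipid-droplet models;
#' (7) their areas replaced by background; (8) thresholding restricted to a
#' user-supplied central-area mask (chromosomes share their contrast with
#' mitochondria, so global thresholding cannot discriminate them);
#' (9) smoothing into the chromosome model; (10) background replacement and
#' a second diffusion pass; (11) grayscale opening plus thresholding for
#' mitochondria; (12) smoothing and small-object filtration into the
#' mitochondrion model; (13) combination of all models.
#'
#' All numeric parameters are recipe parameters with phantom-tuned,
#' non-canonical defaults; override via `params`.
#'
#' @param params named list overriding any step parameter record
#' @param seed recipe seed
#' @return a `PipelineRecipe` (run with [run_recipe()]; step 8 requires
#'   `aux = list(central_mask = ...)`)
#' @export
mitotic_cell_recipe <- function(params = list(), seed = 1) {
  p <- function(name, default) {
    if (!is.null(params[[name]])) utils::modifyList(default, params[[name]])
    else default
  }
  skip_bh <- isTRUE(params$skip_bottomhat)
  steps <- list(
    recipe_step("diffusion", p("diffusion",
      list(iterations = 8, kappa = 25, lambda = 0.25, dims = "2d"))),
    if (skip_bh) recipe_step("invert_to_aux", list(output = "aux:bh"))
    else recipe_step("bottomhat", p("bottomhat",
      list(radius = 5, output = "aux:bh"))),
    recipe_step("frangi_model", p("frangi",
      list(input = "aux:bh", scales = c(1.5, 2.5), polarity = "bright",
           planes = "sequential-planes", threshold = 0.15,
           intensity_window = c(55, 110), material = "ER"))),
    recipe_step("replace_background", p("replace_er",
      list(materials = "ER", grow = 1, intensity_window = c(55, 110)))),
    recipe_step("threshold", p("threshold_singulars",
      list(window = c(0, 70)))),
    recipe_step("classify_by_size", p("singulars",
      list(radius = 1,
           classes = list(peroxisome = c(25, 250),
                          lysosome = c(251, 1100),
                          LD = c(1101, 12000))))),
    recipe_step("replace_background", p("replace_singulars",
      list(materials = c("peroxisome", "lysosome", "LD"), grow = 2))),
    recipe_step("set_central_mask", p("threshold_chromosome",
      list(window = c(0, 140)))),
    recipe_step("smooth_to_model", p("chromosome",
      list(radius = 2, material = "chromosome"))),
    recipe_step("replace_background", p("replace_chromosome",
      list(materials = "chromosome", grow = 2))),
    recipe_step("opening_threshold", p("mito_threshold",
      list(shape = "ball", radius = 2, window = c(0, 150)))),
    recipe_step("smooth_to_model", p("mitochondrion",
      list(radius = 1, min_voxels = 300, material = "mitochondrion"))),
    recipe_step("combine_models", list())
  )
  pipeline_recipe("mitotic-cell-13-step", steps,
    description = "Stepwise organelle segmentation of a mitotic cell",
    seed = seed)
}

#' Run the 13-step mitotic-cell workflow on a dataset
#' @param ds a `LayeredDataset` (grayscale, dark-stained organelles)
#' @param central_mask binary volume marking the central cell area for the
#'   chromosome step; without it the run halts at step 8 requesting one
#' @param params,seed see [mitotic_cell_recipe()]
#' @return list with `ds` (model populated), `report`
#' @export
mitotic_cell_workflow <- function(ds, central_mask = NULL, params = list(),
                                  seed = 1) {
  recipe <- mitotic_cell_recipe(params, seed)
  aux <- list()
  if (!is.null(central_mask)) aux$central_mask <- central_mask
  run_recipe(ds, recipe, aux = aux)
}

#' ER segmentation by global thresholding plus quantification filtering
#'
#' For high-contrast (cytochemically stained) data: global black-and-white
#' thresholding, 3-D connected-component labelling, removal of objects
#' below a minimum volume, and assignment of the survivors to an "ER"
#' model material.
#' @param ds a `LayeredDataset`
#' @param window intensity window `c(low, high)`
#' @param min_size minimum object size in voxels (0 = plain thresholding)
#' @return list with `ds` (model populated), `table` (surviving objects)
#' @export
er_threshold_workflow <- function(ds, window, min_size = 0) {
  ds <- threshold_bw(ds, window)
  lo <- label_objects(get_layer(ds, "selection"), "3d",
                      voxel_size = ds$geometry$voxel_size,
                      units = ds$geometry$units)
  fo <- filter_objects(lo$labels, lo$table, n_voxels = c(min_size, Inf))
  ds$selection <- array(as.integer(fo$labels > 0), ds_dim(ds))
  state <- list(ds = ds, aux = list())
  state <- assign_selection_to_model(state, "ER")
  ds <- log_action(state$ds, "er_threshold_workflow",
                   list(window = window, min_size = min_size,
                        removed = fo$removed))
  list(ds = ds, table = fo$table)
}
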