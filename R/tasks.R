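#' Construct a decoding task
#'
#' A decoding task partitions a subset of the stimulus registry into M
#' mutually exclusive classes; trials whose stimulus belongs to no class are
#' excluded from that task.
#'
#' @param name task name.
#' @param classes named list, class label -> character vector of stimulus ids.
#' @param balanced logical; `TRUE` selects stratified tenfold cross-validation
#'   downstream, `FALSE` the Monte Carlo resampling scheme.
#' @return Object of class `decoding_task` with element `M` (class count).
#' @export
decoding_task <- function(name, classes, balanced) {
  if (length(classes) < 2) stop("task '", name, "': needs at least 2 classes")
  empty <- names(classes)[lengths(classes) == 0]
  if (length(empty))
    stop("task '", name, "': empty class(es) ", paste(empty, collapse = ", "),
         " - registry is missing the required stimulus family")
  all_ids <- unlist(classes, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("task '", name, "': classes are not mutually exclusive (",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "), ")")
  structure(list(name = name, classes = classes, M = length(classes),
                 balanced = isTRUE(balanced)),
            class = "decoding_task")
}

#' @export
print.decoding_task <- function(x, ...) {
  cat("<decoding_task>", x$name, "- M =", x$M,
      if (x$balanced) "(balanced)" else "(unbalanced)", "\n")
  for (nm in names(x$classes))
    cat("  ", nm, ": ", length(x$classes[[nm]]), " stimuli\n", sep = "")
  invisible(x)
}

stim_table <- function(registry) {
  st <- registry$stimuli
  nr <- registry$grid$n_rows; nc <- registry$grid$n_cols
  data.frame(
    id = names(st),
    area = vapply(st, `[[`, 0, "area"),
    crow = vapply(st, function(s) s$centroid[["row"]], 0),
    ccol = vapply(st, function(s) s$centroid[["col"]], 0),
    orientation = vapply(st, `[[`, "", "orientation"),
    all_border = vapply(st, function(s)
      all(s$lit_cells[, 1] %in% c(0, nr - 1) |
          s$lit_cells[, 2] %in% c(0, nc - 1)), NA),
    none_border = vapply(st, function(s)
      !any(s$lit_cells[, 1] %in% c(0, nr - 1) |
           s$lit_cells[, 2] %in% c(0, nc - 1)), NA),
    bbox_h = vapply(st, function(s) diff(range(s$lit_cells[, 1])) + 1, 0),
    bbox_w = vapply(st, function(s) diff(range(s$lit_cells[, 2])) + 1, 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# balanced if the largest class has at most 1.5x the stimuli of the smallest
is_balanced <- function(classes) {
  n <- lengths(classes)
  max(n) <= 1.5 * min(n)
}

#' Build the ten standard decoding tasks
#'
#' Derives the ten decoding tasks from stimulus geometry (centroid relative to
#' the grid centre, lit-cell/border relations, area and shape), so a custom
#' registry produces consistent tasks as long as the required families exist:
#'
#' * `left_vs_right`, `superior_vs_inferior` (M = 2): centroid strictly left/
#'   right (above/below) of the grid centre column (row); centred stimuli are
#'   excluded.
#' * `vertical_bars`, `horizontal_bars` (M = 5): one positional level per
#'   column (row) for the 1-cell-wide bar stimuli.
#' * `corners` (M = 4): stimuli whose centroid lies strictly inside one of the
#'   four quadrants and that are square blocks or single cells.
#' * `outer_vs_middle` (M = 2): all lit cells on the border ring vs none.
#' * `bars` (M = 3): 1-block vs 3-cell bars vs 5-cell bars.
#' * `blocks` (M = 3): 1-block vs 2x2 vs 3x3 square blocks.
#' * `luminosities` (M = 5): lit-area levels 1/3/4/5/9 over all stimuli.
#' * `outer_vs_center` (M = 2): large peripheral shapes (rings, corner cells,
#'   corner blocks) vs small central shapes (area <= 4, interior, centroid at
#'   the centre), probing the compensation of luminosity by eccentricity.
#'
#' @param registry a [build_stimulus_registry()] result containing the default
#'   families.
#' @return Named list of ten [decoding_task()] objects.
#' @export
build_task_registry <- function(registry) {
  tb <- stim_table(registry)
  g <- registry$grid
  mr <- (g$n_rows - 1) / 2; mc <- (g$n_cols - 1) / 2
  eps <- 1e-9
  cls <- function(...) {
    x <- list(...)
    lapply(x, function(f) tb$id[f])
  }

  tasks <- list()

  lr <- cls(left = tb$ccol < mc - eps, right = tb$ccol > mc + eps)
  tasks$left_vs_right <- decoding_task("left_vs_right", lr, is_balanced(lr))

  si <- cls(superior = tb$crow < mr - eps, inferior = tb$crow > mr + eps)
  tasks$superior_vs_inferior <-
    decoding_task("superior_vs_inferior", si, is_balanced(si))

  vb <- tb$orientation == "vertical" & tb$bbox_w == 1
  vcls <- lapply(0:(g$n_cols - 1), function(cc) tb$id[vb & tb$ccol == cc])
  names(vcls) <- sprintf("col%d", 0:(g$n_cols - 1))
  tasks$vertical_bars <-
    decoding_task("vertical_bars", vcls, is_balanced(vcls))

  hb <- tb$orientation == "horizontal" & tb$bbox_h == 1
  hcls <- lapply(0:(g$n_rows - 1), function(r) tb$id[hb & tb$crow == r])
  names(hcls) <- sprintf("row%d", 0:(g$n_rows - 1))
  tasks$horizontal_bars <-
    decoding_task("horizontal_bars", hcls, is_balanced(hcls))

  square <- tb$bbox_h == tb$bbox_w & tb$area == tb$bbox_h * tb$bbox_w
  co <- cls(top_left = square & tb$crow < mr - eps & tb$ccol < mc - eps,
            top_right = square & tb$crow < mr - eps & tb$ccol > mc + eps,
            bottom_left = square & tb$crow > mr + eps & tb$ccol < mc - eps,
            bottom_right = square & tb$crow > mr + eps & tb$ccol > mc + eps)
  tasks$corners <- decoding_task("corners", co, is_balanced(co))

  om <- cls(outer = tb$all_border, middle = tb$none_border)
  tasks$outer_vs_middle <-
    decoding_task("outer_vs_middle", om, is_balanced(om))

  bar <- tb$orientation %in% c("vertical", "horizontal")
  ba <- cls(`1-block` = tb$area == 1 & !bar,
            `3-bars` = bar & tb$area == 3,
            `5-bars` = bar & tb$area == 5)
  tasks$bars <- decoding_task("bars", ba, is_balanced(ba))

  bl <- cls(`1-block` = square & tb$area == 1,
            `4-blocks` = square & tb$area == 4,
            `9-blocks` = square & tb$area == 9)
  tasks$blocks <- decoding_task("blocks", bl, is_balanced(bl))

  lum_levels <- c(1, 3, 4, 5, 9)
  lu <- lapply(lum_levels, function(a) tb$id[tb$area == a])
  names(lu) <- sprintf("area%d", lum_levels)
  tasks$luminosities <- decoding_task("luminosities", lu, is_balanced(lu))

  central <- tb$area <= 4 & tb$none_border &
    abs(tb$crow - mr) <= 0.5 + eps & abs(tb$ccol - mc) <= 0.5 + eps
  ring <- tb$all_border & tb$area >= 4
  corner_block <- square & tb$area >= 4 &
    pmax(abs(tb$crow - mr), abs(tb$ccol - mc)) >= 1 - eps
  oc <- cls(outer = ring | corner_block, center = central)
  tasks$outer_vs_center <-
    decoding_task("outer_vs_center", oc, is_balanced(oc))

  tasks
}

#' Class membership of a stimulus within a task
#'
#' @param task a [decoding_task()].
#' @param stimulus_id stimulus identifier (must exist in `registry` when
#'   given).
#' @param registry optional registry used to validate the id.
#' @return The class label, or `NA_character_` if the stimulus is excluded
#'   from the task.
#' @export
assign_class <- function(task, stimulus_id, registry = NULL) {
  if (!is.null(registry) && !stimulus_id %in% stimulus_ids(registry))
    stop("unknown stimulus id: '", stimulus_id, "'")
  hit <- names(task$classes)[vapply(task$classes,
                                    function(ids) stimulus_id %in% ids, NA)]
  if (length(hit) == 0) return(NA_character_)
  hit[[1]]
}

#' Map a vector of stimulus ids to task class labels
#' @inheritParams assign_class
#' @param stimulus_ids character vector of ids.
#' @return Character vector of labels (`NA` where excluded).
#' @export
assign_classes <- function(task, stimulus_ids) {
  lab <- rep(NA_character_, length(stimulus_ids))
  for (nm in names(task$classes))
    lab[stimulus_ids %in% task$classes[[nm]]] <- nm
  lab
}

#' Serialize registry and tasks to YAML
#'
#' @param registry a stimulus registry.
#' @param tasks optional task list from [build_task_registry()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
registry_to_yaml <- function(registry, tasks = NULL, path) {
  obj <- list(
    grid = unclass(registry$grid),
    stimuli = lapply(registry$stimuli, function(s)
      list(id = s$id, gray_level = s$gray_level, orientation = s$orientation,
           lit_cells = apply(s$lit_cells, 1, function(rc)
             list(row = rc[[1]], col = rc[[2]]), simplify = FALSE)))
  )
  if (!is.null(tasks))
    obj$tasks <- lapply(tasks, function(tk)
      list(name = tk$name, balanced = tk$balanced, classes = tk$classes))
  yaml::write_yaml(obj, path)
  invisible(path)
}
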