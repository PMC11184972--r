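#' Screen grid specification
#'
#' Describes the stimulation region of the screen: an `n_rows` x `n_cols` grid
#' of equally sized squares covering most of the subject's visual field.
#' Defaults mirror a 75-inch screen (166 x 93 cm) viewed at 40 cm, divided
#' into 25 equal squares.
#'
#' @param n_rows,n_cols grid dimensions (default 5 x 5).
#' @param screen_w,screen_h screen size in cm.
#' @param viewing_distance distance from eyes to screen in cm.
#' @param stimulus_region length-4 numeric `c(x0, y0, x1, y1)` rectangle in
#'   screen coordinates (cm, origin bottom-left) containing the grid; defaults
#'   to the largest centred square fitting the screen.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows = 5L, n_cols = 5L, screen_w = 166, screen_h = 93,
                      viewing_distance = 40, stimulus_region = NULL) {
  stopifnot(n_rows >= 1, n_cols >= 1, screen_w > 0, screen_h > 0,
            viewing_distance > 0)
  if (is.null(stimulus_region)) {
    side <- min(screen_w, screen_h)
    stimulus_region <- c((screen_w - side) / 2, (screen_h - side) / 2,
                         (screen_w + side) / 2, (screen_h + side) / 2)
  }
  stopifnot(length(stimulus_region) == 4,
            stimulus_region[1] >= 0, stimulus_region[2] >= 0,
            stimulus_region[3] <= screen_w, stimulus_region[4] <= screen_h)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 screen_w = screen_w, screen_h = screen_h,
                 viewing_distance = viewing_distance,
                 stimulus_region = stimulus_region),
            class = "grid_spec")
}

#' Construct a single stimulus
#'
#' A stimulus is a set of lit grid cells rendered at a common gray level on a
#' black background (a phosphene-like solid bright shape). Cell coordinates
#' are 0-based `(row, col)` with row 0 at the top of the screen (superior
#' visual field).
#'
#' @param id unique identifier string.
#' @param lit_cells two-column integer matrix of `(row, col)` cells.
#' @param grid a [grid_spec()].
#' @param gray_level luminance fraction in `[0, 1]` (default 0.5).
#' @param orientation one of `"none"`, `"vertical"`, `"horizontal"`.
#' @return An object of class `stimulus` with derived `area` (number of lit
#'   cells) and `centroid` (fractional `(row, col)`).
#' @export
stimulus <- function(id, lit_cells, grid = grid_spec(), gray_level = 0.5,
                     orientation = c("none", "vertical", "horizontal")) {
  orientation <- match.arg(orientation)
  lit_cells <- matrix(as.integer(lit_cells), ncol = 2,
                      dimnames = list(NULL, c("row", "col")))
  if (nrow(lit_cells) == 0) stop("stimulus '", id, "': lit_cells is empty")
  if (anyDuplicated(lit_cells)) stop("stimulus '", id, "': duplicate cells")
  if (any(lit_cells[, 1] < 0) || any(lit_cells[, 1] >= grid$n_rows) ||
      any(lit_cells[, 2] < 0) || any(lit_cells[, 2] >= grid$n_cols))
    stop("stimulus '", id, "': cells outside the ", grid$n_rows, "x",
         grid$n_cols, " grid")
  if (gray_level < 0 || gray_level > 1)
    stop("gray_level must lie in [0, 1]")
  structure(list(id = id, lit_cells = lit_cells, gray_level = gray_level,
                 orientation = orientation, area = nrow(lit_cells),
                 centroid = c(row = mean(lit_cells[, 1]),
                              col = mean(lit_cells[, 2]))),
            class = "stimulus")
}

cells_rect <- function(rows, cols) as.matrix(expand.grid(row = rows, col = cols))

cell_key <- function(stim) {
  m <- stim$lit_cells[order(stim$lit_cells[, 1], stim$lit_cells[, 2]), ,
                      drop = FALSE]
  paste(paste(m[, 1], m[, 2], sep = ","), collapse = ";")
}

#' Build the stimulus registry
#'
#' Constructs the registry of grid-based stimuli from named families. The
#' default configuration yields exactly 60 stimuli on the 5 x 5 grid:
#' \describe{
#'   \item{singles}{25 single blocks, one per cell.}
#'   \item{vbar5 / hbar5}{5 full-column vertical bars and 5 full-row
#'     horizontal bars.}
#'   \item{vbar3 / hbar3}{5 vertically centred 1x3 vertical bars (one per
#'     column) and 5 horizontally centred 1x3 horizontal bars (one per row).}
#'   \item{block2 / block3}{five 2x2 and five 3x3 square blocks (four corners
#'     plus a centred one).}
#'   \item{rings}{5 ring/centre shapes for the outer-vs-center task: the full
#'     16-cell outer ring, the 12-cell outer ring without corners, the 4
#'     corner cells, a 9-cell cross through the centre, and a 4-cell diamond
#'     around the centre.}
#' }
#'
#' @param grid a [grid_spec()]; families other than `rings` generalise to
#'   other odd grid sizes, the defaults target the 5 x 5 grid.
#' @param families character vector naming the families to generate.
#' @param gray_level luminance fraction shared by all stimuli.
#' @return An object of class `stimulus_registry`: a list with `stimuli`
#'   (named list of [stimulus()] objects, in construction order) and `grid`.
#' @export
build_stimulus_registry <- function(grid = grid_spec(),
                                    families = c("singles", "vbar5", "hbar5",
                                                 "vbar3", "hbar3", "block2",
                                                 "block3", "rings"),
                                    gray_level = 0.5) {
  nr <- grid$n_rows; nc <- grid$n_cols
  mid_r <- (nr - 1L) %/% 2L; mid_c <- (nc - 1L) %/% 2L
  stims <- list()
  add <- function(s) {
    if (!is.null(stims[[s$id]]))
      stop("duplicate stimulus ids: ", s$id)
    stims[[s$id]] <<- s
  }
  for (fam in families) {
    switch(fam,
      singles = for (r in 0:(nr - 1)) for (cc in 0:(nc - 1))
        add(stimulus(sprintf("single_r%dc%d", r, cc), cbind(r, cc), grid,
                     gray_level)),
      vbar5 = for (cc in 0:(nc - 1))
        add(stimulus(sprintf("vbar5_c%d", cc), cells_rect(0:(nr - 1), cc),
                     grid, gray_level, "vertical")),
      hbar5 = for (r in 0:(nr - 1))
        add(stimulus(sprintf("hbar5_r%d", r), cells_rect(r, 0:(nc - 1)),
                     grid, gray_level, "horizontal")),
      vbar3 = for (cc in 0:(nc - 1))
        add(stimulus(sprintf("vbar3_c%d", cc),
                     cells_rect((mid_r - 1):(mid_r + 1), cc),
                     grid, gray_level, "vertical")),
      hbar3 = for (r in 0:(nr - 1))
        add(stimulus(sprintf("hbar3_r%d", r),
                     cells_rect(r, (mid_c - 1):(mid_c + 1)),
                     grid, gray_level, "horizontal")),
      block2 = {
        pos <- list(tl = c(0, 0), tr = c(0, nc - 2), bl = c(nr - 2, 0),
                    br = c(nr - 2, nc - 2), c = c(mid_r - 1, mid_c - 1))
        for (nm in names(pos))
          add(stimulus(sprintf("block2_%s", nm),
                       cells_rect(pos[[nm]][1] + 0:1, pos[[nm]][2] + 0:1),
                       grid, gray_level))
      },
      block3 = {
        pos <- list(tl = c(0, 0), tr = c(0, nc - 3), bl = c(nr - 3, 0),
                    br = c(nr - 3, nc - 3), c = c(mid_r - 1, mid_c - 1))
        for (nm in names(pos))
          add(stimulus(sprintf("block3_%s", nm),
                       cells_rect(pos[[nm]][1] + 0:2, pos[[nm]][2] + 0:2),
                       grid, gray_level))
      },
      rings = {
        border <- cells_rect(0:(nr - 1), 0:(nc - 1))
        border <- border[border[, 1] %in% c(0, nr - 1) |
                         border[, 2] %in% c(0, nc - 1), , drop = FALSE]
        corners <- cells_rect(c(0, nr - 1), c(0, nc - 1))
        ring12 <- border[!(border[, 1] %in% c(0, nr - 1) &
                           border[, 2] %in% c(0, nc - 1)), , drop = FALSE]
        cross <- unique(rbind(cells_rect(0:(nr - 1), mid_c),
                              cells_rect(mid_r, 0:(nc - 1))))
        diamond <- rbind(c(mid_r - 1, mid_c), c(mid_r + 1, mid_c),
                         c(mid_r, mid_c - 1), c(mid_r, mid_c + 1))
        add(stimulus("ring16", border, grid, gray_level))
        add(stimulus("ring12", ring12, grid, gray_level))
        add(stimulus("corners4", corners, grid, gray_level))
        add(stimulus("cross9", cross, grid, gray_level))
        add(stimulus("diamond4", diamond, grid, gray_level))
      },
      stop("unknown stimulus family: '", fam, "'")
    )
  }
  ids <- vapply(stims, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate stimulus ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  keys <- paste(vapply(stims, cell_key, ""),
                vapply(stims, `[[`, 0, "gray_level"))
  if (anyDuplicated(keys)) {
    dup <- ids[keys %in% keys[duplicated(keys)]]
    stop("stimuli with identical lit-cell sets and gray level: ",
         paste(dup, collapse = ", "))
  }
  structure(list(stimuli = stims, grid = grid), class = "stimulus_registry")
}

#' @export
print.stimulus_registry <- function(x, ...) {
  cat("<stimulus_registry>", length(x$stimuli), "stimuli on a",
      x$grid$n_rows, "x", x$grid$n_cols, "grid\n")
  invisible(x)
}

#' Look up a stimulus by id
#' @param registry a [build_stimulus_registry()] result.
#' @param id stimulus identifier.
#' @return The [stimulus()] object.
#' @export
get_stimulus <- function(registry, id) {
  s <- registry$stimuli[[id]]
  if (is.null(s)) stop("unknown stimulus id: '", id, "'")
  s
}

#' Stimulus ids in registry order
#' @param registry a stimulus registry.
#' @return Character vector of ids.
#' @export
stimulus_ids <- function(registry) names(registry$stimuli)

#' Render a stimulus to a luminance image
#'
#' @param stim a [stimulus()].
#' @param grid the [grid_spec()] the stimulus lives on.
#' @param resolution pixels per grid cell (positive integer).
#' @return Numeric matrix (`n_rows * resolution` x `n_cols * resolution`);
#'   lit cells carry the stimulus gray level, the rest is 0, so the image
#'   mean equals `area * gray_level / (n_rows * n_cols)`.
#' @export
render_stimulus <- function(stim, grid = grid_spec(), resolution = 10L) {
  stopifnot(resolution >= 1)
  resolution <- as.integer(resolution)
  img <- matrix(0, grid$n_rows * resolution, grid$n_cols * resolution)
  for (k in seq_len(nrow(stim$lit_cells))) {
    r <- stim$lit_cells[k, 1]; cc <- stim$lit_cells[k, 2]
    img[r * resolution + 1:resolution, cc * resolution + 1:resolution] <-
      stim$gray_level
  }
  img
}
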