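#' Symptom labels of the assessment grid
#'
#' The instrument records presence/absence of four facial skin problems:
#' erythema, papules, dryness, and exudate/yellow scaling (a single merged
#' item). The order is fixed and is part of the serialization contract.
#'
#' @return Character vector of the four symptom labels, in canonical order.
#' @export
#' @examples
#' symptoms()
symptoms <- function() {
  c("erythema", "papules", "dryness", "exudate_yellow_scaling")
}

#' Facial area labels of the assessment grid
#'
#' The finalized instrument divides the infant face into nine areas. The
#' combined eight-area layout used by the version-2 scoring method merges the
#' left and right forehead into a single `forehead` area.
#'
#' @param layout `"nine_area"` (the instrument as administered) or
#'   `"eight_area_combined"` (foreheads merged for scoring version 2).
#' @return Character vector of area labels in canonical order.
#' @export
#' @examples
#' facial_areas()
#' facial_areas("eight_area_combined")
facial_areas <- function(layout = c("nine_area", "eight_area_combined")) {
  layout <- match.arg(layout)
  nine <- c(
    "scalp_hairline", "right_forehead", "left_forehead", "eyebrows_eyes",
    "nose", "right_cheek", "left_cheek", "mouth_jaw", "ears"
  )
  if (layout == "nine_area") {
    return(nine)
  }
  c(
    "scalp_hairline", "forehead", "eyebrows_eyes", "nose",
    "right_cheek", "left_cheek", "mouth_jaw", "ears"
  )
}

#' Construct an assessment grid
#'
#' An assessment grid is a complete symptom-by-area logical matrix recording
#' presence (`TRUE`) or absence (`FALSE`) of each symptom in each facial
#' area for one rater and one infant. Cells are strictly binary; grids with
#' missing cells are rejected rather than imputed.
#'
#' @param cells Logical (or 0/1) matrix with one row per symptom and one
#'   column per area. Dimnames, if present, must match [symptoms()] and
#'   [facial_areas()] for the chosen layout; unnamed matrices are assumed to
#'   be in canonical order.
#' @param layout Grid layout, `"nine_area"` or `"eight_area_combined"`.
#' @return An `ifsat_grid` object: a named logical matrix with a `layout`
#'   attribute.
#' @export
#' @examples
#' g <- empty_grid()
#' g["erythema", "nose"] <- TRUE
#' score_original(g)
assessment_grid <- function(cells, layout = c("nine_area", "eight_area_combined")) {
  layout <- match.arg(layout)
  areas <- facial_areas(layout)
  if (!is.matrix(cells)) {
    stop("`cells` must be a matrix of ", length(symptoms()), " x ",
         length(areas), " presence indicators", call. = FALSE)
  }
  if (nrow(cells) != length(symptoms()) || ncol(cells) != length(areas)) {
    stop("grid must be ", length(symptoms()), " symptoms x ", length(areas),
         " areas for layout '", layout, "'; got ", nrow(cells), " x ",
         ncol(cells), call. = FALSE)
  }
  if (anyNA(cells)) {
    stop("grid cells must be fully observed 0/1; missing values are not allowed",
         call. = FALSE)
  }
  if (is.numeric(cells)) {
    if (!all(cells %in% c(0, 1))) {
      stop("numeric grid cells must be 0 or 1", call. = FALSE)
    }
    cells <- cells == 1
  }
  if (!is.logical(cells)) {
    stop("grid cells must be logical or 0/1 numeric", call. = FALSE)
  }
  if (!is.null(dimnames(cells))) {
    if (!identical(sort(rownames(cells)), sort(symptoms())) ||
        !identical(sort(colnames(cells)), sort(areas))) {
      stop("grid dimnames do not match the instrument's symptoms/areas",
           call. = FALSE)
    }
    cells <- cells[symptoms(), areas, drop = FALSE]
  } else {
    dimnames(cells) <- list(symptoms(), areas)
  }
  structure(cells, layout = layout, class = c("ifsat_grid", "matrix", "array"))
}

#' @rdname assessment_grid
#' @export
empty_grid <- function(layout = c("nine_area", "eight_area_combined")) {
  layout <- match.arg(layout)
  areas <- facial_areas(layout)
  assessment_grid(
    matrix(FALSE, length(symptoms()), length(areas)),
    layout = layout
  )
}

#' @rdname assessment_grid
#' @export
full_grid <- function(layout = c("nine_area", "eight_area_combined")) {
  layout <- match.arg(layout)
  areas <- facial_areas(layout)
  assessment_grid(
    matrix(TRUE, length(symptoms()), length(areas)),
    layout = layout
  )
}

#' @export
print.ifsat_grid <- function(x, ...) {
  cat("IFSAT assessment grid (", attr(x, "layout"), "), ",
      sum(x), " of ", length(x), " cells present\n", sep = "")
  m <- matrix(ifelse(unclass(x), "x", "."), nrow(x), ncol(x),
              dimnames = dimnames(x))
  print(m, quote = FALSE)
  invisible(x)
}

grid_layout <- function(grid) {
  if (!inherits(grid, "ifsat_grid")) {
    stop("expected an `ifsat_grid` object; see assessment_grid()", call. = FALSE)
  }
  attr(grid, "layout")
}

require_layout <- function(grid, layout) {
  have <- grid_layout(grid)
  if (!identical(have, layout)) {
    stop("this operation requires a '", layout, "' grid; got '", have, "'",
         call. = FALSE)
  }
  invisible(grid)
}

#' Merge the two forehead areas of a nine-area grid
#'
#' The version-2 scoring method collapses the left and right forehead into a
#' single forehead area. Per symptom, the combined forehead is present if the
#' symptom is present on either the left or right forehead (logical OR);
#' every other cell is copied unchanged.
#'
#' @param grid A nine-area [assessment_grid()].
#' @return An eight-area `ifsat_grid`.
#' @export
#' @examples
#' g <- empty_grid()
#' g["erythema", "left_forehead"] <- TRUE
#' combine_forehead(g)["erythema", "forehead"]
combine_forehead <- function(grid) {
  require_layout(grid, "nine_area")
  areas8 <- facial_areas("eight_area_combined")
  out <- matrix(FALSE, length(symptoms()), length(areas8),
                dimnames = list(symptoms(), areas8))
  for (a in setdiff(areas8, "forehead")) out[, a] <- grid[, a]
  out[, "forehead"] <- grid[, "left_forehead"] | grid[, "right_forehead"]
  assessment_grid(out, layout = "eight_area_combined")
}

# Weight tables for the two weighted scoring methods. Every cell defaults to
# weight 1; the listed erythema/papules cells and all dryness and exudate
# cells get weight 2 (doubling the dryness/exudate totals cell-by-cell is
# arithmetically identical to doubling each symptom's subtotal).
v1_weights <- function() {
  w <- matrix(1L, length(symptoms()), length(facial_areas("nine_area")),
              dimnames = list(symptoms(), facial_areas("nine_area")))
  w["erythema", c("left_forehead", "right_forehead")] <- 2L
  w["papules", c("left_forehead", "right_forehead",
                 "left_cheek", "right_cheek", "mouth_jaw")] <- 2L
  w["dryness", ] <- 2L
  w["exudate_yellow_scaling", ] <- 2L
  w
}

v2_weights <- function() {
  w <- matrix(1L, length(symptoms()), length(facial_areas("eight_area_combined")),
              dimnames = list(symptoms(), facial_areas("eight_area_combined")))
  w["erythema", "forehead"] <- 2L
  w["papules", c("forehead", "left_cheek", "right_cheek", "mouth_jaw")] <- 2L
  w["dryness", ] <- 2L
  w["exudate_yellow_scaling", ] <- 2L
  w
}

#' Score an assessment grid
#'
#' Three scoring methods are defined on the nine-area grid:
#'
#' * **original** — the unweighted count of present cells (each present cell
#'   scores 1 point; range 0-36).
#' * **v1** — a weighted count on the nine-area grid: erythema on either
#'   forehead, papules on either forehead, either cheek or the mouth/jaw area
#'   score 2 points each, and every dryness and exudate cell scores 2 points
#'   (equivalently, the dryness and exudate subtotals are doubled); all other
#'   present cells score 1 (range 0-61).
#' * **v2** — the finalized method: the foreheads are first merged with
#'   [combine_forehead()], then erythema on the forehead, papules on the
#'   forehead, left cheek, right cheek or mouth/jaw score 2 points each, and
#'   every dryness and exudate cell scores 2 points; other present cells
#'   score 1 (range 0-53).
#'
#' @param grid A nine-area [assessment_grid()].
#' @param version One of `"original"`, `"v1"`, `"v2"`.
#' @return A non-negative integer score.
#' @seealso [score_set()] for all three at once, [max_score()].
#' @export
#' @examples
#' g <- empty_grid()
#' g["papules", "right_cheek"] <- TRUE
#' score_grid(g, "v2")  # 2: a doubled item
score_grid <- function(grid, version = c("original", "v1", "v2")) {
  version <- match.arg(version)
  switch(version,
    original = score_original(grid),
    v1 = score_v1(grid),
    v2 = score_v2(grid)
  )
}

#' @rdname score_grid
#' @export
score_original <- function(grid) {
  require_layout(grid, "nine_area")
  as.integer(sum(grid))
}

#' @rdname score_grid
#' @export
score_v1 <- function(grid) {
  require_layout(grid, "nine_area")
  as.integer(sum(v1_weights()[unclass(grid)]))
}

#' @rdname score_grid
#' @export
score_v2 <- function(grid) {
  require_layout(grid, "nine_area")
  g8 <- combine_forehead(grid)
  as.integer(sum(v2_weights()[unclass(g8)]))
}

#' All three scores for one grid
#'
#' @inheritParams score_grid
#' @return Named integer vector with elements `original`, `v1`, `v2`.
#'   Always satisfies `original <= v1 <= 2 * original` and `v2 <= v1`.
#' @export
score_set <- function(grid) {
  c(original = score_original(grid), v1 = score_v1(grid), v2 = score_v2(grid))
}

#' Maximum attainable score of a scoring method
#'
#' Computed by scoring the all-present nine-area grid, not from a stored
#' constant.
#'
#' @inheritParams score_grid
#' @return Integer maximum (36 for original, 61 for v1, 53 for v2).
#' @export
max_score <- function(version = c("original", "v1", "v2")) {
  version <- match.arg(version)
  score_grid(full_grid("nine_area"), version)
}

#' Convert grids to and from long-format data frames
#'
#' The long serialization has one row per cell with columns `symptom`,
#' `area`, `present` (0/1), plus any identifying columns supplied via `...`.
#' Symptom-major canonical ordering is used so serialization is byte-stable.
#'
#' @param grid An [assessment_grid()].
#' @param ... Named length-1 columns prepended to the output (e.g.
#'   `infant_id`, `rater_role`).
#' @return `grid_to_long()`: a data.frame; `long_to_grid()`: an `ifsat_grid`.
#' @export
grid_to_long <- function(grid, ...) {
  layout <- grid_layout(grid)
  areas <- facial_areas(layout)
  df <- expand.grid(area = areas, symptom = symptoms(),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[, c("symptom", "area")]
  df$present <- as.integer(t(unclass(grid))[cbind(match(df$area, areas),
                                                  match(df$symptom, symptoms()))])
  ids <- list(...)
  if (length(ids)) {
    df <- cbind(as.data.frame(ids, stringsAsFactors = FALSE), df)
  }
  rownames(df) <- NULL
  df
}

#' @rdname grid_to_long
#' @param long A data.frame with columns `symptom`, `area`, `present`
#'   covering every cell of the layout exactly once.
#' @param layout Layout of the grid encoded in `long`.
#' @export
long_to_grid <- function(long, layout = c("nine_area", "eight_area_combined")) {
  layout <- match.arg(layout)
  need <- c("symptom", "area", "present")
  miss <- setdiff(need, names(long))
  if (length(miss)) {
    stop("long grid data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  areas <- facial_areas(layout)
  m <- matrix(NA, length(symptoms()), length(areas),
              dimnames = list(symptoms(), areas))
  i <- match(long$symptom, symptoms())
  j <- match(long$area, areas)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(long$symptom[is.na(i)], long$area[is.na(j)]))
    stop("unknown symptom/area label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m[cbind(i, j)] <- long$present
  if (anyNA(m)) {
    stop("long grid data does not cover every (symptom, area) cell",
         call. = FALSE)
  }
  assessment_grid(m == 1, layout = layout)
}

#' Wide one-row encoding of a nine-area grid
#'
#' Columns are named `<symptom>_<area>` in symptom-major canonical order
#' (`erythema_scalp_hairline`, ..., `exudate_yellow_scaling_ears`), each 0/1.
#'
#' @param grid A nine-area [assessment_grid()].
#' @return A one-row data.frame with 36 integer columns.
#' @export
grid_to_wide <- function(grid) {
  require_layout(grid, "nine_area")
  v <- as.integer(t(unclass(grid)))
  nm <- as.vector(t(outer(symptoms(), facial_areas("nine_area"), paste, sep = "_")))
  out <- as.data.frame(as.list(stats::setNames(v, nm)), check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname grid_to_wide
#' @param wide A one-row data.frame (or named vector) with the 36 canonical
#'   `<symptom>_<area>` columns.
#' @export
wide_to_grid <- function(wide) {
  nm <- as.vector(t(outer(symptoms(), facial_areas("nine_area"), paste, sep = "_")))
  wide <- unlist(wide[nm])
  if (anyNA(wide)) {
    stop("wide grid encoding is missing canonical columns", call. = FALSE)
  }
  m <- matrix(as.numeric(wide), nrow = length(symptoms()), byrow = TRUE,
              dimnames = list(symptoms(), facial_areas("nine_area")))
  assessment_grid(m)
}
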