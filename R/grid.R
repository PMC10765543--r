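#' @keywords internal
"_PACKAGE"

WALLS <- c("RV", "LV", "SEPTUM")
WALL_CODES <- c(RV = "RV", LV = "LV", SEPTUM = "SEP")

#' Format an electrode channel label
#'
#' Channel labels follow the codec \code{"W{RV|LV|SEP}L{level}C{column}D{depth}"},
#' e.g. \code{"WLVL3C2D0"} for the epicardial electrode (depth 0) of the LV
#' needle at level 3, column 2. Depth 0 is the electrode closest to the
#' epicardium; depths run 0-3 towards the endocardium.
#'
#' @param wall one of \code{"RV"}, \code{"LV"}, \code{"SEPTUM"}.
#' @param level base-to-apex level, integer 1 (base) to 6 (apex).
#' @param column circumferential column index, integer >= 1.
#' @param depth intra-needle depth index, integer 0-3 (0 = epicardial).
#' @return character vector of channel labels.
#' @seealso [parse_channel_label()]
#' @export
#' @examples
#' format_channel_label("LV", 3, 2, 0)
format_channel_label <- function(wall, level, column, depth) {
  wall <- match_wall(wall)
  stopifnot(all(depth %in% 0:3))
  sprintf("W%sL%dC%dD%d", WALL_CODES[wall], as.integer(level),
          as.integer(column), as.integer(depth))
}

#' Parse electrode channel labels
#'
#' Inverse of [format_channel_label()]; \code{format(parse(x))} round-trips
#' for every valid label.
#'
#' @param x character vector of labels such as \code{"WSEPL1C2D3"}.
#' @return data.frame with columns \code{wall}, \code{level}, \code{column},
#'   \code{depth}.
#' @export
parse_channel_label <- function(x) {
  m <- regmatches(x, regexec("^W(RV|LV|SEP)L([0-9]+)C([0-9]+)D([0-3])$", x))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) {
    stop("invalid channel label(s): ", paste(x[bad], collapse = ", "))
  }
  wall_code <- vapply(m, `[`, "", 2L)
  data.frame(
    wall = names(WALL_CODES)[match(wall_code, WALL_CODES)],
    level = as.integer(vapply(m, `[`, "", 3L)),
    column = as.integer(vapply(m, `[`, "", 4L)),
    depth = as.integer(vapply(m, `[`, "", 5L)),
    stringsAsFactors = FALSE
  )
}

match_wall <- function(wall) {
  wall <- toupper(as.character(wall))
  wall[wall == "SEP"] <- "SEPTUM"
  if (!all(wall %in% WALLS)) {
    stop("unknown wall: ", paste(setdiff(wall, WALLS), collapse = ", "))
  }
  wall
}

#' Default needle layout for the 56-needle mapping grid
#'
#' Allocates 56 intramural needles over the free walls and septum as
#' level-by-column lattices: LV free wall 6 levels x 4 columns (24 needles),
#' RV free wall 5 levels x 4 columns (20), septum 6 levels x 2 columns (12).
#' The analysis depends only on the adjacency structure, so any alternative
#' allocation can be supplied to [build_mapping_grid()] as a layout table.
#'
#' @return data.frame with columns \code{needle_id}, \code{wall},
#'   \code{level}, \code{column}.
#' @export
default_needle_layout <- function() {
  alloc <- list(
    LV = expand.grid(level = 1:6, column = 1:4),
    RV = expand.grid(level = 1:5, column = 1:4),
    SEPTUM = expand.grid(level = 1:6, column = 1:2)
  )
  out <- do.call(rbind, lapply(names(alloc), function(w) {
    d <- alloc[[w]]
    data.frame(wall = w, level = d$level, column = d$column,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(match(out$wall, WALLS), out$level, out$column), ]
  out <- cbind(needle_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Build the intramural needle mapping grid
#'
#' Constructs the lattice of recording needles (four unipolar electrodes
#' each, depth index 0-3 from epicardium to endocardium) together with the
#' precomputed adjacency used by all dispersion statistics: vertical needle
#' pairs (adjacent base-to-apex levels, same wall and column), horizontal
#' needle pairs (adjacent circumferential columns, same wall and level), and
#' 2 x 2 needle squares. Horizontal adjacency wraps circumferentially within
#' the LV and RV free-wall rings; the septum is treated as a bounded sheet.
#'
#' @param layout optional needle layout: a data.frame with columns
#'   \code{needle_id}, \code{wall}, \code{level}, \code{column}, or a path to
#'   a JSON geometry file with those fields. Defaults to
#'   [default_needle_layout()].
#' @param wrap named logical vector giving, per wall, whether horizontal
#'   adjacency wraps around the ring. Default wraps the free walls only.
#' @param intra_needle_spacing_mm electrode spacing along one needle (4 mm).
#' @param inter_needle_spacing_mm spacing between adjacent needles (10 mm).
#' @return an object of class \code{mapping_grid}: list with elements
#'   \code{needles} (layout data.frame), \code{electrodes} (224-row channel
#'   table for the default grid), \code{vertical_pairs},
#'   \code{horizontal_pairs} (2-column matrices of needle ids),
#'   \code{squares} (4-column matrix of needle ids), \code{wrap}, and the
#'   spacing metadata.
#' @export
#' @examples
#' g <- build_mapping_grid()
#' g$n_needles       # 56
#' nrow(g$electrodes) # 224
build_mapping_grid <- function(layout = NULL,
                               wrap = c(RV = TRUE, LV = TRUE, SEPTUM = FALSE),
                               intra_needle_spacing_mm = 4,
                               inter_needle_spacing_mm = 10) {
  if (is.null(layout)) {
    layout <- default_needle_layout()
  } else if (is.character(layout) && length(layout) == 1L) {
    layout <- read_geometry_json(layout)
  }
  layout <- as.data.frame(layout)
  required <- c("needle_id", "wall", "level", "column")
  if (!all(required %in% names(layout))) {
    stop("layout must have columns: ", paste(required, collapse = ", "))
  }
  layout$wall <- match_wall(layout$wall)
  layout$level <- as.integer(layout$level)
  layout$column <- as.integer(layout$column)
  layout$needle_id <- as.integer(layout$needle_id)
  if (anyDuplicated(layout$needle_id)) {
    stop("geometry error: duplicate needle_id")
  }
  key <- paste(layout$wall, layout$level, layout$column)
  if (anyDuplicated(key)) {
    stop("geometry error: duplicate needle coordinates (wall, level, column)")
  }
  if (any(layout$level < 1L | layout$level > 6L)) {
    stop("geometry error: level outside 1-6")
  }
  if (any(layout$column < 1L)) stop("geometry error: column must be >= 1")
  stopifnot(intra_needle_spacing_mm > 0, inter_needle_spacing_mm > 0)
  wrap_full <- c(RV = TRUE, LV = TRUE, SEPTUM = FALSE)
  wrap_full[names(wrap)] <- wrap

  idx <- function(wall, level, column) {
    i <- which(layout$wall == wall & layout$level == level &
                 layout$column == column)
    if (length(i)) layout$needle_id[i] else NA_integer_
  }

  vpairs <- list(); hpairs <- list(); squares <- list()
  for (w in unique(layout$wall)) {
    sub <- layout[layout$wall == w, ]
    ncol_w <- max(sub$column)
    wrap_w <- isTRUE(wrap_full[[w]])
    for (lev in sort(unique(sub$level))) {
      # vertical: same column, adjacent level
      for (co in sort(unique(sub$column[sub$level == lev]))) {
        a <- idx(w, lev, co); b <- idx(w, lev + 1L, co)
        if (!is.na(a) && !is.na(b)) vpairs[[length(vpairs) + 1L]] <- c(a, b)
      }
      # horizontal: same level, adjacent column; ring edges when wrapping
      cols <- if (wrap_w) seq_len(ncol_w) else seq_len(ncol_w - 1L)
      for (co in cols) {
        co2 <- if (co == ncol_w) 1L else co + 1L
        if (co2 == co) next
        a <- idx(w, lev, co); b <- idx(w, lev, co2)
        if (!is.na(a) && !is.na(b)) hpairs[[length(hpairs) + 1L]] <- c(a, b)
      }
      # squares: (level, level+1) x (column, column+1 with wrap)
      for (co in cols) {
        co2 <- if (co == ncol_w) 1L else co + 1L
        if (co2 == co) next
        quad <- c(idx(w, lev, co), idx(w, lev, co2),
                  idx(w, lev + 1L, co), idx(w, lev + 1L, co2))
        if (!anyNA(quad)) squares[[length(squares) + 1L]] <- quad
      }
    }
  }
  to_mat <- function(lst, nc) {
    if (!length(lst)) return(matrix(integer(0), ncol = nc))
    do.call(rbind, lst)
  }
  sq <- to_mat(squares, 4L)
  if (nrow(sq)) {
    sq <- sq[!duplicated(apply(sq, 1L, function(r) paste(sort(r), collapse = "-"))),
             , drop = FALSE]
  }

  electrodes <- layout[rep(seq_len(nrow(layout)), each = 4L), ]
  electrodes$depth <- rep(0:3, nrow(layout))
  electrodes$channel <- format_channel_label(electrodes$wall, electrodes$level,
                                             electrodes$column, electrodes$depth)
  rownames(electrodes) <- NULL

  structure(list(
    needles = layout,
    electrodes = electrodes,
    n_needles = nrow(layout),
    vertical_pairs = to_mat(vpairs, 2L),
    horizontal_pairs = to_mat(hpairs, 2L),
    squares = sq,
    wrap = wrap_full,
    intra_needle_spacing_mm = intra_needle_spacing_mm,
    inter_needle_spacing_mm = inter_needle_spacing_mm
  ), class = "mapping_grid")
}

#' @export
print.mapping_grid <- function(x, ...) {
  cat("Intramural mapping grid\n")
  tab <- table(x$needles$wall)
  cat(sprintf("  %d needles (%s), %d electrodes\n", x$n_needles,
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              nrow(x$electrodes)))
  cat(sprintf("  adjacency: %d vertical pairs, %d horizontal pairs, %d squares\n",
              nrow(x$vertical_pairs), nrow(x$horizontal_pairs), nrow(x$squares)))
  cat(sprintf("  spacing: %g mm intra-needle, %g mm inter-needle\n",
              x$intra_needle_spacing_mm, x$inter_needle_spacing_mm))
  invisible(x)
}

#' Adjacent needles in one lattice orientation
#'
#' @param grid a [build_mapping_grid()] object.
#' @param needle_id needle identifier present in the grid.
#' @param orientation \code{"VERTICAL"} (adjacent levels, same column) or
#'   \code{"HORIZONTAL"} (adjacent columns, same level).
#' @return integer vector of neighbouring needle ids (sorted, unique).
#' @export
neighbors <- function(grid, needle_id, orientation = c("VERTICAL", "HORIZONTAL")) {
  stopifnot(inherits(grid, "mapping_grid"))
  orientation <- match.arg(orientation)
  needle_id <- as.integer(needle_id)
  if (!needle_id %in% grid$needles$needle_id) {
    stop("unknown needle_id: ", needle_id)
  }
  pairs <- if (orientation == "VERTICAL") grid$vertical_pairs else grid$horizontal_pairs
  hit <- pairs[, 1L] == needle_id | pairs[, 2L] == needle_id
  sort(unique(setdiff(as.vector(pairs[hit, , drop = FALSE]), needle_id)))
}

#' Enumerate 2 x 2 needle squares
#'
#' Squares are the spatial unit of cubic dispersion: four needles at adjacent
#' levels and adjacent columns within one wall (columns wrap on free-wall
#' rings). The list is deduplicated and returned in a deterministic order.
#'
#' @param grid a [build_mapping_grid()] object.
#' @return integer matrix, one row per square, columns = 4 needle ids.
#' @export
enumerate_squares <- function(grid) {
  stopifnot(inherits(grid, "mapping_grid"))
  grid$squares
}

#' Read / write lattice geometry JSON
#'
#' Geometry files hold one record per needle with fields \code{needle_id},
#' \code{wall}, \code{level}, \code{column}.
#'
#' @param path file path.
#' @return data.frame needle layout.
#' @export
read_geometry_json <- function(path) {
  d <- jsonlite::fromJSON(path)
  as.data.frame(d)
}

#' @rdname read_geometry_json
#' @param layout needle layout data.frame (or a \code{mapping_grid}).
#' @export
write_geometry_json <- function(layout, path) {
  if (inherits(layout, "mapping_grid")) layout <- layout$needles
  jsonlite::write_json(layout[, c("needle_id", "wall", "level", "column")],
                       path, dataframe = "rows", auto_unbox = FALSE)
  invisible(path)
}
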