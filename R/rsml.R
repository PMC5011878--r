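#' Read a traced root system from an RSML file
#'
#' Root System Markup Language (RSML) is the XML interchange format exported
#' by interactive tracing software. One file holds the trace of one slide
#' side at one imaging timepoint. Axile roots (primary, seminal, crown) are
#' top-level `<root>` elements; lateral roots are either nested `<root>`
#' children or top-level roots carrying a `parent` attribute.
#'
#' Coordinates are converted to cm: if the metadata `<unit>` is `cm`, points
#' are taken as-is; if it is `pixel` (or absent), the metadata `<resolution>`
#' is read as mm per pixel and lengths become `px * resolution / 10` cm. A
#' pixel-unit file without resolution metadata falls back to the platform
#' default of 0.13 mm per pixel, with a warning.
#'
#' @param path RSML (XML) file.
#' @param timepoint day index of the trace (stored on the returned system).
#' @param slide_id,side identifiers stored on the returned system.
#' @param default_scale fallback resolution in mm per pixel.
#' @return A `root_system`: list with `timepoint`, `slide_id`, `side`, and
#'   `roots`, a list of axile roots. Each axile root is a list with `id`,
#'   `root_class`, `polyline` (n x 2 matrix of (x, y) in cm, origin at the
#'   paper's top-left, y downward), `length` (cm, polyline arc length) and
#'   `laterals` (list of laterals with `id`, `polyline`, `length`,
#'   `insertion_position` in cm along the parent, `emergence_timepoint`).
#' @export
read_rsml <- function(path, timepoint = NA_integer_, slide_id = NA_character_,
                      side = NA_character_, default_scale = 0.13) {
  doc <- xml2::read_xml(path)  # malformed XML errors here
  unit <- xml2::xml_text(xml2::xml_find_first(doc, ".//metadata/unit"))
  res <- xml2::xml_text(xml2::xml_find_first(doc, ".//metadata/resolution"))
  if (!is.na(unit) && tolower(unit) == "cm") {
    to_cm <- 1
  } else {
    mm_per_px <- suppressWarnings(as.numeric(res))
    if (is.na(mm_per_px)) {
      warning("RSML has no resolution metadata; assuming ", default_scale,
              " mm per pixel", call. = FALSE)
      mm_per_px <- default_scale
    }
    to_cm <- mm_per_px / 10
  }

  top <- xml2::xml_find_all(doc, ".//scene/plant/root | .//scene/root")
  axiles <- list()
  orphans <- list()  # top-level laterals referencing a parent by id
  for (node in top) {
    parent_id <- xml2::xml_attr(node, "parent")
    r <- parse_rsml_root(node, to_cm, timepoint)
    if (!is.na(parent_id)) {
      r$parent_id <- parent_id
      orphans[[length(orphans) + 1L]] <- r
    } else {
      axiles[[length(axiles) + 1L]] <- r
    }
  }
  ids <- vapply(axiles, `[[`, character(1), "id")
  for (lat in orphans) {
    k <- match(lat$parent_id, ids)
    if (is.na(k))
      stop("RSML integrity error: lateral '", lat$id,
           "' references missing parent '", lat$parent_id, "'", call. = FALSE)
    axiles[[k]]$laterals <- c(axiles[[k]]$laterals,
                              list(as_lateral(lat, axiles[[k]]$polyline)))
  }
  structure(list(timepoint = timepoint, slide_id = slide_id, side = side,
                 roots = axiles),
            class = "root_system")
}

parse_rsml_root <- function(node, to_cm, timepoint) {
  id <- xml2::xml_attr(node, "ID")
  if (is.na(id)) id <- xml2::xml_attr(node, "id")
  label <- xml2::xml_attr(node, "label")
  pts <- xml2::xml_find_all(node, "./geometry/polyline/point")
  xy <- cbind(as.numeric(xml2::xml_attr(pts, "x")),
              as.numeric(xml2::xml_attr(pts, "y"))) * to_cm
  if (nrow(xy) < 2L)
    stop("RSML parse error: root '", id, "' has fewer than 2 points",
         call. = FALSE)
  root <- list(id = id,
               root_class = if (is.na(label) || label == "") "crown_whorl1" else label,
               polyline = xy,
               length = polyline_arclength(xy),
               laterals = list())
  kids <- xml2::xml_find_all(node, "./root")
  for (kid in kids) {
    lat <- parse_rsml_root(kid, to_cm, timepoint)
    root$laterals <- c(root$laterals, list(as_lateral(lat, root$polyline)))
  }
  root$emergence_timepoint <- timepoint
  root
}

as_lateral <- function(r, parent_polyline) {
  list(id = r$id,
       polyline = r$polyline,
       length = r$length,
       insertion_position = project_arclength(parent_polyline, r$polyline[1, ]),
       emergence_timepoint = r$emergence_timepoint)
}

#' @export
print.root_system <- function(x, ...) {
  n_lat <- sum(vapply(x$roots, function(r) length(r$laterals), integer(1)))
  cat(sprintf("root_system: day %s, slide %s side %s; %d axile root(s), %d lateral(s)\n",
              x$timepoint, x$slide_id, x$side, length(x$roots), n_lat))
  invisible(x)
}

#' Write a root system to RSML
#'
#' Inverse of [read_rsml]. Coordinates are written in cm (`<unit>cm</unit>`);
#' laterals are written as nested `<root>` elements.
#'
#' @param system a `root_system`.
#' @param path output file.
#' @export
write_rsml <- function(system, path) {
  doc <- xml2::xml_new_root("rsml")
  meta <- xml2::xml_add_child(doc, "metadata")
  xml2::xml_add_child(meta, "version", "1")
  xml2::xml_add_child(meta, "unit", "cm")
  xml2::xml_add_child(meta, "resolution", "1")
  scene <- xml2::xml_add_child(doc, "scene")
  plant <- xml2::xml_add_child(scene, "plant")
  for (r in system$roots) {
    rn <- add_rsml_root(plant, r)
    for (lat in r$laterals) add_rsml_root(rn, lat)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

add_rsml_root <- function(parent_node, root) {
  rn <- xml2::xml_add_child(parent_node, "root")
  xml2::xml_set_attr(rn, "ID", root$id)
  if (!is.null(root$root_class)) xml2::xml_set_attr(rn, "label", root$root_class)
  geom <- xml2::xml_add_child(rn, "geometry")
  pl <- xml2::xml_add_child(geom, "polyline")
  for (i in seq_len(nrow(root$polyline))) {
    pt <- xml2::xml_add_child(pl, "point")
    xml2::xml_set_attr(pt, "x", format(root$polyline[i, 1], digits = 17))
    xml2::xml_set_attr(pt, "y", format(root$polyline[i, 2], digits = 17))
  }
  rn
}

#' Polyline arc length
#'
#' @param xy n x 2 matrix of points.
#' @return Total length (sum of segment lengths).
#' @export
polyline_arclength <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  sum(sqrt(rowSums(diff(xy)^2)))
}

# arc-length position along polyline `xy` of the point on it nearest `p`
project_arclength <- function(xy, p) {
  best_d2 <- Inf; best_s <- 0; s0 <- 0
  for (i in seq_len(nrow(xy) - 1L)) {
    a <- xy[i, ]; b <- xy[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    tt <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
    q <- a + tt * ab
    d2 <- sum((p - q)^2)
    if (d2 < best_d2) {
      best_d2 <- d2
      best_s <- s0 + tt * sqrt(len2)
    }
    s0 <- s0 + sqrt(len2)
  }
  best_s
}
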