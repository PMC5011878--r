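#' Crown-root eligibility filter for growth analysis
#'
#' A crown root can be used for elongation analysis only if (i) it is already
#' present at the solution change (or a chosen later baseline), (ii) its
#' trace never crosses the wax barrier separating the two nitrogen
#' compartments, and (iii) its final tip stays at least `margin` cm away from
#' the side and bottom edges of the germination paper. Rule (ii) keeps the
#' nitrogen exposure of the root unambiguous; rule (iii) ensures that zero
#' growth reflects biology, not the root running out of paper.
#'
#' @param systems list of `root_system`s for one slide side, one per
#'   timepoint (any order; sorted internally, so the result is invariant to
#'   file ordering).
#' @param geometry list with `paper_width_cm`, `paper_height_cm`,
#'   `barrier_x_cm`, and `n_level_left`/`n_level_right` giving the nitrogen
#'   level on each side of the barrier.
#' @param baseline_day day index a root must exist at (typically the solution
#'   change); the earliest available timepoint `>= baseline_day` is used.
#' @param margin edge margin in cm (default 0.5).
#' @param classes root classes considered crown roots.
#' @return A data frame with one row per crown root: `root_id`,
#'   `compartment` (`high`/`low`), `eligible`, `reason`. The attribute
#'   `flags` lists compartments with no eligible root.
#' @export
filter_traceable <- function(systems, geometry, baseline_day,
                             margin = 0.5,
                             classes = c("crown_whorl1", "crown_whorl2")) {
  stopifnot(length(systems) >= 2L)
  tps <- vapply(systems, `[[`, numeric(1), "timepoint")
  systems <- systems[order(tps)]
  tps <- sort(tps)
  base_idx <- which(tps >= baseline_day)[1]
  if (is.na(base_idx))
    stop("no timepoint at or after baseline_day ", baseline_day, call. = FALSE)
  final <- systems[[length(systems)]]

  all_ids <- unique(unlist(lapply(systems, function(s)
    vapply(s$roots, `[[`, character(1), "id"))))
  rows <- lapply(all_ids, function(id) {
    final_root <- find_root(final, id)
    any_root <- find_root_any(systems, id)
    if (!(any_root$root_class %in% classes)) return(NULL)
    present_at_base <- !is.null(find_root(systems[[base_idx]], id))
    polys <- lapply(systems, function(s) {
      r <- find_root(s, id)
      if (is.null(r)) NULL else r$polyline
    })
    xs <- unlist(lapply(polys, function(p) if (is.null(p)) NULL else p[, 1]))
    crosses <- min(xs) < geometry$barrier_x_cm && max(xs) > geometry$barrier_x_cm
    compartment <- if (max(xs) <= geometry$barrier_x_cm) geometry$n_level_left
                   else if (min(xs) >= geometry$barrier_x_cm) geometry$n_level_right
                   else NA_character_
    reason <- character(0)
    if (!present_at_base)
      reason <- c(reason, sprintf("absent at baseline day %s", tps[base_idx]))
    if (crosses) reason <- c(reason, "crosses wax barrier")
    if (!is.null(final_root)) {
      tip <- final_root$polyline[nrow(final_root$polyline), ]
      at_edge <- tip[1] < margin ||
        tip[1] > geometry$paper_width_cm - margin ||
        tip[2] > geometry$paper_height_cm - margin
      if (at_edge) reason <- c(reason, "tip reaches paper side or bottom")
    } else {
      reason <- c(reason, "absent at final timepoint")
    }
    data.frame(root_id = id, compartment = compartment,
               eligible = length(reason) == 0L,
               reason = paste(reason, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(root_id = character(0), compartment = character(0),
                      eligible = logical(0), reason = character(0))
  flags <- setdiff(c("high", "low"),
                   out$compartment[out$eligible & !is.na(out$compartment)])
  attr(out, "flags") <- if (length(flags))
    sprintf("no eligible crown root in %s-N compartment", flags) else character(0)
  out
}

find_root <- function(system, id) {
  for (r in system$roots) if (identical(r$id, id)) return(r)
  NULL
}

find_root_any <- function(systems, id) {
  for (s in systems) {
    r <- find_root(s, id)
    if (!is.null(r)) return(r)
  }
  stop("root '", id, "' not found in any timepoint", call. = FALSE)
}

#' Crown-root length time series
#'
#' Extracts the (time, length) series of one root across timepoints, with the
#' time axis re-origined to the solution change (day 0 = treatment start;
#' pre-treatment observations get negative `t`). Series that shrink by more
#' than 0.5 cm between consecutive timepoints are kept but flagged as a
#' tracing-QC warning (attribute `qc`).
#'
#' @param systems list of `root_system`s (one per timepoint).
#' @param root_id root identifier.
#' @param solution_change_day day index of the nitrogen split.
#' @return Data frame with columns `t` (days since solution change) and
#'   `length` (cm), ordered by `t`, attribute `qc` (character vector).
#' @export
crown_length_series <- function(systems, root_id, solution_change_day) {
  obs <- list()
  for (s in systems) {
    r <- find_root(s, root_id)
    if (!is.null(r))
      obs[[length(obs) + 1L]] <- c(s$timepoint - solution_change_day, r$length)
  }
  if (length(obs) == 0L)
    stop("lookup error: root '", root_id, "' absent from all timepoints",
         call. = FALSE)
  if (length(obs) == 1L)
    stop("insufficient data: root '", root_id,
         "' observed at a single timepoint", call. = FALSE)
  m <- do.call(rbind, obs)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- data.frame(t = m[, 1], length = m[, 2])
  dl <- diff(out$length)
  qc <- character(0)
  if (any(dl < -0.5))
    qc <- sprintf("root '%s': length decreases by %.2f cm between timepoints",
                  root_id, -min(dl))
  attr(out, "qc") <- qc
  out
}

#' Branching zone of a crown root
#'
#' The branching zone is the interval of the axile root developing laterals
#' after the solution change: its proximal end is the insertion position of
#' the youngest (most distal) lateral already present at solution change, its
#' distal end is the insertion position of the youngest lateral at harvest.
#' The zone is divided into two sections of equal arc length for trait
#' scoring.
#'
#' @param root_id axile root identifier.
#' @param systems list of `root_system`s including the solution-change and
#'   harvest timepoints.
#' @param t_change,t_harvest day indices of solution change and harvest.
#' @return A `branching_zone`: list with `proximal_pos`, `distal_pos`,
#'   `midpoint` (cm along the root), `segment1 = c(proximal, mid)`,
#'   `segment2 = c(mid, distal)`.
#' @export
branching_zone <- function(root_id, systems, t_change, t_harvest) {
  sys_c <- system_at(systems, t_change)
  sys_h <- system_at(systems, t_harvest)
  root_c <- find_root(sys_c, root_id)
  root_h <- find_root(sys_h, root_id)
  if (is.null(root_c) || length(root_c$laterals) == 0L)
    stop("zone-undefined error: root '", root_id,
         "' has no lateral at solution change", call. = FALSE)
  if (is.null(root_h))
    stop("lookup error: root '", root_id, "' absent at harvest", call. = FALSE)
  prox <- max(vapply(root_c$laterals, `[[`, numeric(1), "insertion_position"))
  if (length(root_h$laterals) == 0L)
    stop("zone-empty error: root '", root_id, "' has no lateral at harvest",
         call. = FALSE)
  dist <- max(vapply(root_h$laterals, `[[`, numeric(1), "insertion_position"))
  if (dist <= prox)
    stop("zone-empty error: no lateral distal to the solution-change zone on root '",
         root_id, "'", call. = FALSE)
  mid <- (prox + dist) / 2
  structure(list(proximal_pos = prox, distal_pos = dist, midpoint = mid,
                 segment1 = c(prox, mid), segment2 = c(mid, dist)),
            class = "branching_zone")
}

system_at <- function(systems, day) {
  for (s in systems) if (isTRUE(s$timepoint == day)) return(s)
  stop("no root_system at day ", day, call. = FALSE)
}

#' Lateral-root traits in the two branching-zone segments
#'
#' Per segment: `No_Lat` is the lateral count, `Max_Lat` the longest lateral
#' length, `Med_Lat` the median lateral length (lower of the two middle
#' values for even counts - a deterministic stand-in for the operator-picked
#' "medium sized" lateral; recorded as `medlat_rule = "median"`), and
#' `density` the count per cm of segment. A lateral whose insertion sits
#' exactly on the segment boundary is assigned to the distal segment; the
#' lateral defining the proximal zone end belongs to segment 1.
#'
#' @param root an axile root (from a harvest `root_system`).
#' @param zone a [branching_zone].
#' @return Named list: `No_Lat_1st`, `Max_Lat_1st`, `Med_Lat_1st`,
#'   `density_1st`, and the `_2nd` counterparts; empty segments give count 0
#'   and `NA` lengths. Attribute `medlat_rule`.
#' @export
lateral_metrics <- function(root, zone) {
  ins <- vapply(root$laterals, `[[`, numeric(1), "insertion_position")
  len <- vapply(root$laterals, `[[`, numeric(1), "length")
  in1 <- ins >= zone$proximal_pos & ins < zone$midpoint
  in2 <- ins >= zone$midpoint & ins <= zone$distal_pos
  seg_len <- (zone$distal_pos - zone$proximal_pos) / 2
  seg_stats <- function(l) {
    if (length(l) == 0L)
      return(c(no = 0, max = NA_real_, med = NA_real_))
    ls <- sort(l)
    med <- ls[ceiling(length(ls) / 2)]  # lower median for even counts
    c(no = length(l), max = max(l), med = med)
  }
  s1 <- seg_stats(len[in1]); s2 <- seg_stats(len[in2])
  structure(list(
    No_Lat_1st = unname(s1["no"]), Max_Lat_1st = unname(s1["max"]),
    Med_Lat_1st = unname(s1["med"]), density_1st = unname(s1["no"]) / seg_len,
    No_Lat_2nd = unname(s2["no"]), Max_Lat_2nd = unname(s2["max"]),
    Med_Lat_2nd = unname(s2["med"]), density_2nd = unname(s2["no"]) / seg_len),
    medlat_rule = "median")
}

#' Lateral counts in the pre-change zone
#'
#' Counts laterals inserted proximal to the branching zone (the part of the
#' axile root that had already branched before the solution change) at both
#' the solution-change and the harvest timepoint. Near-equal counts support
#' the view that only root tissue formed after the change responds to
#' nitrogen availability.
#'
#' @inheritParams branching_zone
#' @return `c(change = , harvest = )` lateral counts.
#' @export
laterals_in_pre_change_zone <- function(root_id, systems, t_change, t_harvest) {
  sys_c <- system_at(systems, t_change)
  sys_h <- system_at(systems, t_harvest)
  root_c <- find_root(sys_c, root_id)
  root_h <- find_root(sys_h, root_id)
  if (is.null(root_c) || length(root_c$laterals) == 0L)
    return(c(change = 0L, harvest = 0L))
  prox <- max(vapply(root_c$laterals, `[[`, numeric(1), "insertion_position"))
  count_before <- function(root) {
    if (is.null(root) || length(root$laterals) == 0L) return(0L)
    ins <- vapply(root$laterals, `[[`, numeric(1), "insertion_position")
    sum(ins <= prox)
  }
  c(change = count_before(root_c), harvest = count_before(root_h))
}
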