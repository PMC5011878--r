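#' Load a split-nitrogen experiment design from CSV
#'
#' The design table has one row per slide x paper side x compartment, with
#' columns `slide_id`, `genotype`, `replicate`, `side` (`front`/`back`) and
#' `n_level` (`high`/`low`); an optional `compartment` column labels the two
#' halves of each paper side. Optional geometry columns `paper_width_cm`,
#' `paper_height_cm` and `barrier_x_cm` describe the germination paper and
#' the wax barrier separating the two nitrogen compartments; defaults follow
#' the 49 x 61 cm paper with the barrier at mid-width.
#'
#' Day indexing: day 0 is sowing into the slides, the nitrogen split is
#' applied at `solution_change_day` (14) and plants are harvested at
#' `harvest_day` (26), with imaging every `imaging_interval_days` (2) days.
#'
#' @param path CSV file, UTF-8, header row, decimal point.
#' @param solution_change_day,harvest_day,imaging_interval_days day indices
#'   of the cultivation schedule.
#' @return An object of class `experiment_design`: a list with elements
#'   `table` (validated long table), `slides` (one row per slide),
#'   `solution_change_day`, `harvest_day`, `imaging_interval_days`,
#'   `geometry`, and `warnings` (character vector of policy warnings).
#' @export
load_design <- function(path, solution_change_day = 14L, harvest_day = 26L,
                        imaging_interval_days = 2L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("slide_id", "genotype", "replicate", "side", "n_level")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("design schema error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"compartment" %in% names(tab))
    tab$compartment <- ifelse(tab$n_level == "high", "A", "B")
  validate_design_table(tab, solution_change_day, harvest_day,
                        imaging_interval_days)
}

#' Construct an experiment design from a data frame
#'
#' Same validation as [load_design] but from an in-memory table.
#' @param tab data frame with the design columns (see [load_design]).
#' @inheritParams load_design
#' @return An `experiment_design`.
#' @export
experiment_design <- function(tab, solution_change_day = 14L, harvest_day = 26L,
                              imaging_interval_days = 2L) {
  if (!"compartment" %in% names(tab))
    tab$compartment <- ifelse(tab$n_level == "high", "A", "B")
  validate_design_table(tab, solution_change_day, harvest_day,
                        imaging_interval_days)
}

validate_design_table <- function(tab, solution_change_day, harvest_day,
                                  imaging_interval_days) {
  if (!(solution_change_day < harvest_day))
    stop("solution_change_day must precede harvest_day", call. = FALSE)
  warn <- character(0)
  bad_n <- setdiff(unique(tab$n_level), c("high", "low"))
  if (length(bad_n))
    stop("design value error: n_level must be 'high' or 'low', found ",
         paste(bad_n, collapse = ", "), call. = FALSE)
  key <- paste(tab$slide_id, tab$side, tab$compartment, sep = "\r")
  if (anyDuplicated(key))
    stop("design integrity error: duplicate slide/side/compartment rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  # each slide has exactly one genotype and replicate
  per_slide <- split(tab, tab$slide_id)
  for (s in per_slide) {
    if (length(unique(s$genotype)) != 1L || length(unique(s$replicate)) != 1L)
      stop("design integrity error: slide ", s$slide_id[1],
           " maps to more than one genotype/replicate", call. = FALSE)
    for (sd in split(s, s$side)) {
      if (nrow(sd) != 2L || !setequal(sd$n_level, c("high", "low")))
        stop("design integrity error: slide ", s$slide_id[1], " side ",
             sd$side[1], " must have exactly one high and one low N compartment",
             call. = FALSE)
    }
  }
  out_rep <- !(tab$replicate %in% 1:4)
  if (any(out_rep)) {
    warn <- c(warn, sprintf("replicate %s outside the declared range 1-4 (rows kept)",
                            paste(unique(tab$replicate[out_rep]), collapse = ", ")))
  }
  slides <- unique(tab[, c("slide_id", "genotype", "replicate")])
  rownames(slides) <- NULL
  geom_cols <- c(paper_width_cm = 49, paper_height_cm = 61, barrier_x_cm = 24.5)
  geometry <- lapply(names(geom_cols), function(g) {
    if (g %in% names(tab)) tab[[g]][1] else unname(geom_cols[g])
  })
  names(geometry) <- names(geom_cols)
  structure(list(
    table = tab, slides = slides,
    solution_change_day = as.integer(solution_change_day),
    harvest_day = as.integer(harvest_day),
    imaging_interval_days = as.integer(imaging_interval_days),
    geometry = geometry, warnings = warn
  ), class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "experiment_design: %d slides, %d genotypes; solution change day %d, harvest day %d\n",
    nrow(x$slides), length(unique(x$slides$genotype)),
    x$solution_change_day, x$harvest_day))
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Write an experiment design back to CSV
#'
#' Inverse of [load_design]; round-trips valid designs bit-identically.
#' @param design an `experiment_design`.
#' @param path output CSV path.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average a three-position SPAD reading
#'
#' Leaf chlorophyll is read with a handheld SPAD meter at the base, middle
#' and tip of the last fully developed leaf; the plant-level value is the
#' arithmetic mean of the three readings. Missing or negative readings are an
#' error - no imputation.
#'
#' @param base,middle,tip SPAD readings (relative units, >= 0). `base` may
#'   also be a length-3 vector holding all three.
#' @return The mean reading.
#' @export
#' @examples
#' average_spad(30, 32, 34)  # 32
average_spad <- function(base, middle, tip) {
  if (length(base) == 3L && missing(middle) && missing(tip)) {
    middle <- base[[2]]; tip <- base[[3]]; base <- base[[1]]
  }
  v <- c(base, middle, tip)
  if (length(v) != 3L || anyNA(v))
    stop("SPAD value error: all three positions (base, middle, tip) required",
         call. = FALSE)
  if (any(v < 0))
    stop("SPAD value error: negative reading", call. = FALSE)
  mean(v)
}

#' Long-format trait tables
#'
#' The unit of the statistical layer: one row per measured value with columns
#' `genotype`, `n_level` (`high`, `low`, or `none` for whole-plant shoot
#' traits), `replicate`, `side` (`front`, `back`, or `none`), `trait`,
#' `value`, `units`.
#'
#' @param genotype,n_level,replicate,side,trait,value,units column vectors
#'   (recycled as in `data.frame`).
#' @return A data frame of class `trait_table`.
#' @export
trait_table <- function(genotype = character(0), n_level = character(0),
                        replicate = integer(0), side = character(0),
                        trait = character(0), value = numeric(0),
                        units = character(0)) {
  df <- data.frame(genotype = as.character(genotype),
                   n_level = as.character(n_level),
                   replicate = as.integer(replicate),
                   side = as.character(side),
                   trait = as.character(trait),
                   value = as.numeric(value),
                   units = as.character(units),
                   stringsAsFactors = FALSE)
  bad <- !(df$n_level %in% c("high", "low", "none"))
  if (any(bad))
    stop("trait table value error: n_level must be high/low/none", call. = FALSE)
  class(df) <- c("trait_table", "data.frame")
  df
}

trait_key <- function(df)
  paste(df$genotype, df$n_level, df$replicate, df$side, df$trait, sep = "\r")

#' Merge several trait tables
#'
#' Concatenates tables sharing the long-format schema, drops exact duplicate
#' records, and fails if the same key (genotype, n_level, replicate, side,
#' trait) appears with conflicting values. The result is stably ordered by
#' (trait, genotype, n_level, replicate, side), so the merge is associative
#' and insensitive to input order.
#'
#' @param tables a list of `trait_table`s (or a single table).
#' @return A merged `trait_table`.
#' @export
merge_trait_tables <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  cols <- c("genotype", "n_level", "replicate", "side", "trait", "value", "units")
  for (t in tables)
    if (!all(cols %in% names(t)))
      stop("trait table schema error: need columns ", paste(cols, collapse = ", "),
           call. = FALSE)
  all <- do.call(rbind, lapply(tables, function(t) as.data.frame(t)[cols]))
  all <- unique(all)
  key <- trait_key(all)
  dup <- key[duplicated(key)]
  if (length(dup)) {
    off <- all[key %in% dup, c("genotype", "n_level", "replicate", "side", "trait")]
    stop("trait table integrity error: conflicting values for key(s): ",
         paste(utils::capture.output(print(unique(off), row.names = FALSE)),
               collapse = "\n"), call. = FALSE)
  }
  ord <- order(all$trait, all$genotype, all$n_level, all$replicate, all$side,
               method = "radix")
  all <- all[ord, , drop = FALSE]
  rownames(all) <- NULL
  class(all) <- c("trait_table", "data.frame")
  all
}

#' Read / write a long-format trait CSV
#'
#' @param path CSV path with columns genotype, n_level, replicate, side,
#'   trait, value, units.
#' @return `read_trait_table`: a `trait_table`.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  trait_table(df$genotype, df$n_level, df$replicate, df$side,
              df$trait, df$value, df$units)
}

#' @rdname read_trait_table
#' @param x a `trait_table`.
#' @export
write_trait_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
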