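# Readers/writers for the structured text formats the pipeline consumes:
# secondary-structure maps, loop-pair tables, HSQC peak lists, titration
# manifests and ITC experiment descriptions. All formats are plain text
# (YAML key-value configs, TSV/CSV tables).

#' Read a secondary-structure-element map
#'
#' The config is YAML with an `elements` list; each element has `name`
#' (e.g. "b1", "a1", "L1", "310a"), `start`, `end` (residue numbers,
#' mature numbering) and `kind` (one of strand, helix, 310, loop).
#'
#' @param path YAML file path.
#' @return data.frame of class `"sse_map"` with columns `name`, `start`,
#'   `end`, `kind`.
#' @export
read_sse_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$elements)) stop("SSE config lacks an 'elements' list")
  df <- do.call(rbind, lapply(cfg$elements, function(e) {
    data.frame(name = as.character(e$name), start = as.integer(e$start),
               end = as.integer(e$end), kind = as.character(e$kind),
               stringsAsFactors = FALSE)
  }))
  validate_sse_map(df)
}

#' Validate (and class) an SSE map data.frame
#'
#' Checks start <= end and that ranges do not overlap within a kind.
#'
#' @param df data.frame with columns `name`, `start`, `end`, `kind`.
#' @return the validated data.frame with class `"sse_map"`.
#' @export
validate_sse_map <- function(df) {
  stopifnot(all(c("name", "start", "end", "kind") %in% names(df)))
  if (any(df$start > df$end)) stop("SSE with start > end: ",
                                   df$name[df$start > df$end][1])
  if (!all(df$kind %in% c("strand", "helix", "310", "loop")))
    stop("unknown SSE kind")
  for (k in unique(df$kind)) {
    e <- df[df$kind == k, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)]))
      stop("overlapping ", k, " ranges in SSE map")
  }
  class(df) <- c("sse_map", "data.frame")
  df
}

#' Map residue numbers to SSE names
#'
#' @param sse an `"sse_map"`.
#' @param resno residue numbers.
#' @return character vector of element names (NA where unassigned; the
#'   first matching element wins).
#' @export
sse_assign <- function(sse, resno) {
  out <- rep(NA_character_, length(resno))
  for (i in seq_len(nrow(sse))) {
    hit <- is.na(out) & resno >= sse$start[i] & resno <= sse$end[i]
    out[hit] <- sse$name[i]
  }
  out
}

#' Read a loop-pair / distance-pair specification table
#'
#' YAML with a `pairs` list; each pair has `name`, `residue_a`, `atom_a`,
#' `residue_b`, `atom_b`.
#'
#' @param path YAML file path.
#' @return data.frame with those five columns.
#' @export
read_loop_pairs <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$pairs)) stop("pair config lacks a 'pairs' list")
  do.call(rbind, lapply(cfg$pairs, function(p) {
    data.frame(name = as.character(p$name),
               residue_a = as.integer(p$residue_a),
               atom_a = as.character(p$atom_a),
               residue_b = as.integer(p$residue_b),
               atom_b = as.character(p$atom_b), stringsAsFactors = FALSE)
  }))
}

# ---- peak lists -----------------------------------------------------------

#' Construct/validate an HSQC peak list
#'
#' One backbone NH peak per residue: columns `residue`, `h_ppm`, `n_ppm`,
#' `intensity`, `flags` (comma-separated subset of "overlapped",
#' "unresolved"; empty when clean).
#'
#' @param df data.frame with the columns above (`flags` optional).
#' @return data.frame of class `"peak_list"`.
#' @export
peak_list <- function(df) {
  stopifnot(all(c("residue", "h_ppm", "n_ppm", "intensity") %in% names(df)))
  if (is.null(df$flags)) df$flags <- ""
  df$flags[is.na(df$flags)] <- ""
  if (anyDuplicated(df$residue))
    stop("duplicate residue in peak list: ",
         df$residue[duplicated(df$residue)][1])
  if (!all(is.finite(df$h_ppm)) || !all(is.finite(df$n_ppm)))
    stop("non-finite chemical shift")
  if (any(df$intensity < 0)) stop("negative peak intensity")
  df <- df[order(df$residue), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("peak_list", "data.frame")
  df
}

#' Read a TSV peak list
#'
#' Tab-separated with header `residue  h_ppm  n_ppm  intensity  flags`.
#'
#' @param path file path.
#' @return a [peak_list()].
#' @export
read_peaklist <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("integer", "numeric", "numeric",
                                  "numeric", "character"),
                   stringsAsFactors = FALSE)
  peak_list(df)
}

#' Write a peak list as TSV
#' @param peaks a [peak_list()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaks, path) {
  write.table(peaks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a minimal Sparky-style assignment list
#'
#' Lines of the form `V42N-H  119.52  8.113  1.2e6` (assignment, w1 = 15N
#' ppm, w2 = 1H ppm, height). The residue number is extracted from the
#' assignment label; lines that do not parse are dropped with a warning.
#'
#' @param path file path.
#' @return a [peak_list()] with empty flags.
#' @export
read_sparky_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^(Assignment|#)", lines)]
  parts <- strsplit(lines, "[[:space:]]+")
  ok <- vapply(parts, function(p)
    length(p) >= 3 && grepl("^[A-Za-z]?[0-9]+", p[1]), logical(1))
  if (any(!ok)) warning(sum(!ok), " unparseable line(s) skipped")
  parts <- parts[ok]
  res <- vapply(parts, function(p)
    as.integer(sub("^[A-Za-z]*([0-9]+).*$", "\\1", p[1])), integer(1))
  w1 <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  w2 <- vapply(parts, function(p) as.numeric(p[3]), numeric(1))
  ht <- vapply(parts, function(p)
    if (length(p) >= 4) as.numeric(p[4]) else 1, numeric(1))
  peak_list(data.frame(residue = res, h_ppm = w2, n_ppm = w1,
                       intensity = ht, flags = "",
                       stringsAsFactors = FALSE))
}

# ---- titration series -----------------------------------------------------

#' Construct a titration series
#'
#' @param levels strictly increasing numeric titrant levels starting at 0
#'   (the reference).
#' @param peaklists list of [peak_list()]s, one per level.
#' @param axis_label what the level axis means, e.g. `"urea M"` or
#'   `"ligand:protein molar ratio"`.
#' @return object of class `"titration_series"`.
#' @export
titration_series <- function(levels, peaklists, axis_label = "level") {
  stopifnot(length(levels) == length(peaklists), length(levels) >= 1)
  if (levels[1] != 0) stop("reference point (level 0) must be present")
  if (any(diff(levels) <= 0)) stop("levels must be strictly increasing")
  peaklists <- lapply(peaklists, peak_list)
  structure(list(axis_label = axis_label, levels = as.numeric(levels),
                 peaklists = peaklists), class = "titration_series")
}

#' Read a titration series from a manifest
#'
#' YAML manifest with `axis_label` and a `points` list of `{level, file}`
#' entries; peak-list paths are resolved relative to the manifest.
#'
#' @param path manifest file path.
#' @return a [titration_series()].
#' @export
read_titration_series <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$points)) stop("titration manifest lacks 'points'")
  base <- dirname(path)
  levels <- vapply(cfg$points, function(p) as.numeric(p$level), numeric(1))
  pls <- lapply(cfg$points, function(p) {
    f <- p$file
    if (!file.exists(f)) f <- file.path(base, p$file)
    read_peaklist(f)
  })
  ord <- order(levels)
  titration_series(levels[ord], pls[ord],
                   axis_label = cfg$axis_label %||% "level")
}

#' Write a titration series (peak lists + manifest) to a directory
#'
#' @param series a [titration_series()].
#' @param dir output directory (created if needed).
#' @param name basename for the manifest and peak-list files.
#' @return manifest path, invisibly.
#' @export
write_titration_series <- function(series, dir, name = "series") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_%02d.tsv", name, seq_along(series$levels))
  for (i in seq_along(files))
    write_peaklist(series$peaklists[[i]], file.path(dir, files[i]))
  manifest <- file.path(dir, paste0(name, ".yaml"))
  yaml::write_yaml(list(axis_label = series$axis_label,
                        points = Map(function(l, f) list(level = l, file = f),
                                     series$levels, files)), manifest)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- ITC ------------------------------------------------------------------

#' Read an ITC injection table
#'
#' CSV with header `injection, volume_ul, heat_ucal` (heat column may be
#' absent for a schedule-only file).
#'
#' @param path CSV file path.
#' @return data.frame with `injection`, `volume_ul` and (if present)
#'   `heat_ucal`.
#' @export
read_itc_csv <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", strip.white = TRUE)
  stopifnot(all(c("injection", "volume_ul") %in% names(df)))
  df
}

#' Write an ITC experiment's injection table as CSV
#' @param expt an [itc_experiment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_itc_csv <- function(expt, path) {
  df <- data.frame(injection = seq_along(expt$injections_ul),
                   volume_ul = expt$injections_ul)
  if (!is.null(expt$heats_ucal)) df$heat_ucal <- expt$heats_ucal
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read ITC experiment metadata
#'
#' YAML with `cell_volume_ul`, `cell_conc_uM`, `syringe_conc_uM`,
#' `temperature_K` (default 298.15) and `discard_first` (default TRUE).
#'
#' @param path YAML file path.
#' @param injections data.frame from [read_itc_csv()] supplying the
#'   injection schedule (and heats, if measured).
#' @return an [itc_experiment()].
#' @export
read_itc_config <- function(path, injections) {
  cfg <- yaml::read_yaml(path)
  itc_experiment(cell_volume_ul = cfg$cell_volume_ul,
                 cell_conc_uM = cfg$cell_conc_uM,
                 syringe_conc_uM = cfg$syringe_conc_uM,
                 injections_ul = injections$volume_ul,
                 heats_ucal = injections$heat_ucal,
                 temperature_K = cfg$temperature_K %||% 298.15,
                 discard_first = cfg$discard_first %||% TRUE)
}
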