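#' Write a detector map as delimited text
#'
#' Tab-separated matrix preceded by `#`-prefixed geometry header lines.
#' Values are written with 17 significant digits, so a read/write cycle is
#' bit-exact.
#'
#' @param map a [detector_map()].
#' @param path output file.
#' @export
write_map_tsv <- function(map, path) {
  stopifnot(inherits(map, "detector_map"))
  g <- map$geometry
  hdr <- c(sprintf("# n_axial\t%d", g$n_axial),
           sprintf("# n_circ\t%d", g$n_circ),
           sprintf("# radius\t%.17g", g$radius),
           sprintf("# axial_pitch\t%.17g", g$axial_pitch))
  body <- apply(map$values, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a detector map written by [write_map_tsv()]
#' @param path input file.
#' @return a [detector_map()].
#' @export
read_map_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, "\t"), hdr, value = TRUE)
    if (length(ln) != 1) stop("missing header field: ", key)
    as.numeric(strsplit(ln, "\t")[[1]][2])
  }
  g <- detector_geometry(get("n_axial"), get("n_circ"),
                         get("radius"), get("axial_pitch"))
  body <- lines[!grepl("^#", lines)]
  vals <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  detector_map(vals, g)
}

#' Export a dataset as a directory of text matrices
#'
#' One `calc_<id>.tsv` / `meas_<id>.tsv` pair per sample plus a
#' `manifest.json` with labels, signs, techniques and the generating
#' configuration's seed.  Round-trips bit-exactly through
#' [read_dataset_dir()].
#'
#' @param dataset a `qa_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_dataset_dir <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(n = length(dataset), samples = lapply(dataset, function(s)
    list(plan_id = s$plan_id, class = s$label$class,
         magnitude = s$label$magnitude, sign = s$label$sign,
         technique = s$technique)))
  cfg <- attr(dataset, "config")
  if (!is.null(cfg)) manifest$seed <- cfg$seed
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (s in dataset) {
    write_map_tsv(s$calculated, file.path(dir, sprintf("calc_%s.tsv", s$plan_id)))
    write_map_tsv(s$measured, file.path(dir, sprintf("meas_%s.tsv", s$plan_id)))
  }
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset_dir()]
#' @param dir dataset directory.
#' @return a `qa_dataset`.
#' @export
read_dataset_dir <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  samples <- lapply(manifest$samples, function(m) {
    structure(list(
      calculated = read_map_tsv(file.path(dir, sprintf("calc_%s.tsv", m$plan_id))),
      measured = read_map_tsv(file.path(dir, sprintf("meas_%s.tsv", m$plan_id))),
      label = error_spec(m$class, magnitude = m$magnitude, sign = m$sign),
      technique = m$technique, plan_id = m$plan_id),
      class = "plan_sample")
  })
  structure(samples, class = "qa_dataset")
}

#' Serialize a split plan to JSON
#' @param split a [make_split()] result.
#' @param path output file.
#' @export
write_split_json <- function(split, path) {
  stopifnot(inherits(split, "split_plan"))
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a split plan written by [write_split_json()]
#' @param path input file.
#' @return a `split_plan`.
#' @export
read_split_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$folds <- lapply(x$folds, as.character)
  structure(list(train_ids = as.character(x$train_ids),
                 test_ids = as.character(x$test_ids),
                 folds = x$folds, seed = as.integer(x$seed)),
            class = "split_plan")
}

#' Full-pipeline run configuration
#'
#' One plain-text (JSON) file reproduces a whole experiment: the
#' simulation block, the criteria, the split seed and the training
#' configuration.  [read_run_config()] round-trips it losslessly.
#'
#' @param sim a [sim_config()].
#' @param train a [train_config()].
#' @param split_seed seed for [make_split()].
#' @param augment_factor expansion factor for [augment()].
#' @param out_dir artifact directory for [run_pipeline()].
#' @param verbose print per-stage progress.
#' @export
run_config <- function(sim = sim_config(), train = train_config(),
                       split_seed = 1L, augment_factor = 5L,
                       out_dir = "arcqa_run", verbose = TRUE) {
  structure(list(sim = sim, train = train,
                 split_seed = as.integer(split_seed),
                 augment_factor = as.integer(augment_factor),
                 out_dir = out_dir, verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Write a run configuration file
#' @param config a [run_config()].
#' @param path output JSON file.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$sim <- unclass(x$sim); x$sim$geometry <- unclass(x$sim$geometry)
  x$train <- unclass(x$train)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration file
#' @param path JSON file written by [write_run_config()].
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- do.call(detector_geometry, x$sim$geometry)
  sim <- do.call(sim_config, c(x$sim[setdiff(names(x$sim), "geometry")],
                               list(geometry = geom)))
  train <- do.call(train_config, x$train)
  run_config(sim = sim, train = train, split_seed = x$split_seed,
             augment_factor = x$augment_factor, out_dir = x$out_dir,
             verbose = x$verbose)
}
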