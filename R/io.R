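# Plain-text I/O: tidy trace CSV, pulse tables, YAML configs.

#' Write / read a tidy trace table
#'
#' Traces are stored as plain CSV with one row per cell per frame and the
#' columns produced by [simulate_ktr_dataset()] (`cell_id`, `parent_id`,
#' `frame`, `time_min`, `ratio`, `x_px`, `y_px`, `expression`,
#' `divided_this_frame`, `died_this_frame`).
#'
#' @param traces Trace data frame.
#' @param path File path.
#' @return `write_traces` invisibly returns `path`; `read_traces` returns
#'   the data frame with logical flag columns restored.
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  tr <- utils::read.csv(path)
  for (col in c("divided_this_frame", "died_this_frame")) {
    if (col %in% names(tr)) tr[[col]] <- as.logical(tr[[col]])
  }
  tr
}

#' Read a generator or detector configuration from YAML or JSON
#'
#' The file must contain a top-level `type` field naming the
#' configuration (`puncta_scene`, `translocation_scene`, `ktr_sim`,
#' `decay_sim`, `puncta_params` or `pulse_params`); the remaining fields
#' are passed to the corresponding constructor, so defaults apply to
#' anything omitted.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return The validated configuration object.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$type)) {
    stop("config file must have a `type` field", call. = FALSE)
  }
  constructors <- list(puncta_scene = puncta_scene_config,
                       translocation_scene = translocation_scene_config,
                       ktr_sim = ktr_sim_config,
                       decay_sim = decay_sim_config,
                       puncta_params = puncta_params,
                       pulse_params = pulse_params)
  ctor <- constructors[[raw$type]]
  if (is.null(ctor)) {
    stop(sprintf("unknown config type '%s'", raw$type), call. = FALSE)
  }
  args <- raw[setdiff(names(raw), "type")]
  # YAML scalars arrive length-1; range fields may be lists
  args <- lapply(args, function(a) if (is.list(a)) unlist(a) else a)
  if (raw$type == "ktr_sim" && !is.null(args$expression_levels)) {
    args$expression_levels <- as.list(args$expression_levels)
  }
  do.call(ctor, args)
}

#' Write ground truth (or any result list) as JSON
#'
#' @param x A list (e.g. the `truth` element of a generator output).
#'   Matrix elements are converted to nested arrays; configs are stored
#'   as plain lists.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(unclass_deep(x), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null",
                       pretty = TRUE)
  invisible(path)
}

# strip S3 classes recursively so jsonlite serializes plainly
unclass_deep <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else {
    x
  }
}
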