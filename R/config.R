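# Configuration documents and provenance.

#' Read a simulation configuration file
#'
#' A configuration is one YAML (or JSON) document with up to three blocks:
#' `params` (fields of [sim_params()]), `strategies` (a list of
#' [strategy_spec()] argument sets) and `experiment` (free-form fields used
#' by the caller: `counts`, `seed`, `replicates`, `snapshot_every`,
#' `mutual_immunity`). Unknown keys anywhere are rejected.
#'
#' @param path Path to the YAML/JSON file.
#' @return List with `params` (a `t6_params`), `strategies` (list of
#'   `t6_strategy`) and `experiment` (a list).
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  check_keys(doc, c("params", "strategies", "experiment"), "top level")
  params <- do.call(sim_params, as_args(doc$params, formals(sim_params), "params"))
  strategies <- lapply(doc$strategies, function(s) {
    args <- as_args(s, formals(strategy_spec), "strategies")
    if (!is.null(args$immune_to)) args$immune_to <- unlist(args$immune_to)
    do.call(strategy_spec, args)
  })
  exp_keys <- c("counts", "seed", "replicates", "snapshot_every",
                "mutual_immunity")
  if (!is.null(doc$experiment)) check_keys(doc$experiment, exp_keys, "experiment")
  list(params = params, strategies = strategies,
       experiment = if (is.null(doc$experiment)) list() else doc$experiment)
}

check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    stop(sprintf("unknown key(s) in %s: %s", where, paste(extra, collapse = ", ")))
  invisible(block)
}

as_args <- function(block, fml, where) {
  if (is.null(block)) return(list())
  check_keys(block, names(fml), where)
  block
}

#' Content hash and environment record of a configuration
#'
#' Canonicalizes the configuration (keys sorted recursively, values
#' JSON-encoded) and returns its MD5 hash together with a minimal
#' environment record. The hash depends only on content, not on key order.
#'
#' @param config Any nested list (e.g. the output of [read_config()] or a
#'   raw document).
#' @return List with `hash`, `r_version` and `package_version`.
#' @export
provenance_stamp <- function(config) {
  canon <- canonicalize(config)
  js <- jsonlite::toJSON(canon, auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  hash <- unname(tools::md5sum(tf))
  list(hash = hash,
       r_version = as.character(getRversion()),
       package_version = as.character(utils::packageVersion("t6duel")))
}

canonicalize <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) {
      x <- x[order(nm)]
      lapply(x, canonicalize)
    } else lapply(x, canonicalize)
  } else x
}
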