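#' Read and validate an instance configuration
#'
#' YAML configuration for building a knowledge-base instance. Recognized
#' keys: \code{collections} (list of \code{name}/\code{path}/\code{format}
#' entries; formats gmt, obo, yaml, json), \code{k}, \code{weighting}
#' (\code{c0}, \code{c1}), \code{max_features}, \code{backend},
#' \code{diffusion} (named default strengths). Unknown keys are rejected
#' so typos fail loudly before any build work starts.
#'
#' @param path YAML file path.
#' @return list with \code{config} (a \code{\link{kb_config}}),
#'   \code{collections} spec, and \code{diffusion} defaults.
#' @export
read_instance_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  allowed <- c("collections", "k", "weighting", "max_features",
               "backend", "diffusion")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(raw$collections) || length(raw$collections) == 0L)
    stop("config key 'collections' is required")
  weighting <- raw$weighting
  if (!is.null(weighting)) {
    bad <- setdiff(names(weighting), c("c0", "c1"))
    if (length(bad))
      stop("unknown weighting key(s): ", paste(bad, collapse = ", "))
  }
  cfg <- kb_config(
    k = if (is.null(raw$k)) 6L else raw$k,
    c0 = if (is.null(weighting$c0)) 0 else weighting$c0,
    c1 = if (is.null(weighting$c1)) 1 else weighting$c1,
    max_features = if (is.null(raw$max_features)) 200000L
                   else raw$max_features,
    backend = if (is.null(raw$backend)) "exact" else raw$backend)
  for (cc in raw$collections) {
    miss <- setdiff(c("name", "path"), names(cc))
    if (length(miss))
      stop("collection entry missing key(s): ",
           paste(miss, collapse = ", "))
  }
  list(config = cfg, collections = raw$collections,
       diffusion = raw$diffusion)
}

read_collection_file <- function(path, format = NULL) {
  if (!file.exists(path))
    stop("data file not found: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  switch(format,
    gmt = sets_to_items(read_gmt(path)),
    obo = obo_to_items(read_obo(path)),
    yaml = , yml = {
      items <- yaml::read_yaml(path)
      do.call(rbind, lapply(items, function(it)
        data.frame(id = it$id, title = it$title,
                   body = if (is.null(it$body)) it$data else it$body,
                   stringsAsFactors = FALSE)))
    },
    json = {
      df <- jsonlite::fromJSON(path)
      if (!is.data.frame(df)) df <- do.call(rbind.data.frame, df)
      if (is.null(df$body) && !is.null(df$data)) df$body <- df$data
      df[c("id", "title", "body")]
    },
    stop("unsupported collection format: ", format))
}

#' Build a knowledge base from an instance configuration
#'
#' @param path YAML config path (see \code{\link{read_instance_config}}).
#' @return a \code{knowledge_base}.
#' @export
build_from_config <- function(path) {
  inst <- read_instance_config(path)
  dir <- dirname(path)
  colls <- lapply(inst$collections, function(cc) {
    p <- cc$path
    if (!file.exists(p))
      p <- file.path(dir, cc$path)
    read_collection_file(p, cc$format)
  })
  names(colls) <- vapply(inst$collections, `[[`, "", "name")
  kb_build(colls, inst$config)
}
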