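#' Read / write a Stage-1 parameter specification
#'
#' The specification is a JSON array of objects with `name`, `lower`,
#' `upper`, `init`; a shipped default lives at
#' `system.file("extdata", "stage1_params.json", package = "myoperf")`.
#'
#' @param path JSON file path.
#' @return data.frame usable as `param_spec` in [stage1_tune()].
#' @export
read_param_spec <- function(path) {
  df <- jsonlite::fromJSON(path)
  req <- c("name", "lower", "upper", "init")
  if (!all(req %in% names(df))) {
    stop("param spec must provide columns: ", paste(req, collapse = ", "))
  }
  if (any(df$lower > df$upper)) stop("lower bound exceeds upper bound")
  df[req]
}

#' @rdname read_param_spec
#' @param spec a param-spec data.frame.
#' @export
write_param_spec <- function(spec, path) {
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
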