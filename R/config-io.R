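#' Read and write generator configurations as YAML
#'
#' Serializes a [synthetic_emg_config()] or [synthetic_session_config()]
#' (the class is stored alongside the fields) so study conditions can be
#' versioned and shared as plain text.
#'
#' @param config a configuration object.
#' @param path YAML file path.
#' @return `read_config()` returns the rebuilt configuration object, with
#'   all invariants re-validated by the constructor; `write_config()`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  cls <- class(config)[1]
  if (!cls %in% c("synthetic_emg_config", "synthetic_session_config")) {
    stop("unsupported configuration class: ", cls)
  }
  yaml::write_yaml(c(list(config_class = cls), unclass(config)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$config_class
  obj$config_class <- NULL
  ctor <- switch(cls,
                 synthetic_emg_config = synthetic_emg_config,
                 synthetic_session_config = synthetic_session_config,
                 stop("unsupported configuration class: ", cls))
  args <- obj[names(obj) %in% names(formals(ctor))]
  do.call(ctor, args)
}
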