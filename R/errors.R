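# Condition helpers. Two broad classes drive CLI exit codes:
#   amap_data_error   -> malformed/degenerate input data        (exit 1)
#   amap_config_error -> invalid parameters or configuration    (exit 2)
# Finer subclasses let callers distinguish failure modes.

stop_data <- function(msg, subclass = NULL, call = sys.call(-1)) {
  stop(structure(
    class = c(subclass, "amap_data_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_config <- function(msg, subclass = NULL, call = sys.call(-1)) {
  stop(structure(
    class = c(subclass, "amap_config_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

warn_amap <- function(msg, subclass = NULL) {
  warning(structure(
    class = c(subclass, "amap_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}
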