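# Classed conditions so the CLI can map error categories to exit codes.

ct_error <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "ctsubvol_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

ct_warn <- function(message, class = "ctsubvol_warning") {
  warning(structure(
    class = c(class, "ctsubvol_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}
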