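# Structured error conditions. Every pathcover error inherits "pc_error" plus a
# specific class so callers (and the CLI exit-code mapping) can dispatch on it.

pc_stop <- function(class, msg, ..., call. = FALSE) {
  stop(errorCondition(msg, ..., class = c(class, "pc_error", "error", "condition")))
}

pc_cycle_error         <- function(msg, ...) pc_stop("pc_cycle_error", msg, ...)
pc_format_error        <- function(msg, ...) pc_stop("pc_format_error", msg, ...)
pc_validation_error    <- function(msg, ...) pc_stop("pc_validation_error", msg, ...)
pc_infeasible_error    <- function(msg, ...) pc_stop("pc_infeasible_error", msg, ...)
pc_limit_error         <- function(msg, ...) pc_stop("pc_limit_error", msg, ...)
pc_merge_error         <- function(msg, ...) pc_stop("pc_merge_error", msg, ...)
pc_lift_error          <- function(msg, ...) pc_stop("pc_lift_error", msg, ...)
pc_decomposition_error <- function(msg, ...) pc_stop("pc_decomposition_error", msg, ...)
pc_realization_error   <- function(msg, ...) pc_stop("pc_realization_error", msg, ...)
pc_gadget_error        <- function(msg, ...) pc_stop("pc_gadget_error", msg, ...)
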