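# Classed conditions so callers (and the CLI exit-code mapping) can
# distinguish user errors from integrity/backend failures.

bb_stop <- function(message, class, ...) {
  stop(structure(
    class = c(class, "bb_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# user-facing errors -> CLI exit code 1
bb_user_classes <- c(
  "bb_not_found_error", "bb_config_error", "bb_schema_error",
  "bb_parse_error", "bb_wrong_kind_error", "bb_cycle_error",
  "bb_ambiguity_error", "bb_collision_error", "bb_not_installed_error",
  "bb_argument_error", "bb_duplicate_dependency_error", "bb_usage_error"
)

# integrity / backend errors -> CLI exit code 2
bb_system_classes <- c(
  "bb_integrity_error", "bb_backend_error", "bb_io_error",
  "bb_missing_object_error"
)

is_bb_user_error <- function(cond) {
  any(class(cond) %in% bb_user_classes)
}
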