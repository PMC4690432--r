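# Structured error conditions. Every package error carries a class of the
# form "mg_<snake_case>" plus "mg_error", so callers (and the CLI) can branch
# on the failure kind without parsing messages.

mg_stop <- function(class, message, ..., call. = FALSE) {
  data <- list(...)
  cond <- structure(
    class = c(class, "mg_error", "error", "condition"),
    c(list(message = message, call = NULL), data)
  )
  stop(cond)
}

# Exit-code mapping used by the CLI: 1 = user error, 2 = blocked by
# conflict/inconsistency, 3 = internal.
mg_user_error_classes <- c(
  "mg_file_not_found", "mg_sbml_parse_error", "mg_unsupported_feature",
  "mg_unknown_key", "mg_syntax_error", "mg_duplicate_name",
  "mg_unknown_parent", "mg_unknown_node", "mg_cycle_error",
  "mg_non_ancestor_reference", "mg_no_local_assignment",
  "mg_no_such_conflict", "mg_format_version_error", "mg_schema_error",
  "mg_invalid_assignment", "mg_invalid_spec", "mg_missing_reference",
  "mg_arithmetic_error"
)

mg_blocked_classes <- c(
  "mg_conflict_error", "mg_dangling_reference", "mg_reference_cycle_error",
  "mg_blocked_by_conflict", "mg_blocked_by_inconsistency"
)
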