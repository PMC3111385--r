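# Shared fixtures, computed once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture_ref <- function() {
  if (is.null(.fixture_env$ref)) .fixture_env$ref <- mip_reference()
  .fixture_env$ref
}

fixture_queries <- function() {
  if (is.null(.fixture_env$qs)) .fixture_env$qs <- synthesize_query_set()
  .fixture_env$qs
}

# aligned + trimmed query by id, cached
fixture_aligned <- function(id) {
  key <- paste0("aq_", id)
  if (is.null(.fixture_env[[key]])) {
    qs <- fixture_queries()
    ref <- fixture_ref()
    .fixture_env[[key]] <- trim_to_core(
      align_to_profile(mip_sequence(id, qs$proteins[[id]]), ref), ref)
  }
  .fixture_env[[key]]
}

fixture_features <- function(id) {
  key <- paste0("ft_", id)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- feature_profile(fixture_aligned(id), fixture_ref())
  .fixture_env[[key]]
}

extdata <- function(name) {
  system.file("extdata", name, package = "mipscan", mustWork = TRUE)
}
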