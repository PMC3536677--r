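
# internal validation helpers ------------------------------------------------

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

assert_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  assert_that(
    length(missing) == 0,
    paste0(what, " is missing column(s): ", paste(missing, collapse = ", "))
  )
}

#' Derive a stage-specific seed from a global seed
#'
#' Stage seeds are deterministic functions of the global seed so that a single
#' integer reproduces a whole pipeline run while keeping stages decoupled
#' (changing the number of draws in one stage does not perturb the next).
#' Values stay below 2^31 - 1.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (character) or index.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  assert_that(is.numeric(seed) && length(seed) == 1, "seed must be a single number")
  idx <- if (is.character(stage)) {
    sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  } else {
    as.integer(stage)
  }
  as.integer((as.double(seed) * 7919 + idx) %% 2147483647L)
}

# half-open interval gap; 0 when intervals intersect
interval_gap <- function(a_start, a_end, b_start, b_end) {
  gap <- pmax(b_start - a_end, a_start - b_end)
  pmax(gap, 0)
}
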