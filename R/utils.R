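#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. Nothing here is exported.

UNASSIGNED <- 0L

stop_coexhub <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "coexhub_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

warn_coexhub <- function(msg, class) {
  warning(structure(
    class = c(class, "coexhub_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_matrix <- function(x, what = "values") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_coexhub(sprintf("`%s` must be a numeric matrix", what),
                 "coexhub_bad_input")
  }
  invisible(x)
}

assert_no_missing <- function(x, what = "values") {
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- apply(utils::head(bad, 10), 1, function(rc) {
      sprintf("[%d,%d]", rc[1], rc[2])
    })
    stop_coexhub(
      sprintf("`%s` contains %d missing/non-finite cells, e.g. %s",
              what, nrow(bad), paste(cells, collapse = ", ")),
      "coexhub_missing_values"
    )
  }
  invisible(x)
}

assert_fraction <- function(x, what, closed_right = FALSE) {
  hi_ok <- if (closed_right) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0 || !hi_ok) {
    stop_coexhub(sprintf("`%s` must be a fraction in (0,1%s]", what,
                         if (closed_right) "" else ")"),
                 "coexhub_bad_input")
  }
  invisible(x)
}

assert_count <- function(x, what, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) ||
      x < min || x != round(x)) {
    stop_coexhub(sprintf("`%s` must be an integer >= %d", what, min),
                 "coexhub_bad_input")
  }
  invisible(as.integer(x))
}

# Deterministic child-seed derivation: one global seed fans out to stages so
# a stage can be re-run in isolation and still match a full pipeline run.
# Kept well below 2^31.
derive_seed <- function(seed, stage, index = 0L) {
  stage_id <- sum(utf8ToInt(stage))
  as.integer((as.numeric(seed) * 2654435 + stage_id * 97 + index) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
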