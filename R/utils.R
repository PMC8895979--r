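# Internal helpers shared across modules.

BASES6 <- c("A", "T", "C", "G", "N", "del")
NUCS <- c("A", "T", "C", "G")

#' Derive a stage-specific seed from a master seed
#'
#' Each simulation stage draws from its own stream so stages can be re-run
#' independently without disturbing one another. The derived seed stays below
#' 2^31 - 1.
#'
#' @param seed master seed (single integer).
#' @param stage integer stage identifier.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer(((abs(as.double(seed)) %% 2147483647) * 48271 + stage * 7919) %% 2147483647)
}

assert_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x) ||
      (positive && x <= 0) || (!positive && x < 0)) {
    stop(sprintf("'%s' must be a %s integer", name,
                 if (positive) "positive" else "nonnegative"), call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (open && (x <= 0 || x >= 1)) || (!open && (x < 0 || x > 1))) {
    stop(sprintf("'%s' must lie in %s", name, if (open) "(0, 1)" else "[0, 1]"),
         call. = FALSE)
  }
  invisible(as.numeric(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
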