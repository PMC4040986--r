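# Internal helpers shared across modules.

#' Derive a reproducible child seed from a global seed
#'
#' All stochastic operations take a single integer seed and derive a
#' stage-specific child seed from it, so that one global seed pins down the
#' whole analysis while stages remain independently reproducible.
#'
#' @param seed Integer global seed.
#' @param tag Character stage tag (e.g. `"community"`).
#' @return An integer in `[0, 2^31 - 1)`.
#' @keywords internal
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(tag)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' Round half away from zero to one decimal
#'
#' `base::round()` rounds half to even; completeness and contamination
#' percentages are conventionally presented with half rounded away from
#' zero (98.15 -> 98.2), which this helper implements.
#'
#' @param x Numeric vector.
#' @return Numeric vector rounded to one decimal place.
#' @keywords internal
round1 <- function(x) {
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

# Assign n items to k consecutive groups as evenly as possible.
split_even <- function(n, k) {
  rep(seq_len(k), times = diff(floor(seq(0, n, length.out = k + 1))))
}

stop_if_not_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) ||
      x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}
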