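#' Derive a reproducible per-unit seed from a root seed
#'
#' Parallel and serial runs must agree gene-by-gene, so every stochastic
#' per-gene step (posterior simulation) draws from its own RNG stream seeded
#' deterministically from the run's root seed and the gene identifier.
#'
#' @param root integer root seed for the run.
#' @param id character identifier (e.g. a gene id) mixed into the seed.
#' @return an integer in \[0, 2^31 - 2\] usable with [set.seed()].
#' @export
derive_seed <- function(root, id) {
  stopifnot(length(root) == 1L, is.finite(root), length(id) == 1L)
  m <- 2147483647  # 2^31 - 1, keeps the result a valid 32-bit integer seed
  h <- as.numeric(root) %% m
  for (ch in utf8ToInt(as.character(id))) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

# Internal: FNV-1a style hash of a config list, for run manifests.
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), ch)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Internal: stop with a comma-limited listing of offenders.
stop_listing <- function(msg, offenders, max_show = 10L) {
  shown <- utils::head(offenders, max_show)
  more <- length(offenders) - length(shown)
  suffix <- if (more > 0) sprintf(" ... and %d more", more) else ""
  stop(msg, ": ", paste(shown, collapse = ", "), suffix, call. = FALSE)
}

# Internal: trapezoidal integral of y over x (both numeric, same length).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
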