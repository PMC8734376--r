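#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going up, the convention under
#' which the screened-subset size formula reproduces its published values.
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' Derive a replicate-level seed from a master seed
#'
#' Deterministic, collision-free over the replicate indices used in a study,
#' and kept inside the 32-bit integer range R requires of `set.seed()`.
#' @noRd
derive_seed <- function(master, index) {
  as.integer((as.double(master) %% 65011 * 33013 + as.double(index) * 7907) %% 2147483629) + 1L
}

stop_bad_arg <- function(msg, ...) abort(msg, class = "ahazmed_bad_arg", ...)

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_bad_arg(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    stop_bad_arg(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}
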