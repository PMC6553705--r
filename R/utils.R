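`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Integer rounding used for reported percentages: 0.5 always rounds away
#' from zero (unlike base [round()], which rounds half to even).
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Derive a reproducible sub-seed from a root seed and a stage label.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

z_score <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
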