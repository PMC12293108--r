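# internal validation helpers ------------------------------------------------

stop_if_not_scalar_number <- function(x, name, lower = -Inf, allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && (allow_inf || is.finite(x)) &&
    !is.na(x) && x >= lower
  if (!ok) {
    abort(sprintf("`%s` must be a single %snumber >= %s, got %s",
                  name, if (allow_inf) "" else "finite ", format(lower),
                  paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

stop_if_not_positive <- function(x, name) {
  stop_if_not_scalar_number(x, name, lower = 0)
  if (x <= 0) abort(sprintf("`%s` must be > 0", name))
  invisible(x)
}

set_seed_if_given <- function(seed) {
  if (!is.null(seed)) {
    stop_if_not_scalar_number(seed, "seed")
    set.seed(as.integer(seed))
  }
  invisible(seed)
}

# softmax / logit transforms used by the mixture fitter
softmax <- function(z) {
  z <- c(z, 0)
  e <- exp(z - max(z))
  e / sum(e)
}

inv_softmax <- function(p) {
  # returns length(p) - 1 free logits (last component is reference)
  log(p[-length(p)]) - log(p[length(p)])
}
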