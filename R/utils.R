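#' @keywords internal
"_PACKAGE"

expit <- function(x) 1 / (1 + exp(-x))

# Deterministic child seed: keeps every derived seed a valid 32-bit integer.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(salt) * 104729) %%
               (.Machine$integer.max - 1L)) + 1L
}

# Unweighted mode with a deterministic tie-break: first label in level order.
mode_category <- function(x, levels) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_character_)
  tab <- table(factor(x, levels = levels))
  levels[which.max(tab)]
}

# Weighted quantiles of type 1 (left-continuous inverse CDF).
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1L]], numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
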