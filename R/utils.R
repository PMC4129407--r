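# internal helpers shared across modules

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Pooled dosage-based allele frequency: sum(dosage) / (2N).
dosage_freq <- function(x) sum(x) / (2 * length(x))

# upper-tail chi-square p-value, guarded for df = 0
chisq_upper <- function(stat, df) {
  if (df <= 0) return(1)
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

stop_hfm <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "hlafinemap_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# order labels by descending frequency, ties broken lexicographically
order_by_freq <- function(freqs, labels) {
  order(-freqs, labels)
}
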