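# internal helpers

recycle_n <- function(x, n) {
  if (length(x) == n) return(x)
  if (length(x) == 1L) return(rep(x, n))
  if (n == 0L) return(x[0])
  stop("cannot recycle length ", length(x), " to ", n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
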