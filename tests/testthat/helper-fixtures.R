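# Shared fixtures, all generated in code.

# small default-config dataset, memoised per test file run
small_caussim <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 400, seed = 11, ...) {
    key <- paste(n, seed, deparse(list(...)), collapse = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <- sample_caussim(caussim_config(n_samples = n,
                                                    seed = seed, ...))
    cache[[key]]
  }
})

# a tiny two-spec family for fast selection tests
tiny_family <- function(seed = 5) {
  build_caussim_family(n_bases = 1, seed = seed)
}

# brute-force Kendall tau-b: counts concordant/discordant pairs directly
kendall_brute <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sx <- sign(x[j] - x[i])
      sy <- sign(y[j] - y[i])
      if (sx == 0 && sy == 0) next
      if (sx == 0) tx <- tx + 1
      else if (sy == 0) ty <- ty + 1
      else if (sx == sy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}
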