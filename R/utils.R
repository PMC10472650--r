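# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so generators never perturb user code.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(code)
}

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("mvspop_parameter_error", "error")))
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("mvspop_input_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Method-of-moments negative binomial fit with the package's variance and
# dispersion floors; returns c(mean, dispersion) with var = m + m^2/dispersion.
fit_nb_moments <- function(x, dispersion_floor = 1e-3, variance_pad = 1e-6) {
  m <- mean(x)
  v <- stats::var(x)
  if (!is.finite(v)) v <- 0
  v <- max(v, m + variance_pad)   # variance floor: strictly overdispersed
  disp <- m^2 / (v - m)
  disp <- max(disp, dispersion_floor)
  c(mean = m, dispersion = disp)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
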