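## Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All generators route their randomness through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

stop_if_not_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

stop_if_not_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok) {
    stop(sprintf("`%s` must be a probability in %s0, 1%s", name,
                 if (open_left) "(" else "[", if (open_right) ")" else "]"),
         call. = FALSE)
  }
  invisible(as.numeric(x))
}

# Coerce an abundance input (matrix or rollup result) to the plain
# proteins x timepoints log10 matrix.
as_abundance_matrix <- function(x) {
  if (inherits(x, "abundance_matrix")) return(x$log10_abundance)
  if (is.matrix(x)) return(x)
  stop("expected an abundance matrix (proteins x time points)", call. = FALSE)
}

time_cols <- function(mat) as.numeric(colnames(mat))
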