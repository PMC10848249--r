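#' Derive reproducible child seeds from a single master seed
#'
#' Every stochastic stage of the pipeline (scheduling, noise synthesis, data
#' splitting, weight initialization, ...) consumes its own child seed so that
#' stages can be re-run independently and still reproduce a full-pipeline run.
#' Children are drawn from a generator seeded with the master seed, which makes
#' the mapping deterministic.
#'
#' @param seed Master integer seed.
#' @param n Number of child seeds to derive.
#' @param labels Optional character vector of names for the result.
#' @return Integer vector of length `n` (named if `labels` given), each in
#'   `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n, labels = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  out <- sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
  if (!is.null(labels)) names(out) <- labels
  out
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Run an expression under a local RNG seed
#'
#' Evaluates `expr` with the global RNG seeded to `seed`, restoring the
#' caller's RNG state afterwards so library code never perturbs user
#' randomness.
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)

check_label <- function(label) {
  bad <- setdiff(unique(as.character(label)), c("lie", "truth"))
  if (length(bad) > 0) {
    stop_cfg("unknown label value(s): %s (expected 'lie' or 'truth')",
             paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

channel_names <- function(n_channels) sprintf("ch%02d", seq_len(n_channels))

intensity_colnames <- function(n_channels) {
  as.vector(t(outer(channel_names(n_channels), c("w1", "w2"), paste, sep = "_")))
}
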