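#' Default duplication-node age table
#'
#' Divergence-time estimates (million years) for the duplication-node labels
#' used throughout the package. `Vertebrata` is the conventional root of the
#' vertebrate lineage; nodes older than it (here `Chordata`) mark
#' pre-vertebrate duplications, which are excluded from duplicate
#' classification. Values are config-overridable everywhere they are consumed.
#'
#' @return Named numeric vector of ages in MY.
#' @export
default_node_ages <- function() {
  c(
    Chordata     = 550,
    Vertebrata   = 530,
    Euteleostomi = 430,
    Tetrapoda    = 350,
    Amniota      = 310,
    Mammalia     = 180,
    Primates     = 75,
    Homininae    = 9
  )
}

# stop() with call. = FALSE everywhere; keeps messages clean in drivers
stop2 <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive reproducible child seeds from a master seed
#'
#' Used by the iterated protocols so that every iteration has its own seed
#' while the whole run is a deterministic function of one master seed.
#'
#' @param seed master seed (integer).
#' @param n number of child seeds.
#' @return Integer vector of length `n`, all below 2^31.
#' @keywords internal
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# canonical unordered pair key "a|b" with a < b lexicographically
pair_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop2(what, " is missing required column(s): ",
          paste(missing, collapse = ", "))
  invisible(df)
}
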