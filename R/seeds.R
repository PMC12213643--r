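#' Derive a reproducible child seed from a master seed
#'
#' Every stochastic operation in the package draws its randomness from a child
#' stream derived from `(master_seed, label, index)`, so that modules are
#' independently reproducible: re-running one operation with the same master
#' seed gives the same result regardless of what ran before it.
#'
#' The derivation is a small multiplicative hash over the UTF-8 codes of
#' `label`, mixed with the master seed and replicate index, reduced modulo
#' 2^31 - 2 (R's `set.seed()` accepts 32-bit integers).
#'
#' @param master_seed Integer master seed.
#' @param label Character scalar naming the operation.
#' @param index Non-negative integer replicate index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "meiosis")
#' derive_seed(1, "meiosis", index = 2)
#' @export
derive_seed <- function(master_seed, label, index = 0L) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(label), length(label) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  h <- (as.double(master_seed) %% m) * 48271 %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% m
  }
  h <- (h + as.double(index) * 7919) %% m
  h <- (h * 69621) %% m
  as.integer(h %% (m - 1)) + 1L
}

# Run an expression with a derived child RNG stream, restoring the caller's
# RNG state afterwards.
with_child_seed <- function(master_seed, label, index = 0L, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
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
  set.seed(derive_seed(master_seed, label, index))
  expr
}
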