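# RNG hygiene: seeded functions save and restore the caller's RNG state.
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Derive a per-stage seed from a master seed
#'
#' Deterministic stream splitting: every stochastic stage of the pipeline
#' draws its own seed from the master seed and a stage label, so stages
#' are individually re-runnable and the whole run is reproducible from
#' one integer. Derived seeds stay below 2^31.
#'
#' @param master Integer master seed.
#' @param stage Stage label (character) or integer offset.
#' @return Integer seed.
#' @export
derive_seed <- function(master, stage) {
  off <- if (is.character(stage)) {
    sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  } else as.integer(stage)
  as.integer((as.numeric(master) * 7919 + off * 104729) %% 2147483629)
}
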