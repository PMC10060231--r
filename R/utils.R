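`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a fixed RNG state without disturbing the caller's
## stream; seed = NULL uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("meionascent_input_error",
                                             "error", "condition")))
}

stop_contract <- function(...) {
  stop(errorCondition(paste0(...), class = c("meionascent_contract_error",
                                             "error", "condition")))
}

#' Derive a per-module seed from a master seed
#'
#' Deterministic derivation so each pipeline stage is independently
#' reproducible from one master seed. Results stay below 2^31 - 1.
#' @param master Master integer seed.
#' @param module One of `simulate`, `calibrate`, `normalize`, `pause`,
#'   `cluster`, `overlap`.
#' @return An integer seed.
#' @export
derive_seed <- function(master, module) {
  modules <- c("simulate", "calibrate", "normalize", "pause",
               "cluster", "overlap")
  i <- match(module, modules)
  if (is.na(i)) stop_input("unknown module: ", module)
  as.integer((as.numeric(master) + 7919 * i) %% 2147483647)
}
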