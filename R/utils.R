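#' @keywords internal
"_PACKAGE"

## Molar gas constant, J/(mol K)
.R_GAS <- 8.31446

#' Ideal gas constant used throughout the package
#'
#' @return The molar gas constant in J/(mol K).
#' @export
gas_constant <- function() .R_GAS

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's .Random.seed afterwards so library code never clobbers the
## user's RNG stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      suppressWarnings(rm(".Random.seed", envir = env))
  }, add = TRUE)
  set.seed(seed)
  expr
}

## Condition constructors: errors carry a class so callers can handle the
## specific failure (e.g. invalid_smiles during batch ingestion).
stop_hanna <- function(class, msg, call. = FALSE) {
  cond <- structure(
    class = c(class, "hanna_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  )
  stop(cond)
}

warn_hanna <- function(class, msg) {
  cond <- structure(
    class = c(class, "hanna_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  )
  warning(cond)
}

## 31-bit polynomial rolling hash of a string (deterministic across
## platforms; plain double arithmetic, all intermediates < 2^53).
string_hash <- function(s) {
  codes <- utf8ToInt(s)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  h
}
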