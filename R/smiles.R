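#' Canonicalize a SMILES string
#'
#' Converts a SMILES string to the canonical form of the Open Babel toolkit
#' (via the ChemmineOB package).  Canonicalization is idempotent: applying it
#' to an already-canonical string returns the string unchanged.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES.  Unparsable input raises an
#'   error of class `invalid_smiles`.
#' @examples
#' \dontrun{
#' canonicalize_smiles("OCC")  # "CCO"
#' }
#' @export
canonicalize_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) < 1L || any(!nzchar(smiles)))
    stop_hanna("invalid_smiles", "SMILES must be non-empty strings")
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop_hanna("backend_unavailable",
               "ChemmineOB is required for SMILES canonicalization")
  vapply(smiles, function(s) {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s)),
      error = function(e) ""
    )
    out <- trimws(out)
    if (!nzchar(out))
      stop_hanna("invalid_smiles", sprintf("cannot parse SMILES: '%s'", s))
    ## output is "<smiles>\t<name>" style; keep the first field
    strsplit(out, "[ \t]")[[1]][1]
  }, character(1), USE.NAMES = FALSE)
}

#' Test whether SMILES strings are parsable
#'
#' @param smiles Character vector.
#' @return Logical vector, `TRUE` where the string canonicalizes.
#' @export
is_valid_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    !inherits(tryCatch(canonicalize_smiles(s), error = function(e) e), "error")
  }, logical(1), USE.NAMES = FALSE)
}
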