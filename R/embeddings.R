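## Component embeddings.
##
## A backend maps a SMILES (or component tag) to a fixed-length numeric
## vector.  The production backend of the original method is the CLS-token
## embedding of a pretrained chemical language model (384 dimensions); that
## model must be supplied externally (it cannot be computed here), so two
## offline backends are provided: a deterministic hash-keyed pseudo-embedding
## and a lookup table of precomputed vectors.

#' Deterministic offline embedding backend
#'
#' Maps every component string to a reproducible pseudo-random vector keyed
#' on the string itself: identical strings always give bitwise-identical
#' vectors, distinct strings give distinct vectors with probability ~ 1.
#' Intended for testing and for fully synthetic studies; it carries no
#' chemical information.
#'
#' @param dim Embedding dimension (default 384, matching the language-model
#'   backend's width).
#' @param seed Integer mixed into the per-string key, so different backends
#'   produce unrelated embeddings.
#' @return An object of class `hanna_backend`.
#' @export
hash_backend <- function(dim = 384L, seed = 0L) {
  dim <- as.integer(dim)
  stopifnot(dim >= 1L)
  structure(
    list(name = "hash-fallback", dim = dim, seed = as.integer(seed),
         canonicalize = FALSE),
    class = "hanna_backend"
  )
}

#' Lookup-table embedding backend
#'
#' Serves precomputed embedding vectors (e.g. exported from a chemical
#' language model) from a data frame with a `smiles` column followed by
#' numeric columns.
#'
#' @param table Data frame: column `smiles`, then `dim` numeric columns.
#' @param name Backend tag stored in component records.
#' @return An object of class `hanna_backend`.
#' @export
table_backend <- function(table, name = "table") {
  stopifnot(is.data.frame(table), "smiles" %in% names(table))
  vals <- as.matrix(table[setdiff(names(table), "smiles")])
  storage.mode(vals) <- "double"
  rownames(vals) <- table$smiles
  structure(
    list(name = name, dim = ncol(vals), values = vals, canonicalize = FALSE),
    class = "hanna_backend"
  )
}

#' Pretrained chemical-language-model backend (placeholder)
#'
#' The reference embedding backend is the CLS-token output of the pretrained
#' ChemBERTa-2 "77M-MTR" model (384 dimensions, 512-token limit).  Running
#' that model requires its published checkpoint and a transformer runtime,
#' neither of which this package ships; calling this backend therefore raises
#' a `backend_unavailable` error.  Export the CLS embeddings once with the
#' published model and serve them through [table_backend()], or use
#' [hash_backend()] for synthetic studies.
#'
#' @return Never returns; raises `backend_unavailable`.
#' @export
chemberta_backend <- function() {
  stop_hanna("backend_unavailable", paste0(
    "the 'chemberta2-77M-MTR' backend needs the published language-model ",
    "checkpoint; precompute its CLS embeddings and use table_backend(), ",
    "or use hash_backend() for synthetic data"
  ))
}

#' @export
print.hanna_backend <- function(x, ...) {
  cat(sprintf("<embedding backend '%s', dim = %d>\n", x$name, x$dim))
  invisible(x)
}

#' Embed one component
#'
#' @param smiles Component SMILES string (or synthetic tag for the
#'   hash-fallback backend).
#' @param backend A [hash_backend()] or [table_backend()].
#' @return A `component_record`: list with `smiles`, `embedding` (length
#'   `backend$dim`) and `backend_id`.
#' @export
embed_component <- function(smiles, backend) {
  stopifnot(inherits(backend, "hanna_backend"), is.character(smiles),
            length(smiles) == 1L, nzchar(smiles))
  emb <- switch(backend$name,
    "hash-fallback" = {
      key <- (string_hash(smiles) * 2654435761 + backend$seed) %% 2147483647
      with_seed(as.integer(key), stats::rnorm(backend$dim))
    },
    {
      if (!smiles %in% rownames(backend$values))
        stop_hanna("backend_unavailable",
                   sprintf("no embedding stored for '%s'", smiles))
      as.numeric(backend$values[smiles, ])
    }
  )
  structure(list(smiles = smiles, embedding = emb, backend_id = backend$name),
            class = "component_record")
}

#' Embed many components with caching
#'
#' Embeddings are computed once per unique component string and reused.
#'
#' @param smiles Character vector.
#' @param backend Embedding backend.
#' @param cache Optional environment used as the cache across calls.
#' @return Numeric matrix, one row per element of `smiles`.
#' @export
embed_components <- function(smiles, backend, cache = NULL) {
  uniq <- unique(smiles)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  for (s in uniq) {
    if (is.null(cache[[s]])) cache[[s]] <- embed_component(s, backend)$embedding
  }
  out <- do.call(rbind, lapply(smiles, function(s) cache[[s]]))
  rownames(out) <- NULL
  out
}

#' Fit standardization scalers on training records
#'
#' Computes per-dimension mean and population standard deviation (divide by
#' n) of the component embeddings, and of the temperature.  Dimensions with
#' zero variance get their std replaced by 1 and raise a `degenerate_column`
#' warning.  Mole fractions are never scaled.
#'
#' @param embeddings Numeric matrix (rows = training-record components).
#' @param T_K Numeric vector of training temperatures in Kelvin.
#' @return An object of class `scaler_set`.
#' @export
fit_scalers <- function(embeddings, T_K) {
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) < 2L || length(T_K) < 2L)
    stop_hanna("too_few_records", "need at least 2 records to fit scalers")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  mu <- colMeans(embeddings)
  sd_ <- apply(embeddings, 2L, pop_sd)
  t_mu <- mean(T_K)
  t_sd <- pop_sd(T_K)
  degen <- sd_ <= 0
  if (any(degen) || t_sd <= 0) {
    warn_hanna("degenerate_column", sprintf(
      "%d embedding dimension(s)%s had zero variance; std set to 1",
      sum(degen), if (t_sd <= 0) " and the temperature" else ""))
    sd_[degen] <- 1
    if (t_sd <= 0) t_sd <- 1
  }
  structure(
    list(embedding_mean = mu, embedding_std = sd_,
         temperature_mean = t_mu, temperature_std = t_sd,
         degenerate_dims = which(degen), std_convention = "population"),
    class = "scaler_set"
  )
}

#' @export
print.scaler_set <- function(x, ...) {
  cat(sprintf(
    "<scaler_set: %d embedding dims, T mean %.2f K, T std %.3f K (%s std)>\n",
    length(x$embedding_mean), x$temperature_mean, x$temperature_std,
    x$std_convention))
  invisible(x)
}

#' Standardize embeddings or temperatures
#'
#' Applies `z = (x - mean) / std` with the fitted scalers; the identical
#' transform is used at training and inference time.
#'
#' @param x Numeric matrix of embeddings (`what = "embedding"`) or numeric
#'   vector of temperatures in Kelvin (`what = "temperature"`).
#' @param scalers A [fit_scalers()] result.
#' @param what Which scaler to apply.
#' @return Same shape as `x`.
#' @export
standardize <- function(x, scalers, what = c("embedding", "temperature")) {
  stopifnot(inherits(scalers, "scaler_set"))
  what <- match.arg(what)
  if (what == "temperature")
    return((x - scalers$temperature_mean) / scalers$temperature_std)
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(x) != length(scalers$embedding_mean))
    stop_hanna("shape_mismatch", sprintf(
      "embedding width %d does not match scaler width %d",
      ncol(x), length(scalers$embedding_mean)))
  sweep(sweep(x, 2L, scalers$embedding_mean, "-"),
        2L, scalers$embedding_std, "/")
}

#' Invert [standardize()]
#'
#' @inheritParams standardize
#' @return Same shape as `x`, on the original scale.
#' @export
unstandardize <- function(x, scalers, what = c("embedding", "temperature")) {
  stopifnot(inherits(scalers, "scaler_set"))
  what <- match.arg(what)
  if (what == "temperature")
    return(x * scalers$temperature_std + scalers$temperature_mean)
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  sweep(sweep(x, 2L, scalers$embedding_std, "*"),
        2L, scalers$embedding_mean, "+")
}
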