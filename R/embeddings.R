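#' Deterministic offline string embedder
#'
#' Character trigram counts (with `^`/`$` boundary padding) hashed into `dim`
#' buckets with seeded signs, then L2-normalized. Purely a function of
#' `(text, dim, seed)`: no model download, no RNG state. Similar strings share
#' trigrams and therefore yield correlated vectors, which is all the
#' downstream encoders require of an initial feature; it is not a substitute
#' for chemical or biological semantics.
#'
#' @param text a single non-empty string.
#' @param dim embedding dimension (>= 8).
#' @param seed integer hash seed.
#' @return unit-norm numeric vector of length `dim`.
#' @export
#' @examples
#' v <- offline_embed("MKVLAA", dim = 32, seed = 1)
#' sum(v^2)  # 1
offline_embed <- function(text, dim = 64L, seed = 1L) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || nchar(text) == 0) {
    stop("offline_embed requires a single non-empty string")
  }
  if (dim < 8) stop("dim must be >= 8")
  padded <- paste0("^", text, "$")
  n <- nchar(padded)
  grams <- substring(padded, 1:(n - 2), 3:n)
  hb <- ngram_bucket_sign(grams, as.integer(dim), as.double(seed))
  v <- numeric(dim)
  for (j in seq_along(grams)) {
    v[hb$bucket[j]] <- v[hb$bucket[j]] + hb$sign[j]
  }
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) {
    # signs cancelled exactly; fall back to a deterministic one-hot
    v[1 + (hb$bucket[1] %% dim)] <- 1
    nrm <- 1
  }
  v / nrm
}

#' Embedding backends
#'
#' An embedding backend maps an input string (SMILES for drugs, amino-acid
#' sequence for proteins) to a fixed-length numeric vector. The default,
#' [offline_backend()], wraps [offline_embed()] and needs no downloads.
#' Pretrained chemical- or protein-language models (e.g. the
#' PubChem10M_SMILES_BPE and ESM-2 families) plug in through the same
#' interface: supply any vector-valued `fn` of a string, e.g. one that calls
#' out to a local model server, and declare its output dimension.
#'
#' @param name backend name (recorded in run manifests).
#' @param dim declared output dimension.
#' @param fn function(string) -> numeric vector of length `dim`.
#' @return object of class `embedding_backend`.
#' @export
embedding_backend <- function(name, dim, fn) {
  stopifnot(is.character(name), is.function(fn), dim >= 1)
  structure(list(name = name, dim = as.integer(dim), fn = fn),
            class = "embedding_backend")
}

#' @rdname embedding_backend
#' @param seed hash seed for the offline embedder.
#' @export
offline_backend <- function(dim = 64L, seed = 1L) {
  force(dim); force(seed)
  embedding_backend(sprintf("offline-trigram-%d-s%d", dim, seed), dim,
                    function(s) offline_embed(s, dim = dim, seed = seed))
}

#' Embed drug SMILES strings
#'
#' @param smiles character vector of SMILES strings.
#' @param backend an [embedding_backend()]; default offline.
#' @param ids optional drug ids used in error messages.
#' @return numeric matrix, one row per input string in input order.
#' @export
embed_drugs <- function(smiles, backend = offline_backend(), ids = NULL) {
  embed_strings(smiles, backend, ids, what = "drug")
}

#' Embed protein amino-acid sequences
#'
#' Sequences are validated against the 20-letter amino-acid alphabet plus X;
#' nonstandard letters produce a warning (the vector is still computed).
#'
#' @param sequences character vector of amino-acid sequences.
#' @inheritParams embed_drugs
#' @return numeric matrix, one row per sequence.
#' @export
embed_proteins <- function(sequences, backend = offline_backend(), ids = NULL) {
  aa <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  for (i in seq_along(sequences)) {
    letters_i <- unique(strsplit(sequences[i], "")[[1]])
    bad <- setdiff(letters_i, aa)
    if (length(bad) > 0) {
      warning("sequence ", if (is.null(ids)) i else ids[i],
              " contains nonstandard letters: ", paste(bad, collapse = ""))
    }
  }
  embed_strings(sequences, backend, ids, what = "protein")
}

embed_strings <- function(strings, backend, ids, what) {
  stopifnot(inherits(backend, "embedding_backend"))
  if (length(strings) == 0) stop("no ", what, " strings supplied")
  out <- matrix(0, nrow = length(strings), ncol = backend$dim)
  for (i in seq_along(strings)) {
    s <- strings[i]
    id <- if (is.null(ids)) as.character(i) else ids[i]
    if (is.na(s) || nchar(s) == 0) stop("empty ", what, " string for ", id)
    v <- tryCatch(backend$fn(s), error = function(e) {
      stop("embedding backend '", backend$name, "' failed for ", what, " ",
           id, ": ", conditionMessage(e))
    })
    if (length(v) != backend$dim || any(!is.finite(v))) {
      stop("backend '", backend$name, "' returned an invalid vector for ",
           what, " ", id)
    }
    out[i, ] <- v
  }
  rownames(out) <- ids
  out
}
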