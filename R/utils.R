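#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit string hash (Horner scheme); used only for default
# document ids derived from URLs. Collisions are caught by the uniqueness
# check in load_corpus.
string_hash <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (b in utf8ToInt(enc2utf8(s))) h <- (h * 131 + b) %% 2147483647
    sprintf("u%08x", as.integer(h))
  }, character(1), USE.NAMES = FALSE)
}

# Key helpers shared by the NER and graph modules.
entity_key <- function(vocab, canonical) paste(vocab, canonical, sep = ":")

stop_ndkg <- function(...) stop(..., call. = FALSE)
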