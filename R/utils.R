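#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded package functions do not perturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a child seed from a parent seed and a label
#'
#' Deterministic 32-bit FNV-style hash of `(seed, label)`, kept within the
#' positive integer range so every stage and fold of a run gets its own
#' reproducible stream from one global seed.
#'
#' @param seed parent integer seed.
#' @param label character or integer tag for the consumer.
#' @return a positive integer seed.
#' @keywords internal
derive_seed <- function(seed, label) {
  bytes <- utf8ToInt(paste0(format(seed, scientific = FALSE), "/",
                            paste(as.character(label), collapse = "/")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648), as.integer(b)) +
      (if (h >= 2147483648) 2147483648 else 0)
    # 32-bit multiply by the FNV prime in 16-bit halves (doubles lack the
    # precision for a direct 56-bit product)
    h0 <- h %% 65536
    h1 <- h %/% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  h <- h %% 2147483646
  as.integer(h + 1)
}

#' Stable short hash of a character vector
#' @keywords internal
label_hash <- function(x) {
  derive_seed(0L, paste(x, collapse = "|"))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Is a value a single finite number?
#' @keywords internal
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
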