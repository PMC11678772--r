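stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression with a private, restorable RNG state
#'
#' All stochastic steps in the package draw from R's RNG through this wrapper
#' so that user session RNG state is never disturbed and every draw is
#' reproducible from an integer seed.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream label, keeping the
# result a valid 32-bit R integer.  Cheap string hash (djb2), not crypto.
derive_seed <- function(seed, label) {
  h <- 5381
  for (ch in utf8ToInt(paste0(label, ":", seed)))
    h <- (h * 33 + ch) %% 2147483629
  as.integer(h)
}

# md5 of an in-memory object via a temporary serialized file (tools::md5sum
# is file-based); used for corpus/config fingerprints in manifests.
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}
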