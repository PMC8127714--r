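# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic 31-bit string hash
#'
#' Polynomial rolling hash used to derive per-population RNG sub-streams
#' from a master seed, so generated populations are independent of the order
#' in which they are produced. Stable across platforms (pure integer
#' arithmetic below 2^31).
#'
#' @param x character scalar.
#' @return integer in [0, 2^31 - 2].
#' @keywords internal
hash_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# run code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# moment-based sample skewness (used by the auto transform policy)
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  s <- stats::sd(x)
  if (s == 0) return(0)
  mean(((x - mean(x)) / s)^3)
}

# stable hash of an arbitrary R object (config fingerprinting in manifests)
object_hash <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "keepInteger")), collapse = "\n")
  hash_string(txt)
}

#' Trait name sets used throughout the selection analyses
#'
#' Four inflorescence-level traits (disk diameter DD, ray length RL, ray
#' width RW, number of rays NR), five disk-flower traits (corolla lobe size
#' CS, distal throat width DTW, distal throat length DTL, proximal throat
#' size PTS, corolla tube size TS), and two antagonist traits (proportion of
#' seeds attacked by the moth, ISO, and by the midge, NEO).
#'
#' @return named list of character vectors with elements `inflorescence`,
#'   `flower`, `antagonist`, `all` (the eleven analysis traits) and
#'   `gradient_covariates` (the eleven traits plus stem volume).
#' @export
trait_sets <- function() {
  infl <- c("DD", "RL", "RW", "NR")
  flow <- c("CS", "DTW", "DTL", "PTS", "TS")
  antg <- c("ISO", "NEO")
  list(
    inflorescence = infl,
    flower = flow,
    antagonist = antg,
    all = c(infl, flow, antg),
    gradient_covariates = c(infl, flow, antg, "volume")
  )
}
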