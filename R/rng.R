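#' Derive a child RNG seed from a root seed and a block name
#'
#' Each stochastic block draws its noise from an independent stream keyed by
#' its name, so adding or removing a block does not perturb the noise seen by
#' the others. The child seed is an FNV-1a style hash of the block name folded
#' with the root seed, reduced modulo 2^31 - 1.
#'
#' @param root_seed integer root seed of the run.
#' @param name character block name.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(root_seed, name) {
  stopifnot(length(name) == 1L, is.character(name))
  h <- 2166136261 %% 2147483647  # FNV offset basis folded into 31 bits
  for (b in utf8ToInt(name)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    # multiply by the FNV prime in double precision (exact below 2^53)
    h <- (as.double(h) * 16777619) %% 2147483647
  }
  s <- (h + as.double(root_seed) * 2654435761) %% 2147483646
  as.integer(s) + 1L
}

# Draw n standard-normal values from a child stream without disturbing the
# caller's RNG state.
child_normals <- function(root_seed, name, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(child_seed(root_seed, name))
  stats::rnorm(n)
}

child_uniforms <- function(root_seed, name, n, min = 0, max = 1) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(child_seed(root_seed, name))
  stats::runif(n, min = min, max = max)
}
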