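#' Derive a child random seed from a master seed
#'
#' Deterministic seed-spawning used throughout the package so that every unit
#' of work (simulation replicate, power-grid cell, region-level test) gets its
#' own reproducible random stream and can be re-run in isolation. The scheme is
#' a Lehmer-style multiplicative hash,
#' `((master mod M) * 69069 + key) mod M` with `M = 2^31 - 1`,
#' mapped to 1 when it lands on 0 so the result is always a valid seed for
#' [set.seed()].
#'
#' @param master Integer master seed.
#' @param key Integer key (or vector of keys) identifying the child stream,
#'   e.g. a replicate index or a region label.
#' @return Integer seed(s) in `[1, 2^31 - 2]`, same length as `key`.
#' @export
#' @examples
#' spawn_seed(42L, 1:3)
spawn_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(key), all(is.finite(key)))
  m <- 2147483647 # 2^31 - 1; all arithmetic stays well below 2^53
  s <- ((abs(as.numeric(master)) %% m) * 69069 + abs(as.numeric(key))) %% m
  s <- floor(s)
  s[s == 0] <- 1
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# YAML loader that keeps YAML-1.1 boolean-like scalars ("n", "y", "no", ...)
# as literal strings, so configuration keys like `n:` survive parsing.
read_config_yaml <- function(path) {
  yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) x,
    "bool#no" = function(x) x
  ))
}
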