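# Conditions, hashing, small shared helpers.

abort_config <- function(msg, field = NULL, call = sys.call(-1)) {
  stop(structure(
    class = c("alsdyn_config_error", "error", "condition"),
    list(message = if (is.null(field)) msg else sprintf("%s [field: %s]", msg, field),
         call = call, field = field)))
}

abort_stale <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("alsdyn_stale_input", "error", "condition"),
                 list(message = msg, call = call)))
}

abort_numerical <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("alsdyn_numerical_error", "error", "condition"),
                 list(message = msg, call = call)))
}

#' Hash an R object (FNV-1a over its serialized bytes)
#'
#' Used as a stale-input guard between pipeline stages; not cryptographic.
#'
#' @param x any serializable R object
#' @return a 16-character hex string
#' @export
hash_object <- function(x) {
  fnv1a_hex(serialize(x, NULL, version = 2, xdr = TRUE))
}

#' Hash a file's bytes
#' @param path file path
#' @return a 16-character hex string
#' @export
hash_file <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("file not found: %s", path))
  fnv1a_hex(readBin(path, "raw", n = file.info(path)$size))
}

# log-sum-exp
lse <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
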