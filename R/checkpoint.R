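# Single-file checkpoints with the architecture descriptor embedded.

#' Save / load parameter checkpoints
#'
#' A checkpoint is a single serialized file containing the parameter
#' collection(s) and their architecture descriptors; a parameter checksum is
#' reported so runs can be compared from logs.
#'
#' @param object a `"generator_params"`, `"discriminator_params"`,
#'   `"ouroboros"` fit or any list of them.
#' @param path output file.
#' @return `path` invisibly; `load_checkpoint()` returns the object.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  message(sprintf("checkpoint %s written (checksum %.6g)", path,
                  checkpoint_checksum(object)))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  object <- readRDS(path)
  message(sprintf("checkpoint %s loaded (checksum %.6g)", path,
                  checkpoint_checksum(object)))
  object
}

checkpoint_checksum <- function(object) {
  acc <- 0
  walk <- function(x) {
    if (is.numeric(x)) acc <<- acc + sum(abs(x))
    else if (is.list(x)) for (el in x) walk(el)
  }
  walk(object)
  acc
}
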