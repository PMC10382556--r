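# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
ps_stop <- function(...) stop(sprintf(...), call. = FALSE)

#' @keywords internal
#' @noRd
ps_warn <- function(...) warning(sprintf(...), call. = FALSE)

#' @keywords internal
#' @noRd
ps_msg <- function(verbose, ...) if (isTRUE(verbose)) message(sprintf(...))

# Deterministic per-stage seed derived from a master seed. Kept below 2^31-1.
#' @keywords internal
#' @noRd
derive_seed <- function(master_seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master_seed) * 2654435.0 + h * 97 + 13) %% 2147483647)
}

#' @keywords internal
#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
#' @noRd
trapezoid <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}
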