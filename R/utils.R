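# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(structure(class = c("pahrisk_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_schema <- function(...) {
  stop(structure(class = c("pahrisk_schema_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_flag_choice <- function(x, choices, name) {
  if (!(is.character(x) && length(x) == 1L && x %in% choices))
    stop_validation(sprintf("'%s' must be one of: %s", name,
                            paste(choices, collapse = ", ")))
  x
}

# deterministic 31-bit hash of a string; used to derive per-parent RNG
# substreams so that adding a parent does not perturb the others
stable_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

md5_of <- function(paths) unname(tools::md5sum(paths))

# write a data.frame preserving full double precision so that a
# write -> read round trip is the identity on values
write_table_precise <- function(x, path, sep = ",") {
  y <- x
  for (j in seq_along(y)) {
    if (is.double(y[[j]])) {
      v <- sprintf("%.17g", y[[j]])
      v[is.na(y[[j]])] <- NA
      y[[j]] <- v
    }
  }
  utils::write.table(y, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
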