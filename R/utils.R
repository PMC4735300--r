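# internal helpers shared across modules

# Coerce a label vector to logical (TRUE = positive class). Accepts logical,
# or character/factor with an explicit positive level.
as_binary_labels <- function(labels, positive = "active") {
  if (is.logical(labels)) return(labels)
  labels <- as.character(labels)
  lab <- labels == positive
  lab[is.na(labels)] <- NA
  lab
}

# md5 of a canonical text rendering of an R object (numbers at full
# precision). Used for training-set fingerprints and pipeline stage hashes.
object_hash <- function(...) {
  objs <- list(...)
  txt <- vapply(objs, function(o) {
    if (is.numeric(o)) paste(sprintf("%.17g", o), collapse = ",")
    else paste(as.character(unlist(o)), collapse = ",")
  }, character(1))
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

fmt_num <- function(x) sprintf("%.17g", x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
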