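## Internal helpers.

## Evaluate `expr` under a temporarily seeded RNG, restoring the caller's
## RNG state afterwards so generators never perturb user code.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## Recursively sort list names so the hash is stable under key reordering.
.canonicalize <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && any(nzchar(names(x))))
      x <- x[order(names(x))]
    lapply(x, .canonicalize)
  } else x
}

#' Content hash of a configuration
#'
#' MD5 of the canonical (key-sorted) JSON serialization, stable under key
#' reordering.
#'
#' @param config a (possibly nested) named list.
#' @return character MD5 hash.
#' @export
configHash <- function(config) {
  js <- jsonlite::toJSON(.canonicalize(config), auto_unbox = TRUE, digits = NA)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(as.character(js), f)
  unname(tools::md5sum(f))
}
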