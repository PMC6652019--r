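# Internal helpers: scoped RNG, argument checks, plain-text table IO.

# Offsets used to derive one independent RNG stream per simulator from the
# master seed, so each fixture can be regenerated on its own.
.STREAM_OFFSETS <- c(
  genome     = 0L,
  expression = 100003L,
  secretion  = 200003L,
  homology   = 300007L,
  alignments = 400009L
)

stream_seed <- function(seed, stream) {
  stopifnot(stream %in% names(.STREAM_OFFSETS))
  s <- as.integer(seed) + .STREAM_OFFSETS[[stream]]
  if (s > .Machine$integer.max - 1L) s <- s %% 1000000007L
  s
}

# Evaluate `code` under set.seed(seed) and restore the caller's RNG state.
with_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a tab-separated table with a header row
#'
#' @param path file path.
#' @return a `data.frame`, strings kept as character.
#' @export
read_tsv_table <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write a data frame as a tab-separated table with a header row
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
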