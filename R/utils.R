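#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the previous
#' global RNG state afterwards, so seeded helpers do not perturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval(expr, envir = parent.frame())
}

#' Derive a per-stage seed from a global seed
#'
#' One global seed fans out to independent substreams, one per named stage,
#' so any generator can be re-run on its own and still reproduce the exact
#' stream it had inside a full run. The derivation hashes the stage name into
#' an offset and folds it into the seed modulo 2^31 - 1.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (e.g. "cohorts", "msa", "scores", "ddg").
#' @return An integer seed in [1, 2^31 - 2].
#' @export
#' @examples
#' derive_seed(1, "cohorts")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647 # 2^31 - 1, keeps derived seeds valid 32-bit integers
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% m
  s <- (abs(as.numeric(seed)) %% m) * 48271 %% m
  as.integer((s + h) %% (m - 1) + 1)
}

# stop() with a sprintf-style message, no call in the condition
.err <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# single-letter amino-acid alphabet (no stop)
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# read a delimited table with data.table but return a plain data.frame
.read_tsv <- function(path, ...) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = c("NA", ""), ...))
}

.write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
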