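# Internal helpers: validation, reproducible local RNG, seed derivation.

`%||%` <- function(a, b) if (is.null(a)) b else a

# sequential ids that stay length-0 for n = 0 (paste0 recycles otherwise)
seq_ids <- function(prefix, n) if (n > 0) paste0(prefix, seq_len(n)) else character(0)

abort_if <- function(cond, ..., class = "insertionfate_error") {
  if (cond) {
    stop(structure(
      class = c(class, "error", "condition"),
      list(message = paste0(...), call = sys.call(-1))
    ))
  }
  invisible(NULL)
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the Mersenne-Twister generator to `seed`, evaluates `code`, and
#' restores the caller's RNG state, so that every randomised operation in the
#' package is reproducible from an explicit seed without disturbing the
#' global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Deterministic substream derivation: the master seed is advanced by a
#' Lehmer step modulo the Mersenne prime 2^31 - 1 and combined with a
#' polynomial hash of the stage tag. Reordering stages therefore cannot
#' change any stage's stream, and every derived seed stays below 2^31.
#'
#' @param master Integer master seed.
#' @param tag Character stage label (e.g. `"simulate"`, `"shuffle:17"`).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "simulate")
#' derive_seed(1L, "enrich") != derive_seed(2L, "enrich")
derive_seed <- function(master, tag) {
  abort_if(length(master) != 1L || is.na(master), "master seed must be a single integer")
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (ch in utf8ToInt(as.character(tag))) h <- (h * 31 + ch) %% m
  s <- (abs(as.numeric(master)) %% m)
  s <- (s * 48271) %% m # Lehmer / MINSTD multiplier
  as.integer(((s + h) %% (m - 1)) + 1)
}

# Stable TSV writer: header line, optional '# key=value' comment block, no
# quoting, no row names. All pipeline outputs go through this so reruns are
# byte-identical.
write_tsv_commented <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_commented <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, ...)
}
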