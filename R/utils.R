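# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Guess the field separator of a delimited text file from its header line.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab >= n_com) "\t" else ","
}

# Stop unless `cond`; message assembled sprintf-style.
assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Simple structured logger: messages go through message() so callers can
# suppress or sink them; level gating via option jsnmf.log_level.
jsnmf_log <- function(level = c("info", "warn", "debug"), fmt, ...) {
  level <- match.arg(level)
  threshold <- getOption("jsnmf.log_level", "info")
  ranks <- c(debug = 1L, info = 2L, warn = 3L)
  if (ranks[[level]] < ranks[[threshold]]) return(invisible(NULL))
  message(sprintf("[jsnmf:%s] %s", level, sprintf(fmt, ...)))
  invisible(NULL)
}

# Frobenius norm.
fnorm <- function(M) sqrt(sum(M * M))

# Population (1/n) standard deviation.
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(seed)
  force(code)
}
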