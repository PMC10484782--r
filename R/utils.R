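# Internal validation and formatting helpers.

stop_validation <- function(...) {
  stop(structure(class = c("exomeburden_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_prob <- function(x, name, upper = 1) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > upper))
    stop_validation(name, " must be in [0, ", upper, "]")
  invisible(x)
}

check_binary <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || !all(x %in% c(0, 1)))
    stop_validation(name, " must be 0/1")
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
    stop_validation(name, " must be an integer >= ", min)
  invisible(as.integer(x))
}

#' @noRd
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log(exp(a - m) + exp(b - m)))
}

# Fixed-format numbers (6 significant digits) so pipeline reruns are
# byte-identical.
format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

# Run an expression under a local RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
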