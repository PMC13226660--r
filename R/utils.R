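# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Offset a user seed without leaving 32-bit integer range.
offset_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k) %% (.Machine$integer.max - 1L)) + 1L
}

stop_input <- function(...) stop(..., call. = FALSE)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input(sprintf("'%s' must be a single finite number", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_input(sprintf("'%s' = %g is outside its allowed range", name, x))
  invisible(x)
}

check_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_input(sprintf("'%s' must be a numeric matrix", name))
  if (anyNA(x)) stop_input(sprintf("'%s' contains missing values", name))
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop_input(sprintf("'%s' must have unique row names (gene ids)", name))
  invisible(x)
}

# Stable content hash of an R object for provenance blocks (md5 of its
# canonical JSON rendering; avoids serialize() version drift).
config_hash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}

format_signif <- function(x, digits = 6L) {
  ifelse(is.na(x), "NA", formatC(signif(x, digits), format = "g", digits = digits))
}
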