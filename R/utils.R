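# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Counter-based child-seed derivation: reproducible, collision-free for
# counters below the modulus, and always a valid 32-bit integer.
child_seed <- function(master, counter) {
  if (is.null(master)) return(NULL)
  as.integer((as.double(master) * 48271 + as.double(counter)) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ctx <- function(...) stop(..., call. = FALSE)

read_csv_checked <- function(path) {
  if (!file.exists(path)) stop_ctx("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_ctx(what, " is missing column(s): ", paste(miss, collapse = ", "))
}
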