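# internal helpers shared across modules

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. seed = NULL leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_("`%s` must be a finite numeric scalar", name)
  if (positive && x <= 0) stop_("`%s` must be > 0", name)
  if (nonneg && x < 0) stop_("`%s` must be >= 0", name)
  invisible(x)
}

# canonical category levels used throughout
RSP_MODELS <- c("Catapult", "Sprinter", "Xtend")
STIFFNESS_CATS <- c("-1", "Rec", "+1")
LEGS <- c("affected", "unaffected")

# Normalise typographic variants seen in published tables: unicode minus
# (U+2212), en-dash, surrounding space.
normalize_category <- function(x, levels, what) {
  x <- trimws(as.character(x))
  x <- gsub("−|–", "-", x)
  x[x %in% c("rec", "REC", "recommended", "Recommended")] <- "Rec"
  bad <- !(x %in% levels)
  if (any(bad))
    stop_("unknown %s value: %s", what,
          paste(unique(x[bad]), collapse = ", "))
  x
}
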